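test_that("ancestor generation is seed-deterministic and density-aware", {
  a1 <- generate_ancestor(2, c(120000, 120000), n_genes = 12, seed = 1)
  a2 <- generate_ancestor(2, c(120000, 120000), n_genes = 12, seed = 1)
  expect_identical(a1$genome, a2$genome)
  expect_identical(a1$genes, a2$genes)
  expect_identical(a1$tes, a2$tes)

  a0 <- generate_ancestor(1, 120000, n_genes = 5, te_density = 0, seed = 2)
  expect_equal(nrow(a0$tes), 0)
})

test_that("observed GC tracks the requested GC closely", {
  # binomial concentration: for 1 Mb, sd of GC-hat ~ 0.0005, so +/- 0.01 is
  # a > 20-sigma band
  a <- generate_ancestor(1, 1000000, n_genes = 0, te_families = 0,
                         te_density = 0, gc = 0.5, seed = 3)
  chars <- strsplit(a$genome[[1]], "")[[1]]
  gc_obs <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5), 0.01)
})

test_that("gene models have 1-6 exons inside their gene and unique names", {
  a <- generate_ancestor(1, 200000, n_genes = 20, seed = 4)
  expect_false(any(duplicated(a$genes$feature_id)))
  per_gene <- table(sub("\\.e\\d+$", "", a$exons$feature_id))
  expect_true(all(per_gene >= 1 & per_gene <= 6))
  for (i in seq_len(nrow(a$genes))) {
    g <- a$genes[i, ]
    ex <- a$exons[startsWith(a$exons$feature_id, paste0(g$feature_id, ".")), ]
    expect_true(all(ex$start >= g$start & ex$end <= g$end))
  }
})

test_that("empty edit scripts give back the ancestor in both genomes", {
  anc <- generate_ancestor(2, c(60000, 60000), n_genes = 6, seed = 5)
  pair <- derive_pair(anc, edit_ops(), edit_ops())
  expect_identical(pair$genome1, anc$genome)
  expect_identical(pair$genome2, anc$genome)
  expect_equal(nrow(pair$truth), 0)
})

test_that("a single deletion shortens the genome and shifts liftover exactly", {
  anc <- generate_ancestor(1, 60000, n_genes = 4, seed = 6)
  pair <- derive_pair(anc, edit_ops(),
                      edit_ops("deletion", "chr1", 10000, 11000))
  expect_equal(nchar(pair$genome2[[1]]), 59000)
  lifted <- svpair:::lift_point(pair$map2, "chr1", 12000)
  expect_equal(lifted$pos, 11000)
  # positions inside the deletion are unliftable
  gone <- svpair:::lift_interval(pair$map2, "chr1", 10200, 10300)
  expect_false(gone$liftable)
})

test_that("a reciprocal translocation conserves total length and swaps tails", {
  anc <- generate_ancestor(2, c(300000, 250000), n_genes = 10, seed = 7)
  pair <- derive_pair(anc, edit_ops(), edit_ops(
    "reciprocal_translocation", "chr1", 200000, 200000, payload_len = 1,
    chrom2 = "chr2", pos2 = 150000))
  expect_equal(nchar(pair$genome2[["chr1"]]), 200000 + (250000 - 150000))
  expect_equal(nchar(pair$genome2[["chr2"]]), 150000 + (300000 - 200000))
  expect_equal(sum(nchar(pair$genome2)), sum(nchar(anc$genome)))
  expect_identical(substr(pair$genome2[["chr1"]], 200001, 200050),
                   substr(anc$genome[["chr2"]], 150001, 150050))
})

test_that("derived length equals ancestor plus net planted gain, exactly", {
  for (seed in c(11, 12)) {
    pair <- tiny_pair(seed = seed)
    tr <- pair$truth
    gains <- sum(tr$payload_len[tr$op_type %in% c(
      "insertion", "te_insertion", "repeat_expansion", "tandem_expansion")])
    losses <- sum(tr$payload_len[tr$op_type %in% c(
      "deletion", "repeat_contraction", "tandem_contraction")])
    expect_equal(sum(nchar(pair$genome2)) - sum(nchar(pair$genome1)),
                 gains - losses)
  }
})

test_that("liftover round trip is the identity away from edited segments", {
  pair <- tiny_pair(seed = 13)
  map <- pair$map2
  set.seed(99)
  for (i in 1:60) {
    chrom <- sample(names(pair$genome2), 1)
    pos <- sample.int(nchar(pair$genome2[[chrom]]), 1) - 1L
    anc <- lift_derived_to_ancestor(map, chrom, pos)
    if (is.na(anc$pos)) next  # inside an inserted payload
    back <- svpair:::lift_point(map, anc$chrom, anc$pos)
    expect_equal(back$chrom, chrom)
    expect_equal(back$pos, pos)
  }
})

test_that("overlapping operations are rejected naming the pair", {
  anc <- generate_ancestor(1, 60000, n_genes = 4, seed = 8)
  bad <- dplyr::bind_rows(
    edit_ops("deletion", "chr1", 10000, 12000),
    edit_ops("insertion", "chr1", 11000, payload_len = 100))
  expect_error(derive_pair(anc, edit_ops(), bad), "overlapping.*10000.*11000")
})

test_that("alignment-block simulation reflects the planted geometry", {
  anc <- generate_ancestor(1, 80000, n_genes = 4, seed = 9)
  # no edits: exactly one full-length + block
  id <- derive_pair(anc, edit_ops(), edit_ops())
  b0 <- simulate_alignment_blocks(id, 0, seed = 1)
  expect_equal(nrow(b0), 1)
  expect_equal(b0$strand, "+")
  expect_equal(b0$ref_end - b0$ref_start, 80000)
  expect_equal(b0$qry_end - b0$qry_start, 80000)

  # one 2 kb insertion: two blocks, ref gap 0, query gap 2000
  ins <- derive_pair(anc, edit_ops(),
                     edit_ops("insertion", "chr1", 40000, payload_len = 2000))
  b1 <- simulate_alignment_blocks(ins, 0, seed = 1)
  expect_equal(nrow(b1), 2)
  expect_equal(b1$ref_start[2] - b1$ref_end[1], 0)
  expect_equal(b1$qry_start[2] - b1$qry_end[1], 2000)

  # a planted inversion: + flanks and one - block over the span
  inv <- derive_pair(anc, edit_ops(),
                     edit_ops("inversion", "chr1", 30000, 50000))
  b2 <- simulate_alignment_blocks(inv, 0, seed = 1)
  expect_equal(b2$strand, c("+", "-", "+"))
  expect_equal(b2$ref_start[2], 30000)
  expect_equal(b2$ref_end[2], 50000)
})

test_that("contact-matrix simulation is seeded and delta-free matrices are flat", {
  p <- hic_sim_params(delta = 0, visibility_sd = 0, seed = 21)
  s1 <- simulate_contact_matrix(3000000, 100000, p)
  s2 <- simulate_contact_matrix(3000000, 100000, p)
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  # expected values depend only on |i-j| when delta = 0
  e <- simulate_contact_matrix(3000000, 100000, p, poisson_noise = FALSE)
  m <- e$matrix$counts
  for (d in c(1, 5, 10)) {
    vals <- m[cbind(seq_len(30 - d), seq_len(30 - d) + d)]
    expect_equal(max(vals) - min(vals), 0)
  }
  expect_error(hic_sim_params(delta = 1), "delta")
})

test_that("short-read call sets are seeded and complete at zero jitter", {
  pair <- tiny_pair(seed = 14, with_rearrangements = FALSE)
  cs1 <- simulate_short_read_callset(pair, 1, n_samples = 10,
                                     support_rate = 5, fp_count = 3,
                                     jitter = 0, seed = 31)
  cs2 <- simulate_short_read_callset(pair, 1, n_samples = 10,
                                     support_rate = 5, fp_count = 3,
                                     jitter = 0, seed = 31)
  expect_identical(cs1, cs2)
  n_pav <- sum(pair$truth$op_type %in% c("insertion", "te_insertion",
                                         "deletion"))
  expect_equal(nrow(cs1$callerA), n_pav + 3)
  expect_true(all(lengths(cs1$callerA$support) == 10))
})
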
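# helpers building gene sets with known collinearity
genes_on <- function(chrom, n, start0 = 0, len = 1000, gap = 4000,
                     prefix = "g") {
  starts <- start0 + (seq_len(n) - 1L) * (len + gap)
  feature_tbl(chrom, starts, starts + len, feature_id = paste0(prefix, seq_len(n)))
}

test_that("perfectly collinear pairs chain into one block per orientation", {
  ref <- genes_on("chr1", 20)
  qry <- genes_on("chr1", 20)
  pairs <- tibble::tibble(ref_gene = paste0("g", 1:20),
                          qry_gene = paste0("g", 1:20))
  blocks <- chain_collinear_anchors(pairs, ref, qry)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$orientation, "+")
  expect_equal(blocks$n_anchors, 20)

  # reversed query order: one - block
  qry_rev <- qry
  qry_rev$start <- rev(qry$start)
  qry_rev$end <- rev(qry$end)
  blocks_rev <- chain_collinear_anchors(pairs, ref, qry_rev)
  expect_equal(nrow(blocks_rev), 1)
  expect_equal(blocks_rev$orientation, "-")

  # four pairs only: below the five-anchor floor
  few <- chain_collinear_anchors(pairs[1:4, ], ref, qry)
  expect_equal(nrow(few), 0)
})

test_that("rank gaps above the cap break chains", {
  ref <- genes_on("chr1", 60)
  qry <- genes_on("chr1", 60)
  # anchors at ref positions 1..10 and 41..50: gap of 30 unanchored genes
  sel <- c(1:10, 41:50)
  pairs <- tibble::tibble(ref_gene = paste0("g", sel),
                          qry_gene = paste0("g", sel))
  blocks <- chain_collinear_anchors(pairs, ref, qry, max_gap_genes = 25)
  expect_equal(nrow(blocks), 2)
  blocks_loose <- chain_collinear_anchors(pairs, ref, qry, max_gap_genes = 35)
  expect_equal(nrow(blocks_loose), 1)
})

test_that("the chain DP matches exhaustive enumeration on small instances", {
  # oracle: brute-force subset enumeration under the same constraints
  oracle_best <- function(r, q, orientation, max_gap) {
    n <- length(r)
    best <- 0L
    for (mask in seq_len(2^n) - 1L) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
      if (length(idx) <= best) next
      idx <- idx[order(r[idx])]
      rr <- r[idx]
      qq <- if (orientation == "+") q[idx] else -q[idx]
      ok <- all(diff(rr) >= 1) && all(diff(qq) >= 1) &&
        all(diff(rr) - 1 <= max_gap) &&
        all(abs(diff(q[idx])) - 1 <= max_gap)
      if (ok) best <- length(idx)
    }
    best
  }
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    sub <- tibble::tibble(ref_rank = sample(1:15, n),
                          qry_rank = sample(1:15, n))
    gap <- sample(c(3, 6, 25), 1)
    for (orient in c("+", "-")) {
      chain <- svpair:::best_chain(sub, orient, gap)
      expect_equal(length(chain),
                   oracle_best(sub$ref_rank, sub$qry_rank, orient, gap),
                   info = sprintf("rep %d orient %s gap %d", rep, orient, gap))
      # the returned chain itself satisfies the constraints
      rr <- sub$ref_rank[chain]
      qq <- sub$qry_rank[chain]
      if (length(chain) > 1) {
        expect_true(all(diff(rr) >= 1))
        d <- if (orient == "+") diff(qq) else -diff(qq)
        expect_true(all(d >= 1))
        expect_true(all(diff(rr) - 1 <= gap) && all(abs(diff(qq)) - 1 <= gap))
      }
    }
  }
})

test_that("block spans of one genome never overlap after greedy extraction", {
  pair <- tiny_pair(seed = 62, with_rearrangements = FALSE)
  shared <- intersect(pair$genes1$feature_id, pair$genes2$feature_id)
  pairs <- tibble::tibble(ref_gene = shared, qry_gene = shared)
  blocks <- chain_collinear_anchors(pairs, pair$genes1, pair$genes2)
  expect_gt(nrow(blocks), 0)
  # anchors used at most once
  used <- unlist(purrr::map(blocks$anchors, ~ .x$ref_gene))
  expect_false(any(duplicated(used)))
  for (chrom in unique(blocks$ref_chrom)) {
    expect_lte(sum(blocks$ref_end[blocks$ref_chrom == chrom] -
                     blocks$ref_start[blocks$ref_chrom == chrom]),
               nchar(pair$genome1[[chrom]]))
  }
})

test_that("an identity comparison classifies every block as collinear", {
  ref <- dplyr::bind_rows(genes_on("chr1", 12, prefix = "a"),
                          genes_on("chr2", 12, prefix = "b"))
  pairs <- tibble::tibble(ref_gene = ref$feature_id,
                          qry_gene = ref$feature_id)
  blocks <- chain_collinear_anchors(pairs, ref, ref)
  cls <- classify_block_rearrangements(blocks)
  expect_true(all(cls$blocks$block_class == "collinear"))
  expect_equal(nrow(cls$reciprocal), 0)
})

test_that("a planted reciprocal translocation yields two swapped translocated groups", {
  anc <- generate_ancestor(2, c(400000, 400000), n_genes = 120,
                           te_density = 0.02, seed = 63)
  # inversion placed well clear of the swapped tails so its block stays on
  # the expected chromosome pairing
  script <- dplyr::bind_rows(
    edit_ops("inversion", "chr1", 80000, 140000),
    edit_ops("deletion", "chr1", 180000, 180500),
    edit_ops("insertion", "chr2", 100000, payload_len = 400),
    edit_ops("reciprocal_translocation", "chr1", 260000, 260000,
             payload_len = 1, chrom2 = "chr2", pos2 = 290000))
  pair <- derive_pair(anc, edit_ops(), script)
  shared <- intersect(pair$genes1$feature_id, pair$genes2$feature_id)
  pairs <- tibble::tibble(ref_gene = shared, qry_gene = shared)
  blocks <- chain_collinear_anchors(pairs, pair$genes1, pair$genes2)
  cls <- classify_block_rearrangements(blocks)
  tr <- cls$blocks[cls$blocks$block_class == "translocated", ]
  expect_setequal(paste(tr$ref_chrom, tr$qry_chrom),
                  c("chr1 chr2", "chr2 chr1"))
  expect_equal(nrow(cls$reciprocal), 2)
  inv <- cls$blocks[cls$blocks$block_class == "inverted", ]
  expect_gte(nrow(inv), 1)
})

test_that("switch summary partitions bp and honours identity/flip/swap", {
  prof_a <- dplyr::bind_rows(
    mk_profile("chr1", n = 8, status = c("A", "A", "B", "B", "A", NA, "B", "A")),
    mk_profile("chr2", n = 6, status = c("B", "B", "A", "A", "B", "B")))
  blocks <- tibble::tibble(
    block_id = 1:2, ref_chrom = c("chr1", "chr2"),
    qry_chrom = c("chr1", "chr2"), orientation = c("+", "-"),
    n_anchors = 10L,
    ref_start = c(0L, 0L), ref_end = c(800000L, 600000L),
    qry_start = c(0L, 0L), qry_end = c(800000L, 600000L),
    anchors = list(NULL, NULL), block_class = "collinear")

  # identity: everything non-NA conserved
  sw_id <- compartment_switch_summary(blocks, prof_a, prof_a, step = 100000)
  expect_equal(sum(sw_id$totals$bp), 1400000)
  expect_equal(sw_id$totals$bp[sw_id$totals$class == "A_to_B"], 0)
  expect_equal(sw_id$totals$bp[sw_id$totals$class == "B_to_A"], 0)

  # global flip: zero conserved; switches cover all non-NA bp
  prof_b <- prof_a
  prof_b$status <- c("B", "A")[match(prof_a$status, c("A", "B"))]
  prof_b$value <- -prof_a$value
  sw_fl <- compartment_switch_summary(blocks, prof_a, prof_b, step = 100000)
  expect_equal(sw_fl$totals$bp[sw_fl$totals$class == "conserved"], 0)
  non_na <- sum(sw_fl$totals$bp) -
    sw_fl$totals$bp[sw_fl$totals$class == "NA"]
  expect_equal(sw_fl$totals$bp[sw_fl$totals$class == "A_to_B"] +
                 sw_fl$totals$bp[sw_fl$totals$class == "B_to_A"], non_na)

  # role swap exchanges the switch directions and keeps conserved bp
  sw_ab <- compartment_switch_summary(blocks, prof_a, prof_b, step = 100000)
  sw_ba <- compartment_switch_summary(blocks, prof_b, prof_a, step = 100000)
  get <- function(s, cl) s$totals$bp[s$totals$class == cl]
  expect_equal(get(sw_ab, "A_to_B"), get(sw_ba, "B_to_A"))
  expect_equal(get(sw_ab, "B_to_A"), get(sw_ba, "A_to_B"))
  expect_equal(get(sw_ab, "conserved"), get(sw_ba, "conserved"))

  # partition invariant on a randomized profile pair
  set.seed(64)
  prof_c <- prof_a
  prof_c$status <- sample(c("A", "B", NA), nrow(prof_c), replace = TRUE)
  sw_r <- compartment_switch_summary(blocks, prof_a, prof_c, step = 100000)
  expect_equal(sum(sw_r$totals$bp), 1400000)
})

test_that("short blocks fall back to a single midpoint sample", {
  prof <- mk_profile(n = 4, status = c("A", "B", "A", "B"))
  blk <- tibble::tibble(
    block_id = 1L, ref_chrom = "chr1", qry_chrom = "chr1",
    orientation = "+", n_anchors = 5L,
    ref_start = 110000L, ref_end = 150000L,
    qry_start = 110000L, qry_end = 150000L,
    anchors = list(NULL), block_class = "collinear")
  sw <- compartment_switch_summary(blk, prof, prof, step = 100000)
  expect_equal(sum(sw$totals$bp), 40000)
  expect_equal(sw$totals$bp[sw$totals$class == "conserved"], 40000)
})

test_that("gene-context windows are 2 kb with exact boundaries", {
  genes <- feature_tbl("chr1", 50000, 52000, feature_id = "g1")
  tes <- feature_tbl("chr1", 53500, 53900, kind = "TE", feature_id = "te1")
  sv_at <- function(s, e) mk_call("deletion", "chr1", s, e, size = 100)
  res <- gene_context_overlap(genes, sv_at(47900, 48100), tes)
  expect_true(res$genes$sv_affected)    # deletion reaches into the window
  res2 <- gene_context_overlap(genes, sv_at(47800, 47999), tes)
  expect_false(res2$genes$sv_affected)  # ends 2,001 bp upstream
  expect_true(res2$genes$te_present)    # TE 1.5 kb downstream
  expect_false(res2$genes$co_occurs)

  # insertion points count by position
  ins <- mk_call("insertion", "chr1", 53999, 53999, size = 400)
  expect_true(gene_context_overlap(genes, ins, tes)$genes$sv_affected)
  ins_far <- mk_call("insertion", "chr1", 54001, 54001, size = 400)
  expect_false(gene_context_overlap(genes, ins_far, tes)$genes$sv_affected)

  # no TEs anywhere: co_occurs is all FALSE
  none <- gene_context_overlap(genes, ins, tes[0, ])
  expect_false(none$genes$co_occurs)
  expect_equal(none$summary$n_sv_affected, 1)
})
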
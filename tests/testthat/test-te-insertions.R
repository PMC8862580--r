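# TE insertion rules: query gap strictly > 1000 bp, reference gap in [0, 100),
# merged TE cover strictly > 0.8, gene flank 500 bp inclusive.

te_fixture <- function(Q_gap, R_gap, cover) {
  blocks <- gap_blocks(R_gap = R_gap, Q_gap = Q_gap)
  qs <- blocks$qry_end[1]
  te_bp <- round(cover * Q_gap)
  tes <- if (te_bp > 0) {
    feature_tbl("chr1", qs, qs + te_bp, kind = "TE", feature_id = "te1")
  } else {
    feature_tbl("chr1", integer(0), integer(0), kind = "TE")
  }
  list(blocks = blocks, tes = tes)
}

test_that("the three TE-insertion rules apply with strict thresholds", {
  cfg <- sv_config()
  run <- function(Q, R, cover) {
    fx <- te_fixture(Q, R, cover)
    call_te_insertions(fx$blocks, fx$tes, cfg)
  }
  # all three rules satisfied
  res <- run(1500, 50, 0.9)
  expect_equal(nrow(res), 1)
  expect_true(res$is_te_insertion)
  expect_equal(res$qry_end - res$qry_start, 1500)
  expect_equal(res$ref_end - res$ref_start, 50)

  # query gap must strictly exceed 1000
  expect_equal(nrow(run(999, 50, 1.0)), 0)
  expect_equal(nrow(run(1000, 50, 1.0)), 0)
  expect_equal(nrow(run(1001, 50, 1.0)), 1)

  # reference gap strictly below 100 (and >= 0)
  expect_equal(nrow(run(1500, 120, 1.0)), 0)
  expect_equal(nrow(run(1500, 101, 1.0)), 0)
  expect_true(run(1500, 99, 1.0)$is_te_insertion)
  expect_true(run(1500, 0, 1.0)$is_te_insertion)   # clean insertion site
  expect_equal(nrow(run(1500, -10, 1.0)), 0)       # overlapping anchors

  # TE cover strictly above 0.8; candidate retained either way
  low <- run(2000, 50, 0.79)
  expect_false(low$is_te_insertion)
  expect_equal(low$te_overlap_frac, 0.79)
  high <- run(2000, 50, 0.81)
  expect_true(high$is_te_insertion)
})

test_that("overlapping TE annotations are merged before the cover test", {
  fx <- te_fixture(2000, 0, 0)
  qs <- fx$blocks$qry_end[1]
  # two annotations covering [0,1200) and [800,1700): union 1700/2000 = 0.85
  tes <- dplyr::bind_rows(
    feature_tbl("chr1", qs, qs + 1200, kind = "TE", feature_id = "a"),
    feature_tbl("chr1", qs + 800, qs + 1700, kind = "TE", feature_id = "b"))
  res <- call_te_insertions(fx$blocks, tes)
  expect_equal(res$te_overlap_frac, 0.85)
  expect_true(res$is_te_insertion)
  # double-counting would have claimed 2100/2000 > 1
  expect_lte(res$te_overlap_frac, 1)
})

test_that("call counts are monotone in each threshold", {
  pair <- tiny_pair(seed = 23)
  blocks <- simulate_alignment_blocks(pair, 0, seed = 5)
  anchors <- select_unique_anchors(blocks, sv_config(anchor_min_len = 3000))
  n_calls <- function(...) {
    cfg <- sv_config(anchor_min_len = 3000, ...)
    sum(call_te_insertions(anchors, pair$tes2, cfg)$is_te_insertion)
  }
  base <- n_calls()
  expect_gte(base, 1)
  expect_lte(n_calls(te_overlap_frac = 0.95), base)
  expect_lte(n_calls(te_ins_qry_gap_min = 2500), base)
  expect_lte(n_calls(te_ins_ref_gap_max = 1), base)
})

test_that("gene flank is inclusive at 500 bp, exclusive at 501", {
  cfg <- sv_config()
  mk_site <- function(pos) tibble::tibble(
    qry_chrom = "chr1", qry_start = 50000L, qry_end = 52000L,
    ref_chrom = "chr1", ref_start = as.integer(pos), ref_end = as.integer(pos),
    te_overlap_frac = 1, is_te_insertion = TRUE)
  gene <- feature_tbl("chr1", 10000, 12000, feature_id = "g1")
  dist_hit <- function(pos) {
    length(te_affected_genes(mk_site(pos), gene, cfg)$genes) == 1
  }
  expect_true(dist_hit(11000))            # inside the gene
  expect_true(dist_hit(12000 + 500 - 1))  # 500 bp past the gene end
  expect_false(dist_hit(12000 + 500))     # 501 bp away
  expect_true(dist_hit(10000 - 500))      # 500 bp before the start
  expect_false(dist_hit(10000 - 501))
})

test_that("planted TE insertions are recovered reciprocally, not doubly", {
  anc <- generate_ancestor(1, 200000, n_genes = 8, te_families = 2,
                           te_density = 0.05, seed = 24)
  script <- dplyr::bind_rows(
    edit_ops("te_insertion", "chr1", 60000, payload_len = 1500,
             te_family = names(anc$te_consensus)[1]),
    edit_ops("te_insertion", "chr1", 120000, payload_len = 2000,
             te_family = names(anc$te_consensus)[2]))
  pair <- derive_pair(anc, edit_ops(), script)
  cfg <- sv_config(anchor_min_len = 3000)
  blocks <- simulate_alignment_blocks(pair, 0, seed = 6)
  anchors <- select_unique_anchors(blocks, cfg)
  # forward direction: genome2 is the query and carries both insertions
  fwd <- call_te_insertions(anchors, pair$tes2, cfg)
  expect_equal(sum(fwd$is_te_insertion), 2)
  # swapped roles: genome1 as query carries none of them
  swapped <- anchors |>
    dplyr::rename(ref_chrom = qry_chrom, ref_start = qry_start,
                  ref_end = qry_end, qry_chrom = ref_chrom,
                  qry_start = ref_start, qry_end = ref_end) |>
    dplyr::arrange(ref_chrom, ref_start)
  rev <- call_te_insertions(swapped, pair$tes1, cfg)
  expect_equal(sum(rev$is_te_insertion), 0)
})
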
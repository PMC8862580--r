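test_that("unique-anchor selection keeps long blocks and resolves conflicts", {
  cfg <- sv_config()
  one <- mk_blocks(
    ~ref_chrom, ~ref_start, ~ref_end, ~qry_chrom, ~qry_start, ~qry_end, ~strand, ~pct_identity,
    "chr1", 0L, 50000L, "chrA", 0L, 50000L, "+", 99)
  expect_equal(nrow(select_unique_anchors(one, cfg)), 1)

  # two identical reference placements to different query spots: one kept
  two <- dplyr::bind_rows(one, dplyr::mutate(one, qry_start = 90000L,
                                             qry_end = 140000L))
  expect_equal(nrow(select_unique_anchors(two, cfg)), 1)

  # short block dropped by the length floor
  short <- dplyr::mutate(one, ref_end = 5000L, qry_end = 5000L)
  expect_equal(nrow(select_unique_anchors(short, cfg)), 0)

  expect_equal(nrow(select_unique_anchors(one[0, ], cfg)), 0)
})

test_that("gap classification matches its printed examples", {
  expect_equal(classify_gap(0, 2000), "insertion")
  expect_equal(classify_gap(300, 10), "deletion")
  expect_equal(classify_gap(-400, 100), "repeat_expansion")
  expect_equal(classify_gap(100, -400), "repeat_contraction")
  expect_equal(classify_gap(-400, -100), "tandem_expansion")
  expect_equal(classify_gap(-100, -400), "tandem_contraction")
  expect_true(is.na(classify_gap(0, 30)))           # below the 50 bp floor
  expect_true(is.na(classify_gap(0, 200000)))       # above the size cap
  expect_true(is.na(classify_gap(150000, 151000)))  # raw gap too large
})

test_that("gap classification agrees with an exhaustive case-table oracle", {
  # independent oracle: literal transcription of the sign/size rule table
  oracle <- function(R, Q, min_sv = 50, max_sv = 100000) {
    d <- Q - R
    if (abs(d) < min_sv || abs(d) > max_sv || max(R, Q) > max_sv) {
      return(NA_character_)
    }
    if (R >= 0 && Q >= 0) {
      if (d > 0) return("insertion") else return("deletion")
    }
    if (R < 0 && Q >= 0) return("repeat_expansion")
    if (R >= 0 && Q < 0) return("repeat_contraction")
    if (d > 0) return("tandem_expansion")
    "tandem_contraction"
  }
  grid <- expand.grid(R = seq(-5000, 5000, by = 37),
                      Q = seq(-5000, 5000, by = 37))
  got <- classify_gap(grid$R, grid$Q)
  want <- mapply(oracle, grid$R, grid$Q)
  expect_identical(unname(got), unname(want))
})

test_that("gap calls carry the documented intervals and PAV flags", {
  cfg <- sv_config(anchor_min_len = 10000)
  # pure insertion: zero-length reference interval at the junction
  b <- gap_blocks(R_gap = 0, Q_gap = 2000)
  calls <- call_svs(select_unique_anchors(b, cfg), cfg)
  expect_equal(calls$sv_type, "insertion")
  expect_true(calls$is_pav)
  expect_equal(calls$ref_start, calls$ref_end)
  expect_equal(calls$qry_end - calls$qry_start, 2000)

  # deletion: reference interval spans the gap, query side is a point
  b <- gap_blocks(R_gap = 1500, Q_gap = 0)
  calls <- call_svs(select_unique_anchors(b, cfg), cfg)
  expect_equal(calls$sv_type, "deletion")
  expect_equal(calls$ref_end - calls$ref_start, 1500)
  expect_equal(calls$qry_start, calls$qry_end)

  # no-edit pair yields zero calls
  anc <- generate_ancestor(1, 80000, n_genes = 3, seed = 41)
  id <- derive_pair(anc, edit_ops(), edit_ops())
  blocks <- simulate_alignment_blocks(id, 0, seed = 1)
  expect_equal(nrow(call_svs(select_unique_anchors(
    blocks, sv_config(anchor_min_len = 5000)))), 0)
})

test_that("minus-strand anchor runs use strand-aware query gaps", {
  # inverted segment with an insertion inside it: query runs descending
  b <- tibble::tibble(
    ref_chrom = "chr1", ref_start = c(0L, 20000L),
    ref_end = c(20000L, 40000L),
    qry_chrom = "chr1",
    qry_start = c(22000L, 0L), qry_end = c(42000L, 20000L),
    strand = "-", pct_identity = 99, is_unique_anchor = NA)
  calls <- call_svs(select_unique_anchors(b, sv_config()))
  expect_equal(calls$sv_type, "insertion")
  expect_equal(calls$size, 2000L)
})

test_that("planted SVs of every gap class are recovered exactly at zero jitter", {
  pair <- tiny_pair(seed = 17)
  blocks <- simulate_alignment_blocks(pair, 0, seed = 2)
  expected <- attr(blocks, "expected_calls")
  cfg <- sv_config(anchor_min_len = 3000)
  calls <- call_svs(select_unique_anchors(blocks, cfg), cfg)
  expect_equal(nrow(calls), nrow(expected))
  key <- function(x) paste(x$sv_type, x$ref_chrom, x$ref_start, x$ref_end,
                           x$qry_chrom, x$qry_start, x$qry_end, x$size)
  expect_setequal(key(calls), key(expected))
})

test_that("inversions and translocations are detected from anchor layout", {
  pair <- tiny_pair(seed = 18)
  blocks <- simulate_alignment_blocks(pair, 0, seed = 2)
  anchors <- select_unique_anchors(blocks, sv_config(anchor_min_len = 3000))
  rearr <- detect_inversions_and_translocations(anchors)
  tr <- pair$truth

  inv_truth <- tr[tr$op_type == "inversion", ]
  inv_call <- rearr[rearr$sv_type == "inversion", ]
  expect_equal(nrow(inv_call), 1)
  expect_equal(inv_call$ref_start, inv_truth$g1_start)
  expect_equal(inv_call$ref_end, inv_truth$g1_end)

  tl <- rearr[rearr$sv_type == "translocation", ]
  expect_equal(nrow(tl), 2)
  expect_setequal(paste(tl$ref_chrom, tl$qry_chrom),
                  c("chr1 chr2", "chr2 chr1"))

  # collinear pair: no rearrangement calls
  anc <- generate_ancestor(1, 80000, n_genes = 3, seed = 42)
  id <- derive_pair(anc, edit_ops(), edit_ops())
  b0 <- simulate_alignment_blocks(id, 0, seed = 1)
  expect_equal(nrow(detect_inversions_and_translocations(b0)), 0)
})

test_that("context annotation follows the priority and flank rules", {
  cfg <- sv_config()
  genes <- feature_tbl("chr1", 20000, 24000, strand = "+", kind = "gene",
                       feature_id = "g1")
  exons <- dplyr::bind_rows(
    feature_tbl("chr1", 20000, 21000, kind = "exon", feature_id = "g1.e1",
                attrs = "Parent=g1"),
    feature_tbl("chr1", 23000, 24000, kind = "exon", feature_id = "g1.e2",
                attrs = "Parent=g1"))
  ann <- function(type, s, e) {
    call <- mk_call(type, "chr1", s, e, size = max(50, e - s))
    out <- annotate_sv_context(call, genes, exons, cfg, side = "ref")
    c(out$context, out$impact)
  }
  # whole-gene deletion: ablation, high impact
  expect_equal(ann("deletion", 19000, 25000), c("transcript_ablation", "high"))
  # exon overlap beats everything below it
  expect_equal(ann("deletion", 20500, 21500), c("exon", "high"))
  # inside the intron, clear of both 2 bp splice regions
  expect_equal(ann("deletion", 21100, 21200), c("intron", "modifier"))
  # touching the first 2 bp of the intron
  expect_equal(ann("deletion", 21000, 21002), c("splice_site", "high"))
  expect_equal(ann("deletion", 22998, 23000), c("splice_site", "high"))
  # intergenic far away
  expect_equal(ann("deletion", 100000, 100100), c("intergenic", "modifier"))

  # insertion point 4,999 bp 5' of the gene start: upstream (5 kb window)
  ins <- mk_call("insertion", "chr1", 20000 - 4999, 20000 - 4999, size = 300)
  out <- annotate_sv_context(ins, genes, exons, cfg, side = "qry") # untouched
  expect_true(is.na(out$context))
  ins$qry_chrom <- "chr1"; ins$qry_start <- ins$ref_start
  ins$qry_end <- ins$ref_end
  out <- annotate_sv_context(ins, genes, exons, cfg, side = "qry")
  expect_equal(out$context, "upstream")
  # 5,001 bp away: intergenic
  ins2 <- ins
  ins2$qry_start <- ins2$qry_end <- 20000L - 5001L
  expect_equal(annotate_sv_context(ins2, genes, exons, cfg,
                                   side = "qry")$context, "intergenic")
  # downstream of a - strand gene mirrors upstream
  gneg <- dplyr::mutate(genes, strand = "-")
  expect_equal(annotate_sv_context(ins, gneg, exons, cfg,
                                   side = "qry")$context, "downstream")
})

test_that("every annotated call gets exactly one context and impact", {
  pair <- tiny_pair(seed = 19)
  blocks <- simulate_alignment_blocks(pair, 0, seed = 3)
  cfg <- sv_config(anchor_min_len = 3000)
  calls <- call_svs(select_unique_anchors(blocks, cfg), cfg)
  calls <- annotate_sv_context(calls, pair$genes1, pair$exons1, cfg, "ref")
  calls <- annotate_sv_context(calls, pair$genes2, pair$exons2, cfg, "qry")
  expect_false(any(is.na(calls$context)))
  expect_true(all(calls$context %in% svpair:::sv_contexts()))
  expect_true(all(calls$impact %in% c("high", "modifier")))
  high <- calls$context %in% c("transcript_ablation", "exon", "splice_site")
  expect_equal(calls$impact, ifelse(high, "high", "modifier"))
})
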
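# TE insertion detection over a reciprocal whole-genome comparison: an
# insertion is an anchor gap of > 1 kb in the query facing < 100 bp in the
# reference, and it is a TE insertion when > 80 % of the inserted query
# sequence is TE-annotated. The (possibly zero-length) reference gap is the
# TE insertion site; genes within 500 bp of a site are TE-affected.

#' Call TE insertions from unique anchors
#'
#' Scans anchor gap pairs: a candidate insertion has a query gap strictly
#' greater than `te_ins_qry_gap_min` (1000 bp) and a reference gap of at least
#' zero and strictly below `te_ins_ref_gap_max` (100 bp). A candidate is a TE
#' insertion when the merged TE-annotated bp of the inserted query interval
#' strictly exceed `te_overlap_frac` (0.8) of its length; overlapping TE
#' annotations are counted once.
#'
#' @param anchors Output of [select_unique_anchors()] for the comparison whose
#'   query is the genome under test.
#' @param te_annot TE feature tibble on the query genome.
#' @param cfg An [sv_config()].
#' @return Tibble of TE insertion calls: `qry_chrom`, `qry_start`, `qry_end`
#'   (inserted interval), `ref_chrom`, `ref_start`, `ref_end` (insertion
#'   site), `te_overlap_frac`, `is_te_insertion` (`FALSE` rows are candidates
#'   failing only the TE-cover rule).
#' @export
call_te_insertions <- function(anchors, te_annot, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  gp <- gap_pairs(anchors)
  empty <- tibble::tibble(
    qry_chrom = character(), qry_start = integer(), qry_end = integer(),
    ref_chrom = character(), ref_start = integer(), ref_end = integer(),
    te_overlap_frac = double(), is_te_insertion = logical())
  if (is.null(gp) || !nrow(gp)) return(empty)
  cand <- gp[gp$Q_gap > cfg$te_ins_qry_gap_min &
               gp$R_gap >= 0 & gp$R_gap < cfg$te_ins_ref_gap_max, ]
  if (!nrow(cand)) return(empty)
  rows <- purrr::map(seq_len(nrow(cand)), function(i) {
    x <- cand[i, ]
    if (x$strand == "+") {
      qs <- x$l_qry_end; qe <- x$r_qry_start
    } else {
      qs <- x$r_qry_end; qe <- x$l_qry_start
    }
    te <- te_annot[te_annot$chrom == x$qry_chrom & te_annot$kind == "TE", ]
    cover <- if (nrow(te)) {
      merged_cover_bp(te$start, te$end, qs, qe) / (qe - qs)
    } else 0
    tibble::tibble(
      qry_chrom = x$qry_chrom, qry_start = qs, qry_end = qe,
      ref_chrom = x$ref_chrom, ref_start = x$l_ref_end,
      ref_end = x$r_ref_start,
      te_overlap_frac = cover,
      is_te_insertion = cover > cfg$te_overlap_frac)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$qry_chrom, .data$qry_start)
}

#' TE-affected genes around TE insertion sites
#'
#' A gene is TE-affected when a TE insertion site lies in the gene or within
#' `te_gene_flank` (500 bp) of it; the flank is inclusive, so a site exactly
#' 500 bp away still qualifies. Zero-length sites are treated as points.
#'
#' @param calls Output of [call_te_insertions()] (only rows with
#'   `is_te_insertion = TRUE` are used).
#' @param genes Gene feature tibble of the genome carrying the insertion
#'   sites (the reference of the comparison).
#' @param cfg An [sv_config()].
#' @return List with `per_call` (tibble: one row per TE insertion, list-column
#'   `affected_genes`) and `genes` (sorted, deduplicated union of gene ids).
#' @export
te_affected_genes <- function(calls, genes, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  calls <- calls[calls$is_te_insertion, , drop = FALSE]
  per_call <- purrr::map(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    g <- genes[genes$chrom == x$ref_chrom, ]
    if (!nrow(g)) return(character(0))
    hit <- interval_hits(x$ref_start, x$ref_end,
                         g$start - cfg$te_gene_flank,
                         g$end + cfg$te_gene_flank)
    sort(g$feature_id[hit])
  })
  out <- calls
  out$affected_genes <- per_call
  list(per_call = out,
       genes = sort(unique(unlist(per_call))))
}
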
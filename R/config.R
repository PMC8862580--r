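#' Pipeline configuration
#'
#' Bundles every tunable threshold of the comparison pipeline in one place so
#' a run is auditable from a single object. Defaults follow the published
#' comparison protocol for a diverged within-species genome pair: SVs between
#' 50 bp and 100 kb, TE insertions defined by a > 1000 bp query gap facing a
#' < 100 bp reference gap with > 80 % TE annotation cover, a 500 bp genic
#' flank for TE-affected genes, a 5 kb upstream/downstream annotation window,
#' 2 bp splice regions, a 2 kb gene-context window, 100 kb Hi-C bins, a
#' 1 kb breakpoint merge distance and a 3-read support floor for short-read
#' calls.
#'
#' @param min_sv_size Minimum emitted SV size in bp.
#' @param max_sv_size Maximum emitted SV size in bp; also bounds each raw gap.
#' @param anchor_min_len Minimum reference span of a unique alignment anchor (bp).
#' @param te_ins_qry_gap_min Query gap must strictly exceed this (bp) for a
#'   candidate TE insertion.
#' @param te_ins_ref_gap_max Reference gap must be strictly below this (bp).
#' @param te_overlap_frac Inserted query sequence must be TE-annotated over
#'   strictly more than this fraction of its length.
#' @param te_gene_flank Genic flank (bp) within which a TE insertion site marks
#'   a gene as TE-affected (distance <= flank qualifies).
#' @param updown_flank Upstream/downstream annotation window (bp).
#' @param splice_bp Width (bp) of the splice region at each intron end.
#' @param gene_context_flank Flank (bp) added to genes for SV/TE co-occurrence.
#' @param bin_size Hi-C bin size (bp).
#' @param merge_dist Maximum breakpoint distance (bp) for merging calls.
#' @param min_support_reads Minimum summed read support across samples.
#' @param recip_overlap Minimum reciprocal overlap for deletion concordance.
#' @param ins_point_tol Maximum insertion-point distance (bp) for concordance.
#'
#' @return A list of class `sv_config`.
#' @examples
#' cfg <- sv_config(anchor_min_len = 5000)
#' cfg$min_sv_size
#' @export
sv_config <- function(min_sv_size = 50,
                      max_sv_size = 100000,
                      anchor_min_len = 10000,
                      te_ins_qry_gap_min = 1000,
                      te_ins_ref_gap_max = 100,
                      te_overlap_frac = 0.8,
                      te_gene_flank = 500,
                      updown_flank = 5000,
                      splice_bp = 2,
                      gene_context_flank = 2000,
                      bin_size = 100000,
                      merge_dist = 1000,
                      min_support_reads = 3,
                      recip_overlap = 0.5,
                      ins_point_tol = 500) {
  cfg <- list(
    min_sv_size = min_sv_size, max_sv_size = max_sv_size,
    anchor_min_len = anchor_min_len,
    te_ins_qry_gap_min = te_ins_qry_gap_min,
    te_ins_ref_gap_max = te_ins_ref_gap_max,
    te_overlap_frac = te_overlap_frac,
    te_gene_flank = te_gene_flank,
    updown_flank = updown_flank,
    splice_bp = splice_bp,
    gene_context_flank = gene_context_flank,
    bin_size = bin_size,
    merge_dist = merge_dist,
    min_support_reads = min_support_reads,
    recip_overlap = recip_overlap,
    ins_point_tol = ins_point_tol
  )
  scalars <- setdiff(names(cfg), c("te_overlap_frac", "recip_overlap"))
  for (nm in scalars) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0) {
      stop("config field `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  for (nm in c("te_overlap_frac", "recip_overlap")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1) {
      stop("config field `", nm, "` must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(cfg, class = "sv_config")
}

#' @export
print.sv_config <- function(x, ...) {
  cat("<sv_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_sv_config <- function(cfg) {
  if (inherits(cfg, "sv_config")) return(cfg)
  if (is.null(cfg)) return(sv_config())
  do.call(sv_config, cfg[intersect(names(cfg), names(formals(sv_config)))])
}
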
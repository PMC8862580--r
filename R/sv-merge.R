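# Merging of SV call sets across callers/samples (SURVIVOR-style
# single-linkage within type), the published retention filters, and
# concordance of alignment-based PAVs with short-read calls.

#' Merge SV call sets
#'
#' Calls merge when they share `sv_type` and chromosome and both breakpoints
#' lie within `merge_dist` (default 1000 bp); clustering is single-linkage
#' within each type. A merged call takes the coordinate median of its
#' members, per-sample support summed across members, and the worst filter
#' status (any non-PASS member taints the cluster). The operation is
#' idempotent and invariant to the order of the input call sets.
#'
#' @param callsets A list of SV call tibbles (or a single tibble).
#' @param cfg An [sv_config()].
#' @return Merged SV call tibble, ordered by position, `source = "merged"`.
#' @export
merge_callsets <- function(callsets, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  if (is.data.frame(callsets)) callsets <- list(callsets)
  all_calls <- dplyr::bind_rows(purrr::map(callsets, complete_sv_calls))
  if (!nrow(all_calls)) return(empty_sv_calls())
  # exact duplicate records are one observation seen twice, not extra support
  key <- paste(all_calls$sv_type, all_calls$ref_chrom, all_calls$ref_start,
               all_calls$ref_end, all_calls$size, all_calls$filter_status,
               vapply(all_calls$support, encode_support, ""))
  all_calls <- all_calls[!duplicated(key), ]
  groups <- split(seq_len(nrow(all_calls)),
                  paste(all_calls$sv_type, all_calls$ref_chrom))
  merged <- list()
  for (idx in groups) {
    sub <- all_calls[idx, ]
    o <- order(sub$ref_start, sub$ref_end)
    sub <- sub[o, ]
    n <- nrow(sub)
    # single-linkage via union-find; candidates limited by sorted starts
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (i in seq_len(n)) {
      j <- i + 1L
      while (j <= n && sub$ref_start[j] - sub$ref_start[i] <= cfg$merge_dist) {
        if (abs(sub$ref_end[j] - sub$ref_end[i]) <= cfg$merge_dist) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
        j <- j + 1L
      }
    }
    roots <- vapply(seq_len(n), find, 1L)
    for (r in unique(roots)) {
      mem <- sub[roots == r, ]
      sup_all <- unlist(mem$support)
      sup <- if (length(sup_all)) {
        tapply(sup_all, names(sup_all), sum)
      } else {
        integer()
      }
      sup <- stats::setNames(as.integer(sup), names(sup))
      filt <- if (all(mem$filter_status == "PASS", na.rm = TRUE) &&
                    !anyNA(mem$filter_status)) {
        "PASS"
      } else {
        worst <- mem$filter_status[is.na(mem$filter_status) |
                                     mem$filter_status != "PASS"]
        worst <- worst[!is.na(worst)]
        if (length(worst)) sort(worst)[1] else "LowQual"
      }
      merged[[length(merged) + 1L]] <- tibble::tibble(
        sv_type = mem$sv_type[1],
        ref_chrom = mem$ref_chrom[1],
        ref_start = as.integer(floor(stats::median(mem$ref_start))),
        ref_end = as.integer(floor(stats::median(mem$ref_end))),
        qry_chrom = mem$qry_chrom[1],
        qry_start = mem$qry_start[1], qry_end = mem$qry_end[1],
        size = as.integer(floor(stats::median(mem$size))),
        source = "merged",
        support = list(sup),
        filter_status = filt,
        is_pav = any(mem$is_pav, na.rm = TRUE),
        context = NA_character_, impact = NA_character_)
    }
  }
  out <- dplyr::bind_rows(merged)
  dplyr::arrange(out, .data$ref_chrom, .data$ref_start, .data$ref_end,
                 .data$sv_type)
}

#' Apply the retention filters to merged calls
#'
#' Keeps calls with summed read support across samples of at least
#' `min_support_reads` (3), size of at least `min_sv_size` (50 bp), and
#' `filter_status == "PASS"`.
#'
#' @param calls Merged SV call tibble.
#' @param cfg An [sv_config()].
#' @return The retained subset.
#' @export
filter_merged <- function(calls, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  if (!nrow(calls)) return(calls)
  total_sup <- vapply(calls$support, function(s) sum(unlist(s)), 1)
  keep <- total_sup >= cfg$min_support_reads &
    calls$size >= cfg$min_sv_size &
    !is.na(calls$filter_status) & calls$filter_status == "PASS"
  calls[keep, , drop = FALSE]
}

#' Concordance of alignment-based PAVs with short-read calls
#'
#' A whole-genome-alignment deletion is confirmed when some short-read
#' deletion on the same chromosome has reciprocal overlap of at least
#' `recip_overlap` (0.5); an alignment insertion is confirmed when some
#' short-read insertion point lies within `ins_point_tol` (500 bp) of its
#' reference-side insertion point.
#'
#' @param wga_pavs PAV calls (insertions/deletions) from the alignment route,
#'   with reference-side coordinates.
#' @param sr_calls Short-read calls (e.g. merged and filtered).
#' @param cfg An [sv_config()].
#' @return List with `fraction` (confirmed / total; `NA` for an empty PAV
#'   set) and `calls` (input PAVs plus a `confirmed` flag).
#' @export
pav_concordance <- function(wga_pavs, sr_calls, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  wga_pavs <- wga_pavs[wga_pavs$sv_type %in% c("insertion", "deletion"), ,
                       drop = FALSE]
  if (!nrow(wga_pavs)) {
    wga_pavs$confirmed <- logical(0)
    return(list(fraction = NA_real_, calls = wga_pavs))
  }
  confirmed <- logical(nrow(wga_pavs))
  sr_del <- sr_calls[sr_calls$sv_type == "deletion", ]
  sr_ins <- sr_calls[sr_calls$sv_type == "insertion", ]
  for (i in seq_len(nrow(wga_pavs))) {
    w <- wga_pavs[i, ]
    if (w$sv_type == "deletion") {
      s <- sr_del[sr_del$ref_chrom == w$ref_chrom, ]
      if (nrow(s)) {
        ov <- interval_overlap_bp(w$ref_start, w$ref_end,
                                  s$ref_start, s$ref_end)
        len_w <- w$ref_end - w$ref_start
        len_s <- s$ref_end - s$ref_start
        confirmed[i] <- any(len_w > 0 & len_s > 0 &
                              ov >= cfg$recip_overlap * len_w &
                              ov >= cfg$recip_overlap * len_s)
      }
    } else {
      s <- sr_ins[sr_ins$ref_chrom == w$ref_chrom, ]
      if (nrow(s)) {
        confirmed[i] <- any(abs(s$ref_start - w$ref_start) <=
                              cfg$ins_point_tol)
      }
    }
  }
  wga_pavs$confirmed <- confirmed
  list(fraction = mean(confirmed), calls = wga_pavs)
}
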
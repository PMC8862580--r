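#' Simulate short-read SV call sets from the planted truth
#'
#' Stands in for two read-based SV callers run on a population sample: every
#' liftable presence/absence variant in the truth table is emitted once per
#' pseudo-caller with per-sample Poisson read support and uniform breakpoint
#' jitter, plus `fp_count` false calls placed uniformly with a random filter
#' status. The default of 10 samples mirrors a typical resequencing panel of
#' ten individuals.
#'
#' @param pair A `genome_pair` from [derive_pair()].
#' @param target_genome Coordinate system of the calls: `1` (reference) or `2`.
#' @param n_samples Number of sequenced individuals.
#' @param support_rate Mean supporting reads per sample per true SV.
#' @param fp_count Number of false-positive calls per caller.
#' @param jitter Maximum uniform breakpoint jitter (bp).
#' @param seed Integer seed.
#' @return A list of two SV call tibbles (one per pseudo-caller).
#' @export
simulate_short_read_callset <- function(pair, target_genome = 1,
                                        n_samples = 10, support_rate = 5,
                                        fp_count = 0, jitter = 0, seed = 1) {
  stopifnot(inherits(pair, "genome_pair"))
  truth <- pair$truth
  pav <- truth[truth$op_type %in% c("insertion", "te_insertion", "deletion"), ]
  pav <- pav[pav$g1_liftable & pav$g2_liftable, ]
  g <- if (target_genome == 1) "g1" else "g2"
  lens <- nchar(if (target_genome == 1) pair$genome1 else pair$genome2)
  samples <- paste0("s", seq_len(n_samples))
  withr::with_seed(seed, {
    callers <- purrr::map(c("callerA", "callerB"), function(cl) {
      rows <- purrr::map(seq_len(nrow(pav)), function(i) {
        op <- pav[i, ]
        # type in the target genome's frame: sequence present there or not
        gains <- op$op_type %in% c("insertion", "te_insertion")
        type <- if ((op$genome == target_genome) == gains) "deletion" else "insertion"
        # the deleted sequence spans an interval in the target genome only
        # when the target genome carries it
        s <- op[[paste0(g, "_start")]]
        e <- op[[paste0(g, "_end")]]
        if (type == "insertion") e <- s
        j1 <- if (jitter > 0) sample(-jitter:jitter, 1) else 0L
        j2 <- if (jitter > 0) sample(-jitter:jitter, 1) else 0L
        s2 <- max(0L, s + j1)
        e2 <- if (type == "deletion") max(s2 + 1L, e + j2) else s2
        sup <- stats::rpois(n_samples, support_rate)
        names(sup) <- samples
        tibble::tibble(
          sv_type = type, ref_chrom = op[[paste0(g, "_chrom")]],
          ref_start = s2, ref_end = e2,
          size = op$payload_len, source = "short_read",
          support = list(sup), filter_status = "PASS",
          is_pav = TRUE)
      })
      calls <- dplyr::bind_rows(rows)
      if (fp_count > 0) {
        fp <- purrr::map(seq_len(fp_count), function(i) {
          chrom <- sample(names(lens), 1)
          type <- sample(c("deletion", "insertion"), 1)
          sz <- sample(50:5000, 1)
          s <- sample.int(max(1L, lens[[chrom]] - sz), 1) - 1L
          sup <- stats::rpois(n_samples, support_rate / 2)
          names(sup) <- samples
          tibble::tibble(
            sv_type = type, ref_chrom = chrom, ref_start = s,
            ref_end = if (type == "deletion") s + sz else s,
            size = sz, source = "short_read", support = list(sup),
            filter_status = sample(c("PASS", "LowQual"), 1), is_pav = TRUE)
        })
        calls <- dplyr::bind_rows(calls, dplyr::bind_rows(fp))
      }
      calls <- complete_sv_calls(calls)
      calls$source <- "short_read"
      dplyr::arrange(calls, .data$ref_chrom, .data$ref_start)
    })
  })
  names(callers) <- c("callerA", "callerB")
  callers
}
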
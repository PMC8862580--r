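#' Hi-C simulation parameters
#'
#' Parameters of the plaid Poisson contact model: the expected count between
#' bins i and j (i != j) is `s_i * s_j * base_c * (|i-j|+1)^(-alpha) *
#' (1 + delta * c_i * c_j)`, where `c` is the planted per-bin compartment sign
#' and `s` are log-normal bin visibilities; the diagonal mean is
#' `s_i^2 * base_c`.
#'
#' @param alpha Distance-decay exponent (> 0).
#' @param delta Plaid (compartment) strength in `[0, 1)`.
#' @param base_c Expected near-diagonal count (> 0). The default of 500 is in
#'   the range seen for deeply sequenced plant Hi-C at 100 kb bins.
#' @param visibility_sd Log-scale spread of multiplicative bin visibilities.
#' @param seed Integer seed.
#' @return A list of class `hic_sim_params`.
#' @export
hic_sim_params <- function(alpha = 1, delta = 0.4, base_c = 500,
                           visibility_sd = 0, seed = 1) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (delta < 0 || delta >= 1) {
    stop("delta must lie in [0, 1): delta >= 1 gives negative means",
         call. = FALSE)
  }
  if (base_c <= 0) stop("base_c must be > 0", call. = FALSE)
  if (visibility_sd < 0) stop("visibility_sd must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, delta = delta, base_c = base_c,
                 visibility_sd = visibility_sd, seed = seed),
            class = "hic_sim_params")
}

#' Simulate a plaid Hi-C contact matrix with planted compartments
#'
#' Draws a symmetric Poisson contact matrix under the plaid model of
#' [hic_sim_params()]. When no compartment truth is supplied, the per-bin
#' signs are drawn as alternating blocks of geometric length (mean 10 bins),
#' emulating the megabase-scale A/B alternation of real chromosomes. With
#' `poisson_noise = FALSE` the noise-free expected-value matrix is returned,
#' which the compartment caller must recover exactly (up to global sign).
#'
#' @param chrom_len Chromosome length in bp.
#' @param bin_size Bin size in bp; a final partial bin is kept but masked when
#'   shorter than half a bin.
#' @param params A `hic_sim_params` object.
#' @param compartment_truth Optional per-bin vector over `{-1, +1}`.
#' @param poisson_noise If `FALSE`, return expected values instead of draws.
#' @param chrom Chromosome name for the record.
#' @return List with `matrix` (a `contact_matrix`) and `truth` (the per-bin
#'   sign vector actually used).
#' @export
simulate_contact_matrix <- function(chrom_len, bin_size = 100000,
                                    params = hic_sim_params(),
                                    compartment_truth = NULL,
                                    poisson_noise = TRUE,
                                    chrom = "chr1") {
  stopifnot(inherits(params, "hic_sim_params"))
  n_full <- chrom_len %/% bin_size
  rem <- chrom_len - n_full * bin_size
  n <- n_full + (rem > 0)
  mask <- rep(TRUE, n)
  if (rem > 0 && rem < bin_size / 2) mask[n] <- FALSE
  withr::with_seed(params$seed, {
    if (is.null(compartment_truth)) {
      cvec <- integer(0)
      sign <- sample(c(-1L, 1L), 1)
      while (length(cvec) < n) {
        run <- 1L + stats::rgeom(1, 1 / 10)
        cvec <- c(cvec, rep(sign, run))
        sign <- -sign
      }
      cvec <- cvec[seq_len(n)]
    } else {
      stopifnot(length(compartment_truth) == n,
                all(compartment_truth %in% c(-1L, 1L)))
      cvec <- as.integer(compartment_truth)
    }
    s <- if (params$visibility_sd > 0) {
      exp(stats::rnorm(n, 0, params$visibility_sd))
    } else {
      rep(1, n)
    }
    dist <- abs(outer(seq_len(n), seq_len(n), "-"))
    mu <- outer(s, s) * params$base_c * (dist + 1) ^ (-params$alpha) *
      (1 + params$delta * outer(cvec, cvec))
    diag(mu) <- s ^ 2 * params$base_c
    if (poisson_noise) {
      counts <- matrix(0, n, n)
      ut <- upper.tri(counts, diag = TRUE)
      counts[ut] <- stats::rpois(sum(ut), mu[ut])
      counts <- counts + t(counts) - diag(diag(counts))
    } else {
      counts <- mu
    }
  })
  list(matrix = contact_matrix(chrom, counts, bin_size, mask), truth = cvec)
}

#' Plant compartment-status switches into a truth vector
#'
#' Flips the sign of contiguous runs of bins (geometric run length, mean 5
#' bins) until roughly `frac` of the bins have switched, emulating the
#' compartment divergence accumulated between two ecotypes.
#'
#' @param truth Integer vector over `{-1, +1}`.
#' @param frac Target fraction of switched bins.
#' @param run_mean Mean run length of a switched stretch (bins).
#' @param seed Integer seed.
#' @return The switched vector.
#' @export
plant_switches <- function(truth, frac, run_mean = 5, seed = 1) {
  n <- length(truth)
  target <- round(frac * n)
  withr::with_seed(seed, {
    flipped <- logical(n)
    guard <- 0L
    while (sum(flipped) < target && guard < 100L * n) {
      guard <- guard + 1L
      start <- sample.int(n, 1)
      len <- 1L + stats::rgeom(1, 1 / run_mean)
      idx <- start:min(n, start + len - 1L)
      idx <- idx[!flipped[idx]]
      idx <- utils::head(idx, target - sum(flipped))
      flipped[idx] <- TRUE
    }
    truth[flipped] <- -truth[flipped]
  })
  truth
}

#' Lift a per-bin compartment truth vector through a simulator segment map
#'
#' Assigns each derived-genome bin the ancestor compartment sign at its bin
#' midpoint; bins whose midpoint falls in inserted sequence inherit the
#' nearest mapped neighbour's sign.
#'
#' @param map Segment map (`map1`/`map2` from [derive_pair()]).
#' @param anc_truth Named list of per-chromosome ancestor sign vectors.
#' @param der_chrom Derived chromosome name.
#' @param der_len Derived chromosome length (bp).
#' @param bin_size Bin size (bp).
#' @return Integer vector over `{-1, +1}` for the derived chromosome's bins.
#' @export
lift_compartment_truth <- function(map, anc_truth, der_chrom, der_len,
                                   bin_size = 100000) {
  n <- ceiling(der_len / bin_size)
  out <- integer(n)
  for (b in seq_len(n)) {
    mid <- min((b - 1) * bin_size + bin_size %/% 2, der_len - 1)
    anc <- lift_derived_to_ancestor(map, der_chrom, mid)
    if (!is.na(anc$pos)) {
      v <- anc_truth[[anc$chrom]]
      out[b] <- v[min(length(v), anc$pos %/% bin_size + 1L)]
    } else {
      out[b] <- NA_integer_
    }
  }
  # fill inserted-bin gaps from the nearest assigned neighbour
  if (anyNA(out)) {
    idx <- which(!is.na(out))
    if (!length(idx)) stop("no mapped bins on ", der_chrom, call. = FALSE)
    for (b in which(is.na(out))) {
      out[b] <- out[idx[which.min(abs(idx - b))]]
    }
  }
  out
}
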
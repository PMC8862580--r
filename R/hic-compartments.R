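# A/B compartment calling: observed/expected normalization, Pearson
# correlation across bins, and the sign of the leading eigenvector (PC1).
# Positive entries (after orientation) are compartment A, negative B.

#' Observed/expected normalization of a contact matrix
#'
#' Masks bins whose marginal sum is below 5 % of the median marginal, then
#' divides each entry by the mean contact at its genomic distance (computed
#' over unmasked bins). Diagonals with zero mean are left at 0. This removes
#' the distance decay so the remaining structure reflects the compartment
#' plaid.
#'
#' @param m A `contact_matrix`.
#' @return List with `oe` (dense O/E matrix, masked rows/cols zeroed) and
#'   `mask` (logical, usable bins).
#' @export
normalize_oe <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  counts <- m$counts
  n <- m$n_bins
  marg <- rowSums(counts)
  mask <- m$bin_mask & marg > 0 & marg >= 0.05 * stats::median(marg)
  if (!any(mask)) stop("matrix too sparse: all bins masked", call. = FALSE)
  oe <- matrix(0, n, n)
  idx <- which(mask)
  sub <- counts[idx, idx, drop = FALSE]
  k <- abs(outer(idx, idx, "-"))
  for (d in unique(as.vector(k))) {
    sel <- k == d
    mu <- mean(sub[sel])
    if (mu > 0) sub[sel] <- sub[sel] / mu else sub[sel] <- 0
  }
  oe[idx, idx] <- sub
  list(oe = oe, mask = mask)
}

# leading eigenvector of a symmetric matrix by shifted power iteration;
# the shift keeps the dominant eigenvalue of the iterated matrix equal to
# the algebraically largest one even for indefinite inputs
leading_eigenvector <- function(a, tol = 1e-12, max_iter = 20000L) {
  n <- nrow(a)
  if (n == 1L) return(c(1))
  shift <- max(rowSums(abs(a)))  # Gershgorin bound: a + shift*I is PSD
  v <- rep(1 / sqrt(n), n)
  v[seq(1, n, by = 2)] <- -v[seq(1, n, by = 2)]
  v <- v + seq_len(n) / n  # deterministic, unlikely to be orthogonal to PC1
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(max_iter)) {
    w <- as.vector(a %*% v) + shift * v
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    if (sum(abs(w - v)) < tol || sum(abs(w + v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  v
}

#' Call per-bin A/B compartments from an O/E matrix
#'
#' Computes the Pearson correlation matrix of the O/E columns over unmasked
#' bins, extracts its leading eigenvector (PC1), orients the global sign, and
#' assigns `A` to positive and `B` to negative entries. The eigenvector sign
#' is mathematically arbitrary, so it is flipped when its correlation with
#' `orientation_track` (typically gene density or GC content, where higher
#' values mark open chromatin) is negative; without a track, the sign is
#' chosen so that B covers at least as many bins as A (heterochromatin
#' majority convention).
#'
#' @param oe Result of [normalize_oe()] (or a plain O/E matrix).
#' @param mask Logical bin mask (taken from `oe` when it is a list).
#' @param orientation_track Optional per-bin numeric track.
#' @param chrom,bin_size Metadata stored in the profile.
#' @return A `compartment_profile`: a tibble with `chrom`, `bin`, `start`,
#'   `end`, `value` (PC1 entry, `NA` for masked bins) and `status`
#'   (`"A"`, `"B"` or `NA`).
#' @export
compartment_eigenvector <- function(oe, mask = NULL, orientation_track = NULL,
                                    chrom = "chr1", bin_size = 100000) {
  if (is.list(oe) && !is.null(oe$oe)) {
    if (is.null(mask)) mask <- oe$mask
    oe <- oe$oe
  }
  n <- nrow(oe)
  if (is.null(mask)) mask <- rep(TRUE, n)
  idx <- which(mask)
  sub <- oe[idx, idx, drop = FALSE]
  # constant columns have undefined correlation: mask them out
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    warning("masking ", sum(sds == 0), " bin(s) with constant O/E column")
    keep <- sds > 0
    idx <- idx[keep]
    sub <- sub[keep, keep, drop = FALSE]
  }
  values <- rep(NA_real_, n)
  if (length(idx) >= 2) {
    cc <- stats::cor(sub)
    v <- leading_eigenvector(cc)
    values[idx] <- v
    if (!is.null(orientation_track)) {
      tr <- orientation_track[idx]
      if (stats::sd(tr) > 0 && stats::sd(v) > 0 &&
            stats::cor(v, tr) < 0) {
        values <- -values
      }
    } else if (sum(values > 0, na.rm = TRUE) >
                 sum(values < 0, na.rm = TRUE)) {
      values <- -values  # majority of bins default to B
    }
  }
  status <- ifelse(is.na(values) | values == 0, NA_character_,
                   ifelse(values > 0, "A", "B"))
  out <- tibble::tibble(
    chrom = chrom, bin = seq_len(n) - 1L,
    start = (seq_len(n) - 1L) * as.integer(bin_size),
    end = seq_len(n) * as.integer(bin_size),
    value = values, status = status)
  class(out) <- c("compartment_profile", class(out))
  attr(out, "bin_size") <- as.integer(bin_size)
  out
}

#' Call compartments straight from a contact matrix
#'
#' Convenience wrapper: [normalize_oe()] then [compartment_eigenvector()].
#'
#' @param m A `contact_matrix`.
#' @param orientation_track Optional per-bin numeric track.
#' @return A `compartment_profile`.
#' @export
call_compartments <- function(m, orientation_track = NULL) {
  oe <- normalize_oe(m)
  compartment_eigenvector(oe$oe, oe$mask, orientation_track,
                          chrom = m$chrom, bin_size = m$bin_size)
}

#' Compartment status of genomic regions
#'
#' Each region's status is the majority of its overlapped bin bp by status; an
#' exact A/B tie falls to the bin containing the region midpoint, and a region
#' is `NA` when more than half of its overlapped bp is unassigned. Regions
#' extending beyond the profiled bins are clipped with a warning.
#'
#' @param profile A `compartment_profile` (rows may span several chromosomes
#'   when profiles were row-bound).
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @return List with `regions` (input plus `status`) and `summary` (count and
#'   bp fraction per status over the region set).
#' @export
region_compartment_status <- function(profile, regions) {
  status <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    bins <- profile[profile$chrom == r$chrom, ]
    if (!nrow(bins)) { status[i] <- NA_character_; next }
    chrom_end <- max(bins$end)
    s <- r$start; e <- r$end
    if (e > chrom_end) {
      warning("region beyond profiled bins on ", r$chrom, "; clipped")
      e <- chrom_end
    }
    if (s >= e) { status[i] <- NA_character_; next }
    ov <- interval_overlap_bp(s, e, bins$start, bins$end)
    bp_A <- sum(ov[!is.na(bins$status) & bins$status == "A"])
    bp_B <- sum(ov[!is.na(bins$status) & bins$status == "B"])
    bp_NA <- sum(ov[is.na(bins$status)])
    if (bp_NA > 0.5 * (bp_A + bp_B + bp_NA)) {
      status[i] <- NA_character_
    } else if (bp_A > bp_B) {
      status[i] <- "A"
    } else if (bp_B > bp_A) {
      status[i] <- "B"
    } else {
      mid <- s + (e - s) %/% 2
      j <- which(bins$start <= mid & bins$end > mid)
      status[i] <- if (length(j)) bins$status[j[1]] else NA_character_
    }
  }
  regions$status <- status
  bp <- regions$end - regions$start
  summarise_one <- function(st) {
    sel <- if (is.na(st)) is.na(status) else !is.na(status) & status == st
    tibble::tibble(status = if (is.na(st)) "NA" else st,
                   n = sum(sel),
                   bp = sum(bp[sel]),
                   frac_n = sum(sel) / max(1L, nrow(regions)),
                   frac_bp = if (sum(bp) > 0) sum(bp[sel]) / sum(bp) else 0)
  }
  summary <- dplyr::bind_rows(summarise_one("A"), summarise_one("B"),
                              summarise_one(NA_character_))
  list(regions = regions, summary = summary)
}

# status lookup for one (chrom, pos); NA outside the profile
profile_status_at <- function(profile, chrom, pos) {
  bins <- profile[profile$chrom == chrom, ]
  if (!nrow(bins)) return(NA_character_)
  j <- which(bins$start <= pos & bins$end > pos)
  if (!length(j)) return(NA_character_)
  bins$status[j[1]]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.compartment_profile <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.compartment_profile <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x),
    n_A = sum(!is.na(x$status) & x$status == "A"),
    n_B = sum(!is.na(x$status) & x$status == "B"),
    n_NA = sum(is.na(x$status)),
    frac_A = sum(!is.na(x$status) & x$status == "A") / nrow(x),
    bin_size = attr(x, "bin_size") %||% (x$end[1] - x$start[1]))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a compartment profile
#'
#' Bar plot of PC1 values along the chromosome, filled by A/B status.
#'
#' @param object A `compartment_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.compartment_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$value, fill = .data$status)) +
    ggplot2::geom_col(width = (df$end[1] - df$start[1]) / 1e6) +
    ggplot2::scale_fill_manual(values = c(A = "#d7301f", B = "#2b8cbe"),
                               na.value = "grey70") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "PC1", fill = "compartment") +
    ggplot2::theme_minimal()
}
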
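# Synteny: collinear chaining of gene-anchor pairs (MCScanX-like defaults:
# at least 5 anchors per block, rank gaps capped), rearrangement
# classification against the mutual-best chromosome pairing, projection of
# compartment status across blocks, and gene-context SV/TE co-occurrence.

#' Chain homologous gene pairs into collinear blocks
#'
#' Within each `(ref_chrom, qry_chrom)` pair and each orientation, extracts
#' best-scoring chains of anchor pairs that are strictly monotone in both
#' genomes' gene ranks with at most `max_gap_genes` skipped genes between
#' consecutive anchors. Chains are extracted greedily by length (longest
#' first); each pair is used at most once; chains shorter than `min_anchors`
#' are discarded.
#'
#' @param pairs Tibble with columns `ref_gene`, `qry_gene` (may be
#'   many-to-many).
#' @param ref_genes,qry_genes Gene feature tibbles giving each gene's
#'   chromosome and interval (ranks are computed per chromosome by `start`).
#' @param min_anchors Minimum anchors per block (default 5).
#' @param max_gap_genes Maximum genes skipped between consecutive anchors.
#' @return Tibble of syntenic blocks: `block_id`, `ref_chrom`, `qry_chrom`,
#'   `orientation`, `n_anchors`, `ref_start`, `ref_end`, `qry_start`,
#'   `qry_end`, and a list-column `anchors` of the member pair rows.
#' @export
chain_collinear_anchors <- function(pairs, ref_genes, qry_genes,
                                    min_anchors = 5, max_gap_genes = 25) {
  rank_of <- function(genes) {
    genes |>
      dplyr::group_by(.data$chrom) |>
      dplyr::arrange(.data$start, .by_group = TRUE) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::select("feature_id", "chrom", "start", "end", "rank")
  }
  rr <- rank_of(ref_genes)
  qq <- rank_of(qry_genes)
  tab <- pairs |>
    dplyr::inner_join(rr, by = c(ref_gene = "feature_id")) |>
    dplyr::rename(ref_chrom = "chrom", ref_gstart = "start",
                  ref_gend = "end", ref_rank = "rank") |>
    dplyr::inner_join(qq, by = c(qry_gene = "feature_id")) |>
    dplyr::rename(qry_chrom = "chrom", qry_gstart = "start",
                  qry_gend = "end", qry_rank = "rank")
  if (!nrow(tab)) return(empty_block_tbl())
  blocks <- list()
  bid <- 0L
  for (key in unique(paste(tab$ref_chrom, tab$qry_chrom))) {
    sub <- tab[paste(tab$ref_chrom, tab$qry_chrom) == key, ]
    repeat {
      ch_p <- best_chain(sub, "+", max_gap_genes)
      ch_m <- best_chain(sub, "-", max_gap_genes)
      use_p <- length(ch_p) >= length(ch_m)
      ch <- if (use_p) ch_p else ch_m
      if (length(ch) < min_anchors) break
      bid <- bid + 1L
      members <- sub[ch, ]
      blocks[[bid]] <- tibble::tibble(
        block_id = bid,
        ref_chrom = members$ref_chrom[1], qry_chrom = members$qry_chrom[1],
        orientation = if (use_p) "+" else "-",
        n_anchors = nrow(members),
        ref_start = min(members$ref_gstart), ref_end = max(members$ref_gend),
        qry_start = min(members$qry_gstart), qry_end = max(members$qry_gend),
        anchors = list(members))
      sub <- sub[-ch, ]
      if (!nrow(sub)) break
    }
  }
  if (!length(blocks)) return(empty_block_tbl())
  dplyr::arrange(dplyr::bind_rows(blocks), .data$ref_chrom, .data$ref_start)
}

empty_block_tbl <- function() {
  tibble::tibble(
    block_id = integer(), ref_chrom = character(), qry_chrom = character(),
    orientation = character(), n_anchors = integer(),
    ref_start = integer(), ref_end = integer(),
    qry_start = integer(), qry_end = integer(), anchors = list(),
    block_class = character())
}

# longest chain by DP over pairs sorted by ref rank; strict monotonicity in
# both ranks, capped rank gaps; returns row indices into `sub`
best_chain <- function(sub, orientation, max_gap_genes) {
  n <- nrow(sub)
  if (!n) return(integer(0))
  ord <- order(sub$ref_rank, sub$qry_rank)
  r <- sub$ref_rank[ord]
  q <- sub$qry_rank[ord]
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      dr <- r[i] - r[j]
      dq <- if (orientation == "+") q[i] - q[j] else q[j] - q[i]
      if (dr >= 1L && dq >= 1L &&
            dr - 1L <= max_gap_genes && dq - 1L <= max_gap_genes &&
            len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  best <- which.max(len)
  chain <- integer(0)
  while (best != 0L) {
    chain <- c(best, chain)
    best <- prev[best]
  }
  ord[chain]
}

#' Classify syntenic blocks as collinear, inverted or translocated
#'
#' The expected chromosome pairing is the mutual best by summed anchor count.
#' Blocks on the expected pairing are `collinear` (`+` orientation) or
#' `inverted` (`-`); blocks off it are `translocated`. A reciprocal
#' translocation is reported when two chromosome pairs each carry translocated
#' blocks in both directions of the swap.
#'
#' @param blocks Output of [chain_collinear_anchors()].
#' @return List with `blocks` (input plus `block_class`), `pairing`
#'   (ref/qry chromosome pairing table) and `reciprocal` (tibble of detected
#'   reciprocal chromosome-pair swaps, possibly empty).
#' @export
classify_block_rearrangements <- function(blocks) {
  if (!nrow(blocks)) {
    return(list(blocks = blocks, pairing = tibble::tibble(
      ref_chrom = character(), qry_chrom = character()),
      reciprocal = tibble::tibble(ref_chrom = character(),
                                  qry_chrom = character())))
  }
  tab <- blocks |>
    dplyr::group_by(.data$ref_chrom, .data$qry_chrom) |>
    dplyr::summarise(n = sum(.data$n_anchors), .groups = "drop")
  best_r <- tab |>
    dplyr::group_by(.data$ref_chrom) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  best_q <- tab |>
    dplyr::group_by(.data$qry_chrom) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  pairing <- dplyr::inner_join(best_r, best_q,
                               by = c("ref_chrom", "qry_chrom", "n")) |>
    dplyr::select("ref_chrom", "qry_chrom")
  expected <- stats::setNames(pairing$qry_chrom, pairing$ref_chrom)
  on_pair <- !is.na(expected[blocks$ref_chrom]) &
    expected[blocks$ref_chrom] == blocks$qry_chrom
  blocks$block_class <- ifelse(
    on_pair, ifelse(blocks$orientation == "+", "collinear", "inverted"),
    "translocated")
  # reciprocal swaps: (c1 -> q2, c2 -> q1) with expected c1 -> q1, c2 -> q2
  tr <- unique(blocks[blocks$block_class == "translocated",
                      c("ref_chrom", "qry_chrom")])
  recip <- list()
  if (nrow(tr) >= 2) {
    for (i in seq_len(nrow(tr))) {
      c1 <- tr$ref_chrom[i]; q2 <- tr$qry_chrom[i]
      # the ref chromosome whose expected partner is q2
      c2 <- names(expected)[expected == q2]
      q1 <- if (c1 %in% names(expected)) expected[[c1]] else NA
      if (length(c2) == 1 && !is.na(q1) &&
            any(tr$ref_chrom == c2 & tr$qry_chrom == q1) && c1 < c2) {
        recip[[length(recip) + 1L]] <- tibble::tibble(
          ref_chrom = c(c1, c2), qry_chrom = c(q2, q1))
      }
    }
  }
  list(blocks = blocks, pairing = pairing,
       reciprocal = if (length(recip)) dplyr::bind_rows(recip) else
         tibble::tibble(ref_chrom = character(), qry_chrom = character()))
}

#' Compartment-switch summary over syntenic blocks
#'
#' Walks each block's query span in steps of `step` bp, maps every step
#' midpoint linearly (orientation-aware) to its reference coordinate, fetches
#' the compartment status of both genomes there, and attributes the step's bp
#' to `conserved` (equal, both assigned), `A_to_B` (reference A, query B),
#' `B_to_A`, or `NA` (either side unassigned). The four classes partition the
#' compared bp exactly. Switch bp are attributed to the query genome, matching
#' the convention of reporting switched Mb in the re-annotated genome.
#'
#' @param blocks Classified block tibble.
#' @param profile_ref,profile_qry Compartment profiles (bins across all
#'   chromosomes of each genome).
#' @param step Sampling step in bp (defaults to the reference profile's bin
#'   size).
#' @return A `switch_summary` list: `totals` (bp and percentage per class),
#'   `per_chromosome` (query-chromosome breakdown), `compared_bp`.
#' @export
compartment_switch_summary <- function(blocks, profile_ref, profile_qry,
                                       step = NULL) {
  if (is.null(step)) {
    step <- attr(profile_ref, "bin_size") %||%
      (profile_ref$end[1] - profile_ref$start[1])
  }
  acc <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    span <- b$qry_end - b$qry_start
    if (span <= 0) next
    starts <- seq(b$qry_start, b$qry_end - 1L, by = step)
    widths <- pmin(starts + step, b$qry_end) - starts
    mids <- starts + widths %/% 2
    frac <- (mids - b$qry_start) / span
    ref_pos <- if (b$orientation == "+") {
      b$ref_start + frac * (b$ref_end - b$ref_start)
    } else {
      b$ref_end - frac * (b$ref_end - b$ref_start)
    }
    ref_pos <- pmin(pmax(floor(ref_pos), b$ref_start), b$ref_end - 1L)
    st_r <- vapply(ref_pos, function(p) {
      profile_status_at(profile_ref, b$ref_chrom, p)
    }, "")
    st_q <- vapply(mids, function(p) {
      profile_status_at(profile_qry, b$qry_chrom, p)
    }, "")
    cls <- dplyr::case_when(
      is.na(st_r) | is.na(st_q) ~ "NA",
      st_r == st_q ~ "conserved",
      st_r == "A" & st_q == "B" ~ "A_to_B",
      TRUE ~ "B_to_A")
    acc[[length(acc) + 1L]] <- tibble::tibble(
      qry_chrom = b$qry_chrom, class = cls, bp = widths)
  }
  if (!length(acc)) {
    acc <- list(tibble::tibble(qry_chrom = character(), class = character(),
                               bp = integer()))
  }
  steps <- dplyr::bind_rows(acc)
  classes <- c("conserved", "A_to_B", "B_to_A", "NA")
  totals <- steps |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(bp = sum(.data$bp), .groups = "drop") |>
    dplyr::right_join(tibble::tibble(class = classes), by = "class") |>
    dplyr::mutate(bp = dplyr::coalesce(.data$bp, 0)) |>
    dplyr::arrange(match(.data$class, classes))
  compared <- sum(totals$bp)
  totals$pct <- if (compared > 0) 100 * totals$bp / compared else 0
  per_chrom <- steps |>
    dplyr::group_by(.data$qry_chrom, .data$class) |>
    dplyr::summarise(bp = sum(.data$bp), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "bp",
                       values_fill = 0)
  for (cl in classes) if (!cl %in% names(per_chrom)) per_chrom[[cl]] <- 0
  structure(list(totals = totals, per_chromosome = per_chrom,
                 compared_bp = compared),
            class = "switch_summary")
}

#' @export
print.switch_summary <- function(x, ...) {
  cat(sprintf("<switch_summary> %s bp compared\n",
              format(x$compared_bp, big.mark = ",")))
  print(x$totals)
  invisible(x)
}

#' Plot a compartment-switch summary
#'
#' Stacked per-chromosome bar chart of conserved and switched bp.
#'
#' @param x A `switch_summary`.
#' @return A ggplot object.
#' @export
plot_switch_summary <- function(x) {
  df <- tidyr::pivot_longer(x$per_chromosome, -"qry_chrom",
                            names_to = "class", values_to = "bp")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$qry_chrom, y = .data$bp / 1e6,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Mb", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Gene-context SV and TE co-occurrence
#'
#' For each gene, a window of the gene plus `gene_context_flank` (2 kb) on
#' both sides is tested for intersecting SV calls (insertion calls count by
#' their point) and TE annotations; `co_occurs` marks genes with both.
#'
#' @param genes Gene feature tibble.
#' @param svs SV call tibble on the same genome's coordinates (reference-side
#'   columns are used).
#' @param tes TE feature tibble on the same genome.
#' @param cfg An [sv_config()].
#' @return List with `genes` (per-gene flags `sv_affected`, `te_present`,
#'   `co_occurs`) and `summary` (counts and fractions).
#' @export
gene_context_overlap <- function(genes, svs, tes, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  fl <- cfg$gene_context_flank
  sv_affected <- logical(nrow(genes))
  te_present <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ws <- g$start - fl
    we <- g$end + fl
    s <- svs[!is.na(svs$ref_chrom) & svs$ref_chrom == g$chrom, ]
    if (nrow(s)) {
      sv_affected[i] <- any(interval_hits(s$ref_start, s$ref_end, ws, we))
    }
    t <- tes[tes$chrom == g$chrom, ]
    if (nrow(t)) {
      te_present[i] <- any(interval_hits(t$start, t$end, ws, we))
    }
  }
  out <- genes
  out$sv_affected <- sv_affected
  out$te_present <- te_present
  out$co_occurs <- sv_affected & te_present
  n <- nrow(genes)
  n_sv <- sum(sv_affected)
  n_co <- sum(out$co_occurs)
  list(genes = out,
       summary = tibble::tibble(
         n_genes = n, n_sv_affected = n_sv,
         frac_sv_affected = if (n) n_sv / n else NA_real_,
         n_te_present = sum(te_present),
         n_co_occur = n_co,
         frac_co_occur_of_sv_affected = if (n_sv) n_co / n_sv else NA_real_))
}
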
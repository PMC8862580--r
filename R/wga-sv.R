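# SV calling from whole-genome-alignment blocks: unique-anchor selection,
# gap classification between consecutive anchors, rearrangement detection,
# and positional annotation of the resulting calls.

#' Select unique alignment anchors
#'
#' Keeps blocks whose reference span is at least `anchor_min_len` and whose
#' reference interval overlaps no already-kept block by more than 50 % of its
#' own length. Selection is greedy by descending reference length with ties
#' broken by `(ref_chrom, ref_start)`, so the longest placement of a repeated
#' sequence wins.
#'
#' @param blocks Alignment-block tibble (sorted or not).
#' @param cfg An [sv_config()].
#' @return The kept blocks, sorted by reference position, with
#'   `is_unique_anchor = TRUE`.
#' @export
select_unique_anchors <- function(blocks, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  if (!nrow(blocks)) return(blocks)
  blocks <- dplyr::mutate(blocks, .len = .data$ref_end - .data$ref_start)
  blocks <- dplyr::filter(blocks, .data$.len >= cfg$anchor_min_len)
  blocks <- dplyr::arrange(blocks, dplyr::desc(.data$.len),
                           .data$ref_chrom, .data$ref_start)
  keep <- logical(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    prev <- which(keep & blocks$ref_chrom == blocks$ref_chrom[i])
    ov <- if (length(prev)) {
      max(interval_overlap_bp(blocks$ref_start[i], blocks$ref_end[i],
                              blocks$ref_start[prev], blocks$ref_end[prev]))
    } else 0
    keep[i] <- ov <= 0.5 * blocks$.len[i]
  }
  out <- dplyr::select(blocks[keep, ], -".len")
  out$is_unique_anchor <- TRUE
  dplyr::arrange(out, .data$ref_chrom, .data$ref_start, .data$ref_end)
}

#' Classify one anchor-gap signature
#'
#' Given the reference gap `R` and the strand-aware query gap `Q` between two
#' consecutive unique anchors, returns the SV class implied by their signs, or
#' `NA` when the discrepancy `d = Q - R` is below the minimum SV size or the
#' gap exceeds the maximum. The sign table: both gaps non-negative gives a
#' plain insertion (`d > 0`) or deletion (`d < 0`); a negative reference gap
#' with non-negative query gap means reference anchors overlap, i.e. the query
#' gained repeat copies (`repeat_expansion`); the mirrored case is
#' `repeat_contraction`; both gaps negative marks a tandem copy-number change
#' (`tandem_expansion`/`tandem_contraction` by the sign of `d`).
#'
#' @param R_gap Reference gap in bp (may be negative).
#' @param Q_gap Query gap in bp (may be negative).
#' @param cfg An [sv_config()].
#' @return A single SV type string, or `NA_character_` for no call.
#' @examples
#' classify_gap(0, 2000)     # insertion
#' classify_gap(-400, 100)   # repeat_expansion
#' classify_gap(0, 30)       # NA: below the 50 bp floor
#' @export
classify_gap <- function(R_gap, Q_gap, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  d <- Q_gap - R_gap
  no_call <- abs(d) < cfg$min_sv_size | abs(d) > cfg$max_sv_size |
    pmax(R_gap, Q_gap) > cfg$max_sv_size
  type <- ifelse(
    R_gap >= 0 & Q_gap >= 0, ifelse(d > 0, "insertion", "deletion"),
    ifelse(R_gap < 0 & Q_gap >= 0, "repeat_expansion",
           ifelse(R_gap >= 0, "repeat_contraction",
                  ifelse(d > 0, "tandem_expansion", "tandem_contraction"))))
  ifelse(no_call, NA_character_, type)
}

# gap pairs between consecutive anchors of one (ref_chrom, qry_chrom, strand)
# run; query gaps are strand-aware (query descends along "-" runs)
gap_pairs <- function(anchors) {
  anchors <- dplyr::arrange(anchors, .data$ref_chrom, .data$ref_start,
                            .data$ref_end)
  grp <- split(anchors,
               paste(anchors$ref_chrom, anchors$qry_chrom, anchors$strand))
  rows <- purrr::map(grp, function(g) {
    if (nrow(g) < 2) return(NULL)
    l <- g[-nrow(g), ]
    r <- g[-1, ]
    R_gap <- r$ref_start - l$ref_end
    Q_gap <- if (g$strand[1] == "+") {
      r$qry_start - l$qry_end
    } else {
      l$qry_start - r$qry_end
    }
    tibble::tibble(
      ref_chrom = l$ref_chrom, qry_chrom = l$qry_chrom, strand = l$strand,
      l_ref_end = l$ref_end, r_ref_start = r$ref_start,
      l_qry_start = l$qry_start, l_qry_end = l$qry_end,
      r_qry_start = r$qry_start, r_qry_end = r$qry_end,
      R_gap = R_gap, Q_gap = Q_gap)
  })
  dplyr::bind_rows(rows)
}

#' Call SVs from unique anchors by gap signatures
#'
#' Scans consecutive anchor pairs within each `(ref_chrom, qry_chrom, strand)`
#' run, classifies every gap with [classify_gap()], and emits one call per
#' classified gap. Presence/absence variants (PAVs) are the plain
#' insertion/deletion calls; all other gap classes are repeat-mediated.
#'
#' @param anchors Output of [select_unique_anchors()].
#' @param cfg An [sv_config()].
#' @return SV call tibble sorted by reference position, `source = "wga"`.
#' @export
call_svs <- function(anchors, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  gp <- gap_pairs(anchors)
  if (is.null(gp) || !nrow(gp)) return(empty_sv_calls())
  gp$sv_type <- classify_gap(gp$R_gap, gp$Q_gap, cfg)
  gp <- gp[!is.na(gp$sv_type), ]
  if (!nrow(gp)) return(empty_sv_calls())
  ref_start <- gp$l_ref_end
  ref_end <- pmax(gp$l_ref_end, gp$r_ref_start)
  qry_start <- ifelse(gp$strand == "+", gp$l_qry_end, gp$r_qry_end)
  qry_end <- ifelse(gp$strand == "+",
                    pmax(gp$l_qry_end, gp$r_qry_start),
                    pmax(gp$r_qry_end, gp$l_qry_start))
  calls <- tibble::tibble(
    sv_type = gp$sv_type,
    ref_chrom = gp$ref_chrom, ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_end),
    qry_chrom = gp$qry_chrom, qry_start = as.integer(qry_start),
    qry_end = as.integer(qry_end),
    size = as.integer(abs(gp$Q_gap - gp$R_gap)),
    source = "wga",
    support = rep(list(integer()), nrow(gp)),
    filter_status = "PASS",
    is_pav = gp$sv_type %in% c("insertion", "deletion"),
    context = NA_character_, impact = NA_character_)
  dplyr::arrange(calls, .data$ref_chrom, .data$ref_start, .data$ref_end)
}

#' Detect inversions and translocations from anchor layout
#'
#' Expected chromosome pairing is the mutual-best match by aligned reference
#' bp (or may be supplied). On an expectedly paired chromosome, each maximal
#' run of `-` strand blocks embedded in a `+` context becomes one inversion
#' call spanning the run; each maximal run of blocks violating the expected
#' pairing becomes one translocation call, so a reciprocal translocation
#' surfaces as two calls with mutually swapped chromosome pairs.
#'
#' @param blocks Anchor-filtered alignment blocks.
#' @param one_to_one Optional tibble `(ref_chrom, qry_chrom)` giving the
#'   expected pairing; computed by mutual best aligned bp when `NULL`.
#' @return SV call tibble of inversions and translocations.
#' @export
detect_inversions_and_translocations <- function(blocks, one_to_one = NULL) {
  if (!nrow(blocks)) return(empty_sv_calls())
  if (is.null(one_to_one)) one_to_one <- expected_pairing(blocks)
  pairing <- stats::setNames(one_to_one$qry_chrom, one_to_one$ref_chrom)
  blocks <- dplyr::arrange(blocks, .data$ref_chrom, .data$ref_start)
  calls <- list()
  for (chrom in unique(blocks$ref_chrom)) {
    b <- blocks[blocks$ref_chrom == chrom, ]
    expect_q <- if (chrom %in% names(pairing)) pairing[[chrom]] else NA
    off <- is.na(expect_q) | b$qry_chrom != expect_q
    # translocation runs: maximal stretches of off-pairing blocks
    r <- rle(off)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (k in seq_along(r$values)) {
      sel <- idx_start[k]:idx_end[k]
      if (r$values[k]) {
        calls[[length(calls) + 1L]] <- tibble::tibble(
          sv_type = "translocation", ref_chrom = chrom,
          ref_start = min(b$ref_start[sel]), ref_end = max(b$ref_end[sel]),
          qry_chrom = b$qry_chrom[sel][1],
          qry_start = min(b$qry_start[sel]), qry_end = max(b$qry_end[sel]),
          size = as.integer(max(b$ref_end[sel]) - min(b$ref_start[sel])),
          source = "wga", support = list(integer()),
          filter_status = "PASS", is_pav = FALSE,
          context = NA_character_, impact = NA_character_)
      }
      {
        # inversion runs: "-" blocks embedded in "+" context, whether the
        # stretch sits on the expected pairing or inside a translocation
        bb <- b[sel, ]
        r2 <- rle(bb$strand == "-")
        e2 <- cumsum(r2$lengths)
        s2 <- e2 - r2$lengths + 1L
        for (m in seq_along(r2$values)) {
          if (!r2$values[m]) next
          sel2 <- s2[m]:e2[m]
          calls[[length(calls) + 1L]] <- tibble::tibble(
            sv_type = "inversion", ref_chrom = chrom,
            ref_start = min(bb$ref_start[sel2]),
            ref_end = max(bb$ref_end[sel2]),
            qry_chrom = bb$qry_chrom[sel2][1],
            qry_start = min(bb$qry_start[sel2]),
            qry_end = max(bb$qry_end[sel2]),
            size = as.integer(max(bb$ref_end[sel2]) - min(bb$ref_start[sel2])),
            source = "wga", support = list(integer()),
            filter_status = "PASS", is_pav = FALSE,
            context = NA_character_, impact = NA_character_)
        }
      }
    }
  }
  if (!length(calls)) return(empty_sv_calls())
  dplyr::arrange(dplyr::bind_rows(calls), .data$ref_chrom, .data$ref_start)
}

# mutual-best ref<->qry chromosome pairing by summed aligned reference bp
expected_pairing <- function(blocks) {
  tab <- blocks |>
    dplyr::mutate(bp = .data$ref_end - .data$ref_start) |>
    dplyr::group_by(.data$ref_chrom, .data$qry_chrom) |>
    dplyr::summarise(bp = sum(.data$bp), .groups = "drop")
  best_r <- tab |>
    dplyr::group_by(.data$ref_chrom) |>
    dplyr::slice_max(.data$bp, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  best_q <- tab |>
    dplyr::group_by(.data$qry_chrom) |>
    dplyr::slice_max(.data$bp, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  dplyr::inner_join(best_r, best_q,
                    by = c("ref_chrom", "qry_chrom", "bp")) |>
    dplyr::select("ref_chrom", "qry_chrom")
}

#' Annotate SV calls with gene context and impact
#'
#' Assigns each call its highest-priority positional category against the
#' feature set of the genome carrying the affected sequence:
#' `transcript_ablation` (call contains an entire gene) > `exon` >
#' `splice_site` (the 2 bp at either intron end) > `intron` > `upstream` /
#' `downstream` (within 5 kb, strand-aware) > `intergenic`. Impact is `high`
#' for the first three, `modifier` otherwise. Deletions and contraction-class
#' calls carry reference-side sequence and are annotated on `side = "ref"`;
#' insertions and expansion-class calls on `side = "qry"` (the insertion
#' point/payload lives in the query genome).
#'
#' @param calls SV call tibble.
#' @param genes,exons Feature tibbles of the annotated genome (with exon
#'   `attrs` of the form `Parent=<gene_id>` tying exons to genes).
#' @param cfg An [sv_config()].
#' @param side `"ref"` or `"qry"`: which calls to annotate, against which
#'   coordinates. Calls whose affected side differs are left untouched.
#' @return `calls` with `context` and `impact` filled in.
#' @export
annotate_sv_context <- function(calls, genes, exons, cfg = sv_config(),
                                side = c("ref", "qry")) {
  cfg <- as_sv_config(cfg)
  side <- match.arg(side)
  if (!nrow(calls)) return(calls)
  ref_side_types <- c("deletion", "repeat_contraction", "tandem_contraction",
                      "inversion", "duplication", "translocation")
  affected <- if (side == "ref") {
    calls$sv_type %in% ref_side_types
  } else {
    !calls$sv_type %in% ref_side_types
  }
  pre <- paste0(side, "_")
  for (i in which(affected)) {
    chrom <- calls[[paste0(pre, "chrom")]][i]
    s <- calls[[paste0(pre, "start")]][i]
    e <- calls[[paste0(pre, "end")]][i]
    if (is.na(chrom) || is.na(s) || is.na(e)) next
    ann <- classify_context(chrom, s, e, genes, exons, cfg)
    calls$context[i] <- ann$context
    calls$impact[i] <- ann$impact
  }
  calls
}

classify_context <- function(chrom, s, e, genes, exons, cfg) {
  g <- genes[genes$chrom == chrom, ]
  x <- exons[exons$chrom == chrom, ]
  ctx <- "intergenic"
  if (nrow(g)) {
    nonzero <- e > s
    if (nonzero && any(s <= g$start & e >= g$end)) {
      ctx <- "transcript_ablation"
    } else if (nrow(x) && any(interval_hits(s, e, x$start, x$end))) {
      ctx <- "exon"
    } else {
      hit_gene <- interval_hits(s, e, g$start, g$end)
      if (any(hit_gene)) {
        # splice region: first/last `splice_bp` bases of each intron
        splice <- splice_regions(g[hit_gene, , drop = FALSE], x, cfg$splice_bp)
        if (nrow(splice) &&
              any(interval_hits(s, e, splice$start, splice$end))) {
          ctx <- "splice_site"
        } else {
          ctx <- "intron"
        }
      } else {
        up <- ifelse(g$strand == "-",
                     interval_hits(s, e, g$end, g$end + cfg$updown_flank),
                     interval_hits(s, e, g$start - cfg$updown_flank, g$start))
        down <- ifelse(g$strand == "-",
                       interval_hits(s, e, g$start - cfg$updown_flank, g$start),
                       interval_hits(s, e, g$end, g$end + cfg$updown_flank))
        if (any(up) || any(down)) {
          # nearest gene decides; ties prefer upstream
          cand <- which(up | down)
          dist <- pmin(abs(g$start[cand] - e), abs(s - g$end[cand]))
          j <- cand[which.min(dist)]
          ctx <- if (up[j]) "upstream" else "downstream"
        }
      }
    }
  }
  impact <- if (ctx %in% c("transcript_ablation", "exon", "splice_site")) {
    "high"
  } else {
    "modifier"
  }
  list(context = ctx, impact = impact)
}

splice_regions <- function(genes, exons, splice_bp) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$feature_id[i]
    ex <- exons[grepl(paste0("Parent=", gid, "$"), exons$attrs) |
                  startsWith(exons$feature_id, paste0(gid, ".")), ]
    ex <- dplyr::arrange(ex, .data$start)
    if (nrow(ex) < 2) next
    for (k in seq_len(nrow(ex) - 1L)) {
      int_s <- ex$end[k]
      int_e <- ex$start[k + 1L]
      if (int_e <= int_s) next
      w <- min(splice_bp, int_e - int_s)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = c(int_s, int_e - w), end = c(int_s + w, int_e))
    }
  }
  if (!length(rows)) return(tibble::tibble(start = integer(), end = integer()))
  dplyr::bind_rows(rows)
}

#' Tabulate SV calls by class and context
#'
#' @param calls SV call tibble.
#' @return A tibble of counts per `sv_type` (and per `context` when present).
#' @export
summarize_sv_categories <- function(calls) {
  by_type <- calls |>
    dplyr::count(.data$sv_type, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  by_ctx <- if (any(!is.na(calls$context))) {
    dplyr::count(calls, .data$context, name = "n")
  } else {
    NULL
  }
  pav <- sum(calls$is_pav, na.rm = TRUE)
  tibble::tibble(
    category = c(by_type$sv_type,
                 if (!is.null(by_ctx)) paste0("context:", by_ctx$context),
                 "pav_total", "total"),
    n = c(by_type$n, if (!is.null(by_ctx)) by_ctx$n, pav, nrow(calls)))
}
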
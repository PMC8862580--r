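# Simulated whole-genome-alignment blocks: the comparison between the two
# derived genomes is composed through the ancestor segment maps, split at
# every planted breakpoint, and decorated with the anchor-overlap signatures
# that repeat/tandem copy-number changes leave in real alignments.

# mirror an op class from "edit relative to ancestor" into "call in the
# ref(genome1)-vs-qry(genome2) comparison"
mirror_gap_class <- function(op_type, genome) {
  mirrored <- c(insertion = "deletion", deletion = "insertion",
                te_insertion = "deletion",
                repeat_expansion = "repeat_contraction",
                repeat_contraction = "repeat_expansion",
                tandem_expansion = "tandem_contraction",
                tandem_contraction = "tandem_expansion")
  fwd <- c(insertion = "insertion", te_insertion = "insertion",
           deletion = "deletion",
           repeat_expansion = "repeat_expansion",
           repeat_contraction = "repeat_contraction",
           tandem_expansion = "tandem_expansion",
           tandem_contraction = "tandem_contraction")
  ifelse(genome == 2L, fwd[op_type], mirrored[op_type])
}

#' Simulate alignment blocks for a derived genome pair
#'
#' Stands in for a whole-genome aligner: emits one collinear block per maximal
#' truth-collinear segment between `genome1` (reference) and `genome2`
#' (query), split at every planted SV and rearrangement breakpoint. Inverted
#' segments carry `strand = "-"`. Repeat- and tandem-class operations emit the
#' overlapping-anchor signatures their class implies, so the downstream gap
#' classifier sees exactly the geometry a real aligner would produce. The
#' returned tibble carries an `expected_calls` attribute: the gap-scan call
#' (type, size, both intervals) that each planted gap-class operation should
#' produce under zero jitter.
#'
#' @param pair A `genome_pair` from [derive_pair()].
#' @param breakpoint_jitter Maximum uniform jitter (bp) added to block ends.
#' @param seed Integer seed (used for jitter and percent identities).
#' @return Alignment-block tibble (see [read_alignment_coords()] for columns),
#'   with attribute `expected_calls`.
#' @export
simulate_alignment_blocks <- function(pair, breakpoint_jitter = 0, seed = 1) {
  stopifnot(inherits(pair, "genome_pair"))
  a1 <- pair$map1[pair$map1$tag == "aligned", ]
  a2 <- pair$map2[pair$map2$tag == "aligned", ]

  pieces <- list()
  for (i in seq_len(nrow(a1))) {
    s1 <- a1[i, ]
    cand <- a2[a2$anc_chrom == s1$anc_chrom &
                 a2$anc_start < s1$anc_end & a2$anc_end > s1$anc_start, ]
    for (j in seq_len(nrow(cand))) {
      s2 <- cand[j, ]
      a <- max(s1$anc_start, s2$anc_start)
      b <- min(s1$anc_end, s2$anc_end)
      if (b <= a) next
      r <- map_sub(s1, a, b)
      q <- map_sub(s2, a, b)
      strand <- if (s1$orientation == s2$orientation) "+" else "-"
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        ref_chrom = r$chrom, ref_start = r$start, ref_end = r$end,
        qry_chrom = q$chrom, qry_start = q$start, qry_end = q$end,
        strand = strand)
    }
  }
  blocks <- dplyr::arrange(dplyr::bind_rows(pieces),
                           .data$ref_chrom, .data$ref_start)

  # signature adjustments + expected gap calls for planted operations
  truth <- pair$truth
  expected <- list()
  gap_ops <- truth[truth$op_type %in% c(gap_classes, "te_insertion"), ]
  for (i in seq_len(nrow(gap_ops))) {
    op <- gap_ops[i, ]
    if (!op$g1_liftable || !op$g2_liftable) next
    call_type <- unname(mirror_gap_class(op$op_type, op$genome))
    s <- op$payload_len
    # junction = (L.ref_end, L.qry_end) of the base split. For a tandem
    # expansion the non-edited genome's footprint is the duplicated unit,
    # whose END is where the alignment splits; all other classes split at
    # the footprint start.
    p <- op$g1_start; q <- op$g2_start
    if (op$op_type == "tandem_expansion") {
      if (op$genome == 2L) p <- op$g1_end else q <- op$g2_end
    }
    # base junction geometry: qry-extra classes have ref point p / qry [q,q+s),
    # ref-extra classes have ref [p,p+s) / qry point q
    qry_extra <- call_type %in% c("insertion", "repeat_expansion",
                                  "tandem_expansion")
    e <- switch(call_type,
                insertion = 0L, deletion = 0L,
                repeat_expansion = min(s, 100L),
                repeat_contraction = min(s, 100L),
                tandem_expansion = s + min(s, 100L),
                tandem_contraction = s + min(s, 100L))
    li <- which(blocks$ref_chrom == op$g1_chrom &
                  blocks$qry_chrom == op$g2_chrom &
                  blocks$ref_end == p & blocks$qry_end == q &
                  blocks$strand == "+")
    if (length(li) != 1L) next  # junction obscured (e.g. op at a map boundary)
    if (e > 0L) {
      blocks$ref_end[li] <- blocks$ref_end[li] + e
      blocks$qry_end[li] <- blocks$qry_end[li] + e
    }
    ref_iv <- if (qry_extra) c(p + e, max(p + e, p)) else c(p + e, max(p + e, p + s))
    qry_iv <- if (qry_extra) c(q + e, max(q + e, q + s)) else c(q + e, max(q + e, q))
    expected[[length(expected) + 1L]] <- tibble::tibble(
      op_id = op$op_id, sv_type = call_type, size = s,
      ref_chrom = blocks$ref_chrom[li], ref_start = ref_iv[1], ref_end = ref_iv[2],
      qry_chrom = blocks$qry_chrom[li], qry_start = qry_iv[1], qry_end = qry_iv[2])
  }

  withr::with_seed(seed, {
    if (breakpoint_jitter > 0) {
      n <- nrow(blocks)
      jit <- function() sample(-breakpoint_jitter:breakpoint_jitter, n,
                               replace = TRUE)
      blocks$ref_start <- pmax(0L, blocks$ref_start + jit())
      blocks$ref_end <- blocks$ref_end + jit()
      blocks$qry_start <- pmax(0L, blocks$qry_start + jit())
      blocks$qry_end <- blocks$qry_end + jit()
      bad_r <- blocks$ref_end <= blocks$ref_start
      blocks$ref_end[bad_r] <- blocks$ref_start[bad_r] + 1L
      bad_q <- blocks$qry_end <= blocks$qry_start
      blocks$qry_end[bad_q] <- blocks$qry_start[bad_q] + 1L
    }
    blocks$pct_identity <- round(stats::runif(nrow(blocks), 95, 99.99), 2)
  })
  blocks$is_unique_anchor <- rep(NA, nrow(blocks))
  blocks <- dplyr::arrange(blocks, .data$ref_chrom, .data$ref_start,
                           .data$ref_end)
  attr(blocks, "expected_calls") <-
    if (length(expected)) dplyr::bind_rows(expected) else tibble::tibble(
      op_id = character(), sv_type = character(), size = integer(),
      ref_chrom = character(), ref_start = integer(), ref_end = integer(),
      qry_chrom = character(), qry_start = integer(), qry_end = integer())
  blocks
}

# orientation-aware sub-interval of an aligned map segment
map_sub <- function(seg, a, b) {
  if (seg$orientation == "+") {
    list(chrom = seg$der_chrom,
         start = seg$der_start + (a - seg$anc_start),
         end = seg$der_start + (b - seg$anc_start))
  } else {
    list(chrom = seg$der_chrom,
         start = seg$der_end - (b - seg$anc_start),
         end = seg$der_end - (a - seg$anc_start))
  }
}

#' Draw a random edit script for the simulator
#'
#' Places the requested number of operations per class at uniformly spaced,
#' non-overlapping ancestor positions with at least `spacing` bp between
#' consecutive operation anchors (and from the chromosome ends), so alignment
#' anchors between events stay long enough to survive unique-anchor filtering.
#'
#' @param ancestor Result of [generate_ancestor()].
#' @param counts Named integer vector of per-class operation counts; classes
#'   as in [edit_ops()] minus rearrangements.
#' @param size_range Length-2 vector, SV sizes drawn uniformly within it (bp).
#' @param te_size_range Size range for `te_insertion` payloads (bp).
#' @param spacing Minimum distance between operation anchors (bp).
#' @param inversion_len Length of the single inversion, if requested via
#'   `counts["inversion"]`.
#' @param translocation `NULL`, or a list `(chrom1, pos1, chrom2, pos2)` for
#'   one reciprocal translocation.
#' @param seed Integer seed.
#' @return An edit-op tibble.
#' @export
sample_edit_script <- function(ancestor,
                               counts = c(insertion = 10, deletion = 10,
                                          repeat_expansion = 10,
                                          repeat_contraction = 10,
                                          tandem_expansion = 10,
                                          tandem_contraction = 10,
                                          te_insertion = 0, inversion = 0),
                               size_range = c(60, 2000),
                               te_size_range = c(1200, 3000),
                               spacing = 15000,
                               inversion_len = 60000,
                               translocation = NULL,
                               seed = 1) {
  withr::with_seed(seed, {
    lens <- nchar(ancestor$genome)
    chroms <- names(lens)
    ops <- list()
    n_inv <- if ("inversion" %in% names(counts)) counts[["inversion"]] else 0L
    classes <- rep(names(counts), counts)
    classes <- setdiff_keep_dups(classes, "inversion")
    classes <- sample(classes)  # interleave classes along the genome
    n <- length(classes)
    # slots: evenly spaced anchors across chromosomes
    slot_step <- spacing + max(size_range[2], te_size_range[2])
    slots <- list()
    margin <- slot_step
    for (chrom in chroms) {
      usable <- lens[[chrom]] - 2 * margin
      if (usable <= 0) next
      k <- max(0L, floor(usable / slot_step))
      if (k > 1) {
        pos <- margin + round(seq(0, usable, length.out = k))
        slots[[chrom]] <- tibble::tibble(chrom = chrom, pos = as.integer(pos))
      }
    }
    slots <- dplyr::bind_rows(slots)
    drop_near <- function(slots, chrom, lo, hi) {
      dplyr::filter(slots, .data$chrom != !!chrom |
                      .data$pos < lo | .data$pos > hi)
    }
    if (!is.null(translocation)) {
      slots <- drop_near(slots, translocation$chrom1,
                         translocation$pos1 - slot_step,
                         translocation$pos1 + slot_step)
      slots <- drop_near(slots, translocation$chrom2,
                         translocation$pos2 - slot_step,
                         translocation$pos2 + slot_step)
    }
    tr_bp <- if (!is.null(translocation)) {
      tibble::tibble(chrom = c(translocation$chrom1, translocation$chrom2),
                     pos = c(translocation$pos1, translocation$pos2))
    } else {
      tibble::tibble(chrom = character(), pos = integer())
    }
    for (k in seq_len(n_inv)) {
      if (!nrow(slots)) stop("not enough genome for the inversion", call. = FALSE)
      ok <- which(purrr::map_lgl(seq_len(nrow(slots)), function(i) {
        fits <- slots$pos[i] + inversion_len + slot_step <
          lens[[slots$chrom[i]]]
        # an inversion must not straddle a translocation breakpoint
        clear <- !any(tr_bp$chrom == slots$chrom[i] &
                        tr_bp$pos > slots$pos[i] - slot_step &
                        tr_bp$pos < slots$pos[i] + inversion_len + slot_step)
        fits && clear
      }))
      if (!length(ok)) stop("no room for an inversion of ", inversion_len,
                            " bp", call. = FALSE)
      i <- sample(ok, 1)
      chrom <- slots$chrom[i]; pos <- slots$pos[i]
      ops[[length(ops) + 1L]] <- edit_ops("inversion", chrom, pos,
                                          pos + inversion_len)
      slots <- drop_near(slots, chrom, pos - slot_step,
                         pos + inversion_len + slot_step)
    }
    if (nrow(slots) < n) {
      stop("not enough genome for ", n, " operations at spacing ", spacing,
           call. = FALSE)
    }
    pick <- slots[sort(sample.int(nrow(slots), n)), ]
    for (i in seq_len(n)) {
      cls <- classes[i]
      chrom <- pick$chrom[i]; pos <- pick$pos[i]
      if (cls == "te_insertion") {
        sz <- sample(te_size_range[1]:te_size_range[2], 1)
        fam <- if (length(ancestor$te_consensus)) {
          sample(names(ancestor$te_consensus), 1)
        } else NA_character_
        ops[[length(ops) + 1L]] <- edit_ops("te_insertion", chrom, pos,
                                            payload_len = sz, te_family = fam)
      } else {
        sz <- sample(size_range[1]:size_range[2], 1)
        if (cls %in% c("insertion", "repeat_expansion")) {
          ops[[length(ops) + 1L]] <- edit_ops(cls, chrom, pos,
                                              payload_len = sz)
        } else {
          # deletions remove [pos, pos+sz); a tandem expansion duplicates it
          ops[[length(ops) + 1L]] <- edit_ops(cls, chrom, pos, pos + sz)
        }
      }
    }
    script <- dplyr::bind_rows(ops)
    if (!is.null(translocation)) {
      script <- dplyr::bind_rows(script, edit_ops(
        "reciprocal_translocation", translocation$chrom1,
        translocation$pos1, translocation$pos1,
        payload_len = 1L,
        chrom2 = translocation$chrom2, pos2 = translocation$pos2))
    }
    script
  })
}
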
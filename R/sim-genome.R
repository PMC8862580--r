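# Two-ecotype genome simulator: an ancestor sequence is edited by two scripts
# of structural operations into a derived genome pair; every edit is recorded
# in a monotone coordinate map so truth can be lifted into either genome.

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic ancestral genome with gene and TE annotation
#'
#' Draws i.i.d. bases at the requested GC content, places non-overlapping gene
#' models (1--6 exons each, echoing the typical 4-ish exons per gene of plant
#' annotations) uniformly along the chromosomes, and stamps in TE copies drawn
#' from per-family consensus motifs with 1--5 % per-base divergence until the
#' requested genomic TE density is reached.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_lengths Integer vector of chromosome lengths (bp).
#' @param n_genes Total number of gene models to place.
#' @param te_families Number of TE families.
#' @param te_density Target fraction of the genome covered by TE copies.
#' @param gc GC content in (0, 1).
#' @param seed Integer seed; identical seeds give identical genomes.
#' @return A list with `genome` (named character vector), `genes`, `exons`,
#'   `tes` (feature tibbles) and `te_consensus` (named character vector).
#' @examples
#' anc <- generate_ancestor(1, 2e5, n_genes = 10, seed = 1)
#' names(anc$genome)
#' @export
generate_ancestor <- function(n_chrom = 2, chrom_lengths = rep(500000, n_chrom),
                              n_genes = 100, te_families = 3,
                              te_density = 0.1, gc = 0.4, seed = 1) {
  stopifnot(length(chrom_lengths) == n_chrom, gc > 0, gc < 1)
  withr::with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    genome <- stats::setNames(
      vapply(chrom_lengths, random_seq, "", gc = gc), chroms)

    # gene placement: uniform, non-overlapping, proportional to chrom length
    gene_tbl <- list(); exon_tbl <- list()
    n_per <- round(n_genes * chrom_lengths / sum(chrom_lengths))
    n_per[n_chrom] <- n_genes - sum(n_per[-n_chrom])
    gi <- 0L
    for (ci in seq_len(n_chrom)) {
      placed <- integer(0); placed_end <- integer(0)
      tries <- 0L
      while (length(placed) < n_per[ci]) {
        if (tries > 200L * n_per[ci] + 1000L) {
          stop("could not place ", n_per[ci], " genes on ", chroms[ci],
               " without overlap; lower gene density", call. = FALSE)
        }
        tries <- tries + 1L
        len <- sample(800:4000, 1)
        s <- sample.int(max(1L, chrom_lengths[ci] - len), 1) - 1L
        if (any(s < placed_end & s + len > placed)) next
        placed <- c(placed, s); placed_end <- c(placed_end, s + len)
        gi <- gi + 1L
        id <- sprintf("g%04d", gi)
        strand <- sample(c("+", "-"), 1)
        gene_tbl[[gi]] <- tibble::tibble(
          chrom = chroms[ci], start = s, end = s + len, strand = strand,
          kind = "gene", feature_id = id, attrs = "")
        exon_tbl[[gi]] <- make_exons(chroms[ci], s, s + len, strand, id)
      }
    }
    genes <- if (length(gene_tbl)) {
      dplyr::arrange(dplyr::bind_rows(gene_tbl), .data$chrom, .data$start)
    } else {
      empty_feature_tbl()
    }
    exons <- if (length(exon_tbl)) {
      dplyr::arrange(dplyr::bind_rows(exon_tbl), .data$chrom, .data$start)
    } else {
      empty_feature_tbl()
    }

    # TE families and copies
    te_consensus <- character(0)
    tes <- empty_feature_tbl()
    if (te_density > 0 && te_families > 0) {
      fam_len <- sample(500:3000, te_families, replace = TRUE)
      te_consensus <- stats::setNames(
        vapply(fam_len, random_seq, "", gc = gc),
        paste0("TEfam", seq_len(te_families)))
      total <- sum(chrom_lengths)
      target_bp <- te_density * total
      te_rows <- list(); covered <- 0; ti <- 0L
      occ <- lapply(seq_len(n_chrom), function(i) {
        cbind(start = integer(0), end = integer(0))
      })
      tries <- 0L
      while (covered < target_bp) {
        if (tries > 20000L) {
          stop("could not reach TE density ", te_density,
               " without overlap; lower density", call. = FALSE)
        }
        tries <- tries + 1L
        fam <- sample(te_families, 1)
        copy <- mutate_seq(te_consensus[[fam]], stats::runif(1, 0.01, 0.05))
        len <- nchar(copy)
        ci <- sample(n_chrom, 1, prob = chrom_lengths)
        if (chrom_lengths[ci] <= len + 2L) next
        s <- sample.int(chrom_lengths[ci] - len, 1) - 1L
        o <- occ[[ci]]
        if (nrow(o) && any(s < o[, "end"] & s + len > o[, "start"])) next
        occ[[ci]] <- rbind(o, c(s, s + len))
        substr(genome[[ci]], s + 1L, s + len) <- copy
        ti <- ti + 1L
        te_rows[[ti]] <- tibble::tibble(
          chrom = chroms[ci], start = s, end = s + len, strand = "+",
          kind = "TE", feature_id = sprintf("te%04d", ti),
          attrs = paste0("family=", names(te_consensus)[fam]))
        covered <- covered + len
      }
      tes <- dplyr::arrange(dplyr::bind_rows(te_rows), .data$chrom, .data$start)
    }
    list(genome = genome, genes = genes, exons = exons, tes = tes,
         te_consensus = te_consensus)
  })
}

make_exons <- function(chrom, s, e, strand, gene_id) {
  len <- e - s
  n_ex <- sample(1:6, 1)
  # alternating exon/intron chunks; shrink exon count until minimum widths fit
  while (n_ex > 1 && len < n_ex * 80L + (n_ex - 1L) * 40L) n_ex <- n_ex - 1L
  if (n_ex == 1) {
    return(tibble::tibble(chrom = chrom, start = s, end = e, strand = strand,
                          kind = "exon",
                          feature_id = paste0(gene_id, ".e1"),
                          attrs = paste0("Parent=", gene_id)))
  }
  n_chunk <- 2L * n_ex - 1L
  mins <- ifelse(seq_len(n_chunk) %% 2L == 1L, 80L, 40L)
  extra <- len - sum(mins)
  w <- as.vector(stats::rmultinom(1, extra, rep(1, n_chunk)))
  widths <- mins + w
  bounds <- s + cumsum(c(0L, widths))
  ex_idx <- which(seq_len(n_chunk) %% 2L == 1L)
  tibble::tibble(
    chrom = chrom, start = bounds[ex_idx], end = bounds[ex_idx + 1L],
    strand = strand, kind = "exon",
    feature_id = paste0(gene_id, ".e", seq_along(ex_idx)),
    attrs = paste0("Parent=", gene_id))
}

mutate_seq <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  }
  paste(chars, collapse = "")
}

#' Construct an edit-operation table
#'
#' One row per planted structural operation. `anc_pos`/`anc_end` are ancestor
#' coordinates (0-based half-open); insertion-like operations use `anc_end =
#' anc_pos` and carry `payload_len`. A `reciprocal_translocation` row names the
#' two breakpoints via (`anc_chrom`, `anc_pos`) and (`chrom2`, `pos2`).
#'
#' @param op_type One of `insertion`, `deletion`, `tandem_expansion`,
#'   `tandem_contraction`, `repeat_expansion`, `repeat_contraction`,
#'   `inversion`, `reciprocal_translocation`, `te_insertion`.
#' @param anc_chrom,anc_pos,anc_end Ancestor anchor locus.
#' @param payload_len Inserted/deleted length in bp.
#' @param te_family TE family for `te_insertion` rows.
#' @param te_frac Fraction of a TE-insertion payload annotated as TE.
#' @param chrom2,pos2 Second breakpoint of a reciprocal translocation.
#' @return An edit-op tibble.
#' @export
edit_ops <- function(op_type = character(), anc_chrom = character(),
                     anc_pos = integer(), anc_end = anc_pos,
                     payload_len = anc_end - anc_pos,
                     te_family = NA_character_, te_frac = 1,
                     chrom2 = NA_character_, pos2 = NA_integer_) {
  tibble::tibble(
    op_type = op_type, anc_chrom = anc_chrom,
    anc_pos = as.integer(anc_pos), anc_end = as.integer(anc_end),
    payload_len = as.integer(payload_len),
    te_family = te_family, te_frac = te_frac,
    chrom2 = chrom2, pos2 = as.integer(pos2))
}

ins_like <- c("insertion", "te_insertion", "repeat_expansion",
              "tandem_expansion")
del_like <- c("deletion", "repeat_contraction", "tandem_contraction")
gap_classes <- c("insertion", "deletion", "repeat_expansion",
                 "repeat_contraction", "tandem_expansion", "tandem_contraction")

validate_edit_script <- function(script, ancestor) {
  if (!nrow(script)) return(invisible(script))
  if (sum(script$op_type == "reciprocal_translocation") > 1L) {
    stop("at most one reciprocal_translocation per edit script", call. = FALSE)
  }
  lens <- nchar(ancestor$genome)
  reg <- dplyr::filter(script, .data$op_type != "reciprocal_translocation")
  if (any(reg$payload_len < 1L)) {
    stop("payload_len must be >= 1 for every operation", call. = FALSE)
  }
  for (chrom in unique(reg$anc_chrom)) {
    ops <- dplyr::arrange(dplyr::filter(reg, .data$anc_chrom == chrom),
                          .data$anc_pos)
    if (any(ops$anc_end > lens[[chrom]])) {
      stop("operation beyond end of ", chrom, call. = FALSE)
    }
    s <- ops$anc_pos
    e <- pmax(ops$anc_end, ops$anc_pos + 1L)  # points widened for overlap test
    if (nrow(ops) > 1L && any(s[-1] < e[-nrow(ops)])) {
      i <- which(s[-1] < e[-nrow(ops)])[1]
      stop("overlapping operations on ", chrom, ": rows with anc_pos ",
           ops$anc_pos[i], " and ", ops$anc_pos[i + 1], call. = FALSE)
    }
  }
  invisible(script)
}

# Apply one edit script to the ancestor. Returns the derived genome, the
# segment map (anc <-> derived), and payload intervals keyed by op row.
apply_edit_script <- function(ancestor, script, genome_id) {
  lens <- nchar(ancestor$genome)
  validate_edit_script(script, ancestor)
  script$op_id <- if (nrow(script)) {
    paste0(genome_id, "_op", seq_len(nrow(script)))
  } else {
    character(0)
  }
  trans <- dplyr::filter(script, .data$op_type == "reciprocal_translocation")
  reg <- dplyr::filter(script, .data$op_type != "reciprocal_translocation")

  genome <- character(0)
  segs <- list()
  for (chrom in names(ancestor$genome)) {
    anc_seq <- ancestor$genome[[chrom]]
    ops <- dplyr::arrange(
      dplyr::filter(reg, .data$anc_chrom == chrom), .data$anc_pos)
    parts <- character(0)
    cur_anc <- 0L; cur_der <- 0L
    push_aligned <- function(upto) {
      if (upto > cur_anc) {
        n <- upto - cur_anc
        parts[[length(parts) + 1L]] <<- substr(anc_seq, cur_anc + 1L, upto)
        segs[[length(segs) + 1L]] <<- tibble::tibble(
          anc_chrom = chrom, anc_start = cur_anc, anc_end = upto,
          der_chrom = chrom, der_start = cur_der, der_end = cur_der + n,
          orientation = "+", tag = "aligned", op_id = NA_character_)
        cur_anc <<- upto; cur_der <<- cur_der + n
      }
    }
    if (nrow(ops)) {
      for (k in seq_len(nrow(ops))) {
        op <- ops[k, ]
        if (op$op_type %in% ins_like) {
          # insertion point: after anc_end for tandem copies, at anc_pos else
          at <- if (op$op_type == "tandem_expansion") op$anc_end else op$anc_pos
          push_aligned(at)
          payload <- switch(
            op$op_type,
            insertion = random_seq(op$payload_len),
            te_insertion = te_payload(ancestor, op),
            repeat_expansion = rep_payload(anc_seq, op),
            tandem_expansion = substr(anc_seq, op$anc_pos + 1L, op$anc_end))
          n <- nchar(payload)
          parts[[length(parts) + 1L]] <- payload
          segs[[length(segs) + 1L]] <- tibble::tibble(
            anc_chrom = chrom, anc_start = at, anc_end = at,
            der_chrom = chrom, der_start = cur_der, der_end = cur_der + n,
            orientation = "+", tag = "inserted", op_id = op$op_id)
          cur_der <- cur_der + n
        } else if (op$op_type %in% del_like) {
          push_aligned(op$anc_pos)
          segs[[length(segs) + 1L]] <- tibble::tibble(
            anc_chrom = chrom, anc_start = op$anc_pos, anc_end = op$anc_end,
            der_chrom = chrom, der_start = cur_der, der_end = cur_der,
            orientation = "+", tag = "deleted", op_id = op$op_id)
          cur_anc <- op$anc_end
        } else if (op$op_type == "inversion") {
          push_aligned(op$anc_pos)
          n <- op$anc_end - op$anc_pos
          parts[[length(parts) + 1L]] <-
            revcomp(substr(anc_seq, op$anc_pos + 1L, op$anc_end))
          segs[[length(segs) + 1L]] <- tibble::tibble(
            anc_chrom = chrom, anc_start = op$anc_pos, anc_end = op$anc_end,
            der_chrom = chrom, der_start = cur_der, der_end = cur_der + n,
            orientation = "-", tag = "aligned", op_id = op$op_id)
          cur_anc <- op$anc_end; cur_der <- cur_der + n
        }
      }
    }
    push_aligned(lens[[chrom]])
    genome[[chrom]] <- paste(parts, collapse = "")
  }
  map <- dplyr::bind_rows(segs)

  if (nrow(trans)) {
    tr <- trans[1, ]
    res <- apply_translocation(genome, map, tr)
    genome <- res$genome
    map <- res$map
  }
  list(genome = genome, map = map, script = script)
}

te_payload <- function(ancestor, op) {
  fam <- op$te_family
  if (is.na(fam) || !fam %in% names(ancestor$te_consensus)) {
    base <- random_seq(op$payload_len)
    return(base)
  }
  cons <- ancestor$te_consensus[[fam]]
  reps <- ceiling(op$payload_len / nchar(cons))
  mutate_seq(substr(strrep(cons, reps), 1L, op$payload_len),
             stats::runif(1, 0.01, 0.05))
}

rep_payload <- function(anc_seq, op) {
  # repeat expansion payload: copies of the sequence just left of the site
  unit <- max(50L, min(op$payload_len, 200L))
  src_s <- max(0L, op$anc_pos - unit)
  unit_seq <- substr(anc_seq, src_s + 1L, op$anc_pos)
  if (!nchar(unit_seq)) unit_seq <- random_seq(unit)
  reps <- ceiling(op$payload_len / nchar(unit_seq))
  substr(strrep(unit_seq, reps), 1L, op$payload_len)
}

apply_translocation <- function(genome, map, tr) {
  c1 <- tr$anc_chrom; c2 <- tr$chrom2
  if (is.na(c2)) stop("reciprocal_translocation needs chrom2/pos2", call. = FALSE)
  bp1 <- lift_point(map, c1, tr$anc_pos)
  bp2 <- lift_point(map, c2, tr$pos2)
  if (is.na(bp1$pos) || is.na(bp2$pos)) {
    stop("translocation breakpoint falls in deleted sequence", call. = FALSE)
  }
  s1 <- genome[[c1]]; s2 <- genome[[c2]]
  genome[[c1]] <- paste0(substr(s1, 1L, bp1$pos), substr(s2, bp2$pos + 1L, nchar(s2)))
  genome[[c2]] <- paste0(substr(s2, 1L, bp2$pos), substr(s1, bp1$pos + 1L, nchar(s1)))
  map <- split_map_at(map, c1, bp1$pos)
  map <- split_map_at(map, c2, bp2$pos)
  reassign <- function(map, from, bp_from, to, bp_to) {
    hit <- map$der_chrom == from & map$der_start >= bp_from
    map$der_chrom[hit] <- paste0(to, "*")  # temp tag to avoid double move
    map$der_start[hit] <- map$der_start[hit] - bp_from + bp_to
    map$der_end[hit] <- map$der_end[hit] - bp_from + bp_to
    map
  }
  map <- reassign(map, c1, bp1$pos, c2, bp2$pos)
  map <- reassign(map, c2, bp2$pos, c1, bp1$pos)
  map$der_chrom <- sub("\\*$", "", map$der_chrom)
  map$op_id[map$tag == "aligned" & is.na(map$op_id) &
              (map$der_chrom != map$anc_chrom)] <- tr$op_id
  list(genome = genome, map = map)
}

# split aligned segments of a derived chromosome at derived position `pos`
split_map_at <- function(map, der_chrom, pos) {
  hit <- which(map$der_chrom == der_chrom & map$der_start < pos &
                 map$der_end > pos)
  if (!length(hit)) return(map)
  out <- list()
  for (i in seq_len(nrow(map))) {
    row <- map[i, ]
    if (!i %in% hit) { out[[length(out) + 1L]] <- row; next }
    if (row$orientation == "-") {
      stop("translocation breakpoint inside an inverted segment is not supported",
           call. = FALSE)
    }
    off <- pos - row$der_start
    left <- row; right <- row
    left$der_end <- pos; left$anc_end <- row$anc_start + off
    right$der_start <- pos; right$anc_start <- row$anc_start + off
    out[[length(out) + 1L]] <- left
    out[[length(out) + 1L]] <- right
  }
  dplyr::bind_rows(out)
}

# ---- liftover ---------------------------------------------------------------

# lift one ancestor point to derived coordinates through a segment map
lift_point <- function(map, anc_chrom, pos) {
  seg <- map[map$anc_chrom == anc_chrom & map$tag == "aligned" &
               map$anc_start <= pos & map$anc_end > pos, ]
  if (!nrow(seg)) {
    # allow the exclusive end of the final aligned segment
    seg <- map[map$anc_chrom == anc_chrom & map$tag == "aligned" &
                 map$anc_end == pos, ]
    if (nrow(seg)) {
      seg <- seg[which.max(seg$anc_end), ]
      der <- if (seg$orientation == "+") seg$der_end else seg$der_start
      return(list(chrom = seg$der_chrom, pos = der))
    }
    del <- map[map$anc_chrom == anc_chrom & map$tag == "deleted" &
                 map$anc_start <= pos & map$anc_end > pos, ]
    if (nrow(del)) return(list(chrom = NA_character_, pos = NA_integer_))
    return(list(chrom = NA_character_, pos = NA_integer_))
  }
  seg <- seg[1, ]
  der <- if (seg$orientation == "+") {
    seg$der_start + (pos - seg$anc_start)
  } else {
    seg$der_end - (pos - seg$anc_start)
  }
  list(chrom = seg$der_chrom, pos = der)
}

# lift an ancestor interval; liftable only when fully inside one aligned segment
lift_interval <- function(map, anc_chrom, start, end) {
  if (start == end) {
    p <- lift_point(map, anc_chrom, start)
    return(list(chrom = p$chrom, start = p$pos, end = p$pos,
                liftable = !is.na(p$pos)))
  }
  seg <- map[map$anc_chrom == anc_chrom & map$tag == "aligned" &
               map$anc_start <= start & map$anc_end >= end, ]
  if (!nrow(seg)) {
    return(list(chrom = NA_character_, start = NA_integer_,
                end = NA_integer_, liftable = FALSE))
  }
  seg <- seg[1, ]
  if (seg$orientation == "+") {
    s <- seg$der_start + (start - seg$anc_start)
    e <- seg$der_start + (end - seg$anc_start)
  } else {
    s <- seg$der_end - (end - seg$anc_start)
    e <- seg$der_end - (start - seg$anc_start)
  }
  list(chrom = seg$der_chrom, start = s, end = e, liftable = TRUE)
}

#' Lift a derived-genome point back to the ancestor
#'
#' Inverse direction of the simulator's coordinate map; positions inside
#' inserted payloads have no ancestor image and return `NA`.
#'
#' @param map Segment map from [derive_pair()] (`map1` or `map2`).
#' @param der_chrom,pos Derived chromosome and 0-based position.
#' @return List with `chrom` and `pos` (ancestor coordinates, or `NA`).
#' @export
lift_derived_to_ancestor <- function(map, der_chrom, pos) {
  seg <- map[map$der_chrom == der_chrom & map$tag == "aligned" &
               map$der_start <= pos & map$der_end > pos, ]
  if (!nrow(seg)) return(list(chrom = NA_character_, pos = NA_integer_))
  seg <- seg[1, ]
  anc <- if (seg$orientation == "+") {
    seg$anc_start + (pos - seg$der_start)
  } else {
    seg$anc_start + (seg$der_end - pos)
  }
  list(chrom = seg$anc_chrom, pos = anc)
}

lift_features <- function(map, features) {
  if (!nrow(features)) return(features)
  rows <- purrr::pmap(features, function(chrom, start, end, strand, kind,
                                         feature_id, attrs, ...) {
    lift <- lift_interval(map, chrom, start, end)
    if (!lift$liftable) return(NULL)
    tibble::tibble(chrom = lift$chrom, start = lift$start, end = lift$end,
                   strand = strand, kind = kind, feature_id = feature_id,
                   attrs = attrs)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty_feature_tbl())
  dplyr::arrange(out, .data$chrom, .data$start)
}

# ---- derive_pair ------------------------------------------------------------

#' Derive a diverged genome pair from an ancestor
#'
#' Applies two edit scripts to one ancestral genome, producing two derived
#' genomes, a segment map per genome (ancestor to derived, the basis for
#' liftover), lifted gene/exon/TE annotation for each genome, and a truth
#' table giving every planted operation's coordinates in both derived genomes.
#' Sequences are edited left to right through an explicit segment walk, so an
#' operation's coordinates are always interpreted in ancestor space.
#'
#' @param ancestor Result of [generate_ancestor()].
#' @param edit_script_1,edit_script_2 Edit-op tibbles (see [edit_ops()]);
#'   at most one `reciprocal_translocation` each.
#' @param seed Integer seed for the randomly drawn payload sequences.
#' @return A list of class `genome_pair`: `genome1`, `genome2`, `map1`, `map2`,
#'   per-genome annotations (`genes1`, `exons1`, `tes1`, ...2), and `truth`
#'   (one row per op with `g1_*`/`g2_*` lifted coordinates and liftability
#'   flags).
#' @export
derive_pair <- function(ancestor, edit_script_1 = edit_ops(),
                        edit_script_2 = edit_ops(), seed = 1) {
  d1 <- withr::with_seed(seed, apply_edit_script(ancestor, edit_script_1, "g1"))
  d2 <- withr::with_seed(seed + 1L,
                         apply_edit_script(ancestor, edit_script_2, "g2"))

  annotate_derived <- function(d) {
    genes <- lift_features(d$map, ancestor$genes)
    exons <- lift_features(d$map, ancestor$exons)
    tes <- lift_features(d$map, ancestor$tes)
    # TE insertions add annotation covering te_frac of their payload
    ins <- d$map[d$map$tag == "inserted" & !is.na(d$map$op_id), ]
    if (nrow(ins)) {
      ops <- d$script
      for (i in seq_len(nrow(ins))) {
        op <- ops[ops$op_id == ins$op_id[i], ]
        if (nrow(op) && op$op_type == "te_insertion") {
          te_bp <- round(op$te_frac * (ins$der_end[i] - ins$der_start[i]))
          if (te_bp > 0) {
            tes <- dplyr::bind_rows(tes, tibble::tibble(
              chrom = ins$der_chrom[i], start = ins$der_start[i],
              end = ins$der_start[i] + as.integer(te_bp), strand = "+",
              kind = "TE", feature_id = paste0("te_", op$op_id),
              attrs = paste0("family=", op$te_family)))
          }
        }
      }
      tes <- dplyr::arrange(tes, .data$chrom, .data$start)
    }
    list(genes = genes, exons = exons, tes = tes)
  }
  a1 <- annotate_derived(d1)
  a2 <- annotate_derived(d2)

  truth <- build_truth(d1, d2)
  structure(
    list(ancestor = ancestor,
         genome1 = d1$genome, genome2 = d2$genome,
         map1 = d1$map, map2 = d2$map,
         genes1 = a1$genes, exons1 = a1$exons, tes1 = a1$tes,
         genes2 = a2$genes, exons2 = a2$exons, tes2 = a2$tes,
         truth = truth),
    class = "genome_pair")
}

#' @export
print.genome_pair <- function(x, ...) {
  cat(sprintf("<genome_pair> %d chromosomes; genome1 %s bp, genome2 %s bp; %d planted ops\n",
              length(x$genome1),
              format(sum(nchar(x$genome1)), big.mark = ","),
              format(sum(nchar(x$genome2)), big.mark = ","),
              nrow(x$truth)))
  invisible(x)
}

build_truth <- function(d1, d2) {
  both <- dplyr::bind_rows(
    dplyr::mutate(d1$script, genome = 1L),
    dplyr::mutate(d2$script, genome = 2L))
  if (!nrow(both)) {
    return(tibble::tibble(
      op_id = character(), genome = integer(), op_type = character(),
      anc_chrom = character(), anc_pos = integer(), anc_end = integer(),
      payload_len = integer(), te_family = character(), te_frac = double(),
      chrom2 = character(), pos2 = integer(),
      g1_chrom = character(), g1_start = integer(), g1_end = integer(),
      g1_liftable = logical(),
      g2_chrom = character(), g2_start = integer(), g2_end = integer(),
      g2_liftable = logical()))
  }
  lift_one <- function(map, d, row) {
    # in the edited genome, insertion-like footprints are the payload interval
    own <- row$op_id %in% d$script$op_id
    if (own && row$op_type %in% ins_like) {
      seg <- d$map[!is.na(d$map$op_id) & d$map$op_id == row$op_id &
                     d$map$tag == "inserted", ]
      if (nrow(seg)) {
        return(list(chrom = seg$der_chrom[1], start = seg$der_start[1],
                    end = seg$der_end[1], liftable = TRUE))
      }
    }
    if (own && row$op_type %in% del_like) {
      seg <- d$map[!is.na(d$map$op_id) & d$map$op_id == row$op_id &
                     d$map$tag == "deleted", ]
      if (nrow(seg)) {
        return(list(chrom = seg$der_chrom[1], start = seg$der_start[1],
                    end = seg$der_start[1], liftable = TRUE))
      }
    }
    lift_interval(map, row$anc_chrom, row$anc_pos, row$anc_end)
  }
  res <- purrr::map(seq_len(nrow(both)), function(i) {
    row <- both[i, ]
    l1 <- lift_one(d1$map, d1, row)
    l2 <- lift_one(d2$map, d2, row)
    tibble::tibble(
      op_id = row$op_id, genome = row$genome, op_type = row$op_type,
      anc_chrom = row$anc_chrom, anc_pos = row$anc_pos, anc_end = row$anc_end,
      payload_len = row$payload_len, te_family = row$te_family,
      te_frac = row$te_frac, chrom2 = row$chrom2, pos2 = row$pos2,
      g1_chrom = l1$chrom, g1_start = l1$start, g1_end = l1$end,
      g1_liftable = l1$liftable,
      g2_chrom = l2$chrom, g2_start = l2$start, g2_end = l2$end,
      g2_liftable = l2$liftable)
  })
  dplyr::bind_rows(res)
}
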
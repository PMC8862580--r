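#' Read a whole-genome-alignment coordinate table
#'
#' Ingests the tab-separated coordinate table produced by `show-coords -T`
#' (or the 21-column btab layout of `show-coords -B`) into a tibble of
#' alignment blocks. File coordinates are 1-based inclusive; the returned
#' blocks use 0-based half-open intervals. Query rows printed with descending
#' coordinates (reverse-strand matches) are stored ascending with
#' `strand = "-"`.
#'
#' @param path Path to the coordinate table.
#' @param dialect `"show-coords-T"` (default) or `"btab"`.
#' @return A tibble of alignment blocks with columns `ref_chrom`, `ref_start`,
#'   `ref_end`, `qry_chrom`, `qry_start`, `qry_end`, `strand`, `pct_identity`,
#'   `is_unique_anchor`, sorted by `(ref_chrom, ref_start, ref_end)`.
#' @examples
#' f <- tempfile()
#' writeLines(c("NUCMER", "", "1\t500\t101\t580\t500\t480\t98.5\tchrA\tchrQ"), f)
#' read_alignment_coords(f)
#' @export
read_alignment_coords <- function(path, dialect = c("show-coords-T", "btab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (grepl("^(NUCMER|MUMMER|=+|/|\\[)", trimws(line))) next  # headers
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (dialect == "show-coords-T") {
      # S1 E1 S2 E2 LEN1 LEN2 %IDY [extra tags] REF QRY
      if (length(f) < 9) {
        stop("malformed coords row at line ", ln, ": expected >= 9 fields",
             call. = FALSE)
      }
      num <- suppressWarnings(as.numeric(f[1:4]))
      pid <- suppressWarnings(as.numeric(f[7]))
      if (anyNA(num) || is.na(pid)) {
        stop("malformed coords row at line ", ln, ": non-numeric coordinates",
             call. = FALSE)
      }
      rs <- num[1]; re <- num[2]; qs <- num[3]; qe <- num[4]
      ref_chrom <- f[length(f) - 1L]
      qry_chrom <- f[length(f)]
    } else {
      # show-coords -B: qry_id date qry_len program ref_file ref_id
      #   qry_start qry_end ref_start ref_end pct_id pct_sim ... (21 cols)
      if (length(f) < 12) {
        stop("malformed btab row at line ", ln, ": expected >= 12 fields",
             call. = FALSE)
      }
      num <- suppressWarnings(as.numeric(f[7:10]))
      pid <- suppressWarnings(as.numeric(f[11]))
      if (anyNA(num) || is.na(pid)) {
        stop("malformed btab row at line ", ln, ": non-numeric coordinates",
             call. = FALSE)
      }
      qs <- num[1]; qe <- num[2]; rs <- num[3]; re <- num[4]
      ref_chrom <- f[6]
      qry_chrom <- f[1]
    }
    if (re < rs) {
      warning("rejecting coords row at line ", ln,
              ": reference interval empty or descending")
      next
    }
    strand <- if (qe >= qs) "+" else "-"
    q_lo <- min(qs, qe)
    q_hi <- max(qs, qe)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      ref_chrom = ref_chrom,
      ref_start = as.integer(rs - 1), ref_end = as.integer(re),
      qry_chrom = qry_chrom,
      qry_start = as.integer(q_lo - 1), qry_end = as.integer(q_hi),
      strand = strand, pct_identity = pid
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    ref_chrom = character(), ref_start = integer(), ref_end = integer(),
    qry_chrom = character(), qry_start = integer(), qry_end = integer(),
    strand = character(), pct_identity = double()
  )
  out$is_unique_anchor <- rep(NA, nrow(out))
  dplyr::arrange(out, .data$ref_chrom, .data$ref_start, .data$ref_end)
}

#' Write alignment blocks as a show-coords -T style table
#'
#' Inverse of [read_alignment_coords()]: writes 1-based inclusive coordinates,
#' printing reverse-strand query intervals descending.
#'
#' @param blocks Tibble of alignment blocks.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_coords <- function(blocks, path) {
  header <- c("NUCMER", "",
              "[S1]\t[E1]\t[S2]\t[E2]\t[LEN 1]\t[LEN 2]\t[% IDY]\t[TAGS]")
  body <- purrr::pmap_chr(blocks, function(ref_chrom, ref_start, ref_end,
                                           qry_chrom, qry_start, qry_end,
                                           strand, pct_identity, ...) {
    q1 <- qry_start + 1L
    q2 <- qry_end
    if (strand == "-") { tmp <- q1; q1 <- q2; q2 <- tmp }
    paste(ref_start + 1L, ref_end, q1, q2,
          ref_end - ref_start, qry_end - qry_start,
          format(pct_identity, nsmall = 2), ref_chrom, qry_chrom, sep = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genomic features from GFF3 or BED
#'
#' Normalizes both formats to 0-based half-open tibble intervals. GFF3 type
#' tokens map to `kind` via `gene -> gene`, `exon -> exon`, any token in
#' `te_types -> TE`; everything else becomes `region`. Rows whose interval is
#' empty after normalization are rejected with a warning.
#'
#' @param path Path to the annotation file.
#' @param fmt `"gff3"` or `"bed"` (BED4; optional strand in column 6).
#' @param te_types Character vector of GFF3 type tokens to treat as TEs.
#' @return A feature tibble: `chrom`, `start`, `end`, `strand`, `kind`,
#'   `feature_id`, `attrs`.
#' @export
read_features <- function(path, fmt = c("gff3", "bed"),
                          te_types = c("transposable_element", "TE",
                                       "repeat_region", "mobile_element")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (!length(lines)) return(empty_feature_tbl())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (fmt == "gff3") {
      if (length(f) < 9) {
        warning("rejecting gff3 row ", i, ": fewer than 9 columns")
        next
      }
      start <- suppressWarnings(as.integer(f[4])) - 1L
      end <- suppressWarnings(as.integer(f[5]))
      type <- f[3]
      kind <- if (type == "gene") "gene"
      else if (type == "exon") "exon"
      else if (type %in% te_types) "TE"
      else "region"
      strand <- if (f[7] %in% c("+", "-")) f[7] else "."
      attrs <- f[9]
      id <- stringr::str_match(attrs, "ID=([^;]+)")[, 2]
      if (is.na(id)) id <- paste0("feat", i)
      chrom <- f[1]
    } else {
      if (length(f) < 3) {
        warning("rejecting bed row ", i, ": fewer than 3 columns")
        next
      }
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      kind <- "region"
      id <- if (length(f) >= 4) f[4] else paste0("feat", i)
      strand <- if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "."
      attrs <- ""
      chrom <- f[1]
    }
    if (is.na(start) || is.na(end) || start >= end) {
      warning("rejecting ", fmt, " row ", i, ": empty or invalid interval")
      next
    }
    rows[[i]] <- tibble::tibble(
      chrom = chrom, start = start, end = end, strand = strand,
      kind = kind, feature_id = id, attrs = attrs
    )
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty_feature_tbl())
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write features to GFF3 or BED
#'
#' @param features Feature tibble (see [read_features()]).
#' @param path Output path.
#' @param fmt `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, fmt = c("gff3", "bed")) {
  fmt <- match.arg(fmt)
  if (fmt == "gff3") {
    kind2type <- c(gene = "gene", exon = "exon", TE = "transposable_element",
                   region = "region")
    body <- purrr::pmap_chr(features, function(chrom, start, end, strand,
                                               kind, feature_id, attrs, ...) {
      at <- paste0("ID=", feature_id,
                   if (nzchar(attrs) && !startsWith(attrs, "ID=")) paste0(";", attrs) else "")
      paste(chrom, "svpair", kind2type[[kind]], start + 1L, end, ".",
            strand, ".", at, sep = "\t")
    })
    writeLines(c("##gff-version 3", body), path)
  } else {
    body <- purrr::pmap_chr(features, function(chrom, start, end, strand,
                                               kind, feature_id, ...) {
      paste(chrom, start, end, feature_id, 0L, strand, sep = "\t")
    })
    writeLines(body, path)
  }
  invisible(path)
}

# ---- SV table ---------------------------------------------------------------

sv_table_cols <- c("CHROM", "POS", "END", "SVTYPE", "SVLEN", "SUPPORT",
                   "FILTER", "QCHROM", "QPOS", "QEND", "SOURCE", "IS_PAV",
                   "CONTEXT", "IMPACT")

encode_support <- function(sup) {
  if (is.null(sup) || !length(sup)) return(".")
  paste(names(sup), unlist(sup), sep = ":", collapse = ";")
}

decode_support <- function(s) {
  if (is.na(s) || s == ".") return(integer())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  out <- as.integer(vapply(kv, `[`, "", 2))
  names(out) <- vapply(kv, `[`, "", 1)
  out
}

#' Write an SV call table
#'
#' Serializes calls to a minimal VCF-like tab-separated table with 1-based
#' `POS` and inclusive `END` (`END = POS - 1` marks a zero-length insertion
#' point). A [read_sv_table()] of the written file reproduces every field.
#'
#' @param calls SV call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(calls, path) {
  calls <- complete_sv_calls(calls)
  lines <- paste(sv_table_cols, collapse = "\t")
  if (nrow(calls)) {
    body <- purrr::pmap_chr(calls, function(sv_type, ref_chrom, ref_start,
                                            ref_end, qry_chrom, qry_start,
                                            qry_end, size, source, support,
                                            filter_status, is_pav, context,
                                            impact, ...) {
      na_dot <- function(x) ifelse(is.na(x), ".", as.character(x))
      paste(na_dot(ref_chrom), ref_start + 1L, ref_end, sv_type, size,
            encode_support(support), na_dot(filter_status),
            na_dot(qry_chrom),
            ifelse(is.na(qry_start), ".", qry_start + 1L), na_dot(qry_end),
            na_dot(source), na_dot(is_pav), na_dot(context), na_dot(impact),
            sep = "\t")
    })
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an SV call table
#'
#' Reads the table written by [write_sv_table()] (or any conforming minimal
#' VCF-like table with at least `CHROM POS END SVTYPE SVLEN SUPPORT FILTER`).
#' An unrecognized `SVTYPE` token raises an error naming the allowed types.
#'
#' @param path Path to the table.
#' @return SV call tibble.
#' @export
read_sv_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (!nrow(tab)) return(empty_sv_calls())
  bad <- setdiff(unique(tab$SVTYPE), sv_types())
  if (length(bad)) {
    stop("unknown SVTYPE token(s) ", paste(bad, collapse = ", "),
         "; allowed types: ", paste(sv_types(), collapse = ", "),
         call. = FALSE)
  }
  undot <- function(x) ifelse(x == ".", NA_character_, x)
  tibble::tibble(
    sv_type = tab$SVTYPE,
    ref_chrom = undot(tab$CHROM),
    ref_start = as.integer(tab$POS) - 1L,
    ref_end = as.integer(tab$END),
    qry_chrom = if ("QCHROM" %in% names(tab)) undot(tab$QCHROM) else NA_character_,
    qry_start = if ("QPOS" %in% names(tab)) {
      suppressWarnings(as.integer(tab$QPOS)) - 1L
    } else NA_integer_,
    qry_end = if ("QEND" %in% names(tab)) {
      suppressWarnings(as.integer(tab$QEND))
    } else NA_integer_,
    size = as.integer(tab$SVLEN),
    source = if ("SOURCE" %in% names(tab)) undot(tab$SOURCE) else NA_character_,
    support = purrr::map(tab$SUPPORT, decode_support),
    filter_status = undot(tab$FILTER),
    is_pav = if ("IS_PAV" %in% names(tab)) as.logical(undot(tab$IS_PAV)) else NA,
    context = if ("CONTEXT" %in% names(tab)) undot(tab$CONTEXT) else NA_character_,
    impact = if ("IMPACT" %in% names(tab)) undot(tab$IMPACT) else NA_character_
  )
}

# ---- Contact matrix ---------------------------------------------------------

#' Construct a binned contact-matrix record
#'
#' @param chrom Chromosome name.
#' @param counts Symmetric, non-negative numeric matrix of binned contacts.
#' @param bin_size Bin size in bp.
#' @param bin_mask Logical vector, `TRUE` for usable bins.
#' @return A list of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, counts, bin_size, bin_mask = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  stopifnot(ncol(counts) == n)
  if (any(counts < 0)) stop("contact counts must be non-negative", call. = FALSE)
  if (max(abs(counts - t(counts))) > 1e-8) {
    stop("contact matrix must be symmetric", call. = FALSE)
  }
  if (is.null(bin_mask)) bin_mask <- rep(TRUE, n)
  structure(
    list(chrom = chrom, bin_size = as.integer(bin_size), n_bins = n,
         counts = counts, bin_mask = bin_mask),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins of %d bp (%d masked)\n",
              x$chrom, x$n_bins, x$bin_size, sum(!x$bin_mask)))
  invisible(x)
}

#' Write a contact matrix as sparse triple text
#'
#' One header line `#chrom n_bins bin_size` followed by upper-triangle
#' `bin_i bin_j count` triples (0-based, `i <= j`, zero entries omitted).
#'
#' @param m A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  lines <- sprintf("#%s %d %d", m$chrom, m$n_bins, m$bin_size)
  if (nrow(idx)) {
    o <- order(idx[, 1], idx[, 2])
    idx <- idx[o, , drop = FALSE]
    vals <- m$counts[idx]
    lines <- c(lines, paste(idx[, 1] - 1L, idx[, 2] - 1L,
                            format(vals, scientific = FALSE, trim = TRUE)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sparse-triple contact matrix
#'
#' @param path Path written by [write_contact_matrix()] or conforming text:
#'   header `#chrom n_bins bin_size`, then `i j count` with `i <= j`.
#' @return A `contact_matrix` with the mirrored (symmetric) dense counts.
#' @export
read_contact_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], "#")) {
    stop("contact-matrix file must start with '#chrom n_bins bin_size'",
         call. = FALSE)
  }
  hdr <- strsplit(sub("^#", "", lines[1]), "\\s+")[[1]]
  chrom <- hdr[1]
  n_bins <- as.integer(hdr[2])
  bin_size <- as.integer(hdr[3])
  counts <- matrix(0, n_bins, n_bins)
  for (ln in seq_along(lines)[-1]) {
    f <- as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]])
    if (length(f) != 3 || anyNA(f)) {
      stop("malformed triple at line ", ln, call. = FALSE)
    }
    i <- f[1]; j <- f[2]; v <- f[3]
    if (i > j) stop("triple at line ", ln, " has i > j (i <= j required)",
                    call. = FALSE)
    if (v < 0) stop("negative count at line ", ln, call. = FALSE)
    if (i >= n_bins || j >= n_bins) {
      stop("bin index out of range at line ", ln, call. = FALSE)
    }
    counts[i + 1, j + 1] <- v
    counts[j + 1, i + 1] <- v
  }
  contact_matrix(chrom, counts, bin_size)
}

# ---- FASTA ------------------------------------------------------------------

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path (plain or line-wrapped).
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}
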
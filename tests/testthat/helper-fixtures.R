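# Shared fixture builders. Everything is generated in code at test time.

# a small two-chromosome pair with a handful of ops of every gap class
tiny_pair <- function(seed = 1, chrom_len = 300000, n_genes = 30,
                      with_rearrangements = TRUE) {
  anc <- generate_ancestor(2, c(chrom_len, chrom_len), n_genes = n_genes,
                           te_families = 2, te_density = 0.05, seed = seed)
  transloc <- if (with_rearrangements) {
    list(chrom1 = "chr1", pos1 = round(chrom_len * 0.65),
         chrom2 = "chr2", pos2 = round(chrom_len * 0.72))
  } else {
    NULL
  }
  counts <- c(insertion = 3, deletion = 3, repeat_expansion = 2,
              repeat_contraction = 2, tandem_expansion = 2,
              tandem_contraction = 2, te_insertion = 2,
              inversion = if (with_rearrangements) 1 else 0)
  script <- sample_edit_script(anc, counts = counts, spacing = 8000,
                               inversion_len = 30000,
                               translocation = transloc, seed = seed + 1)
  derive_pair(anc, edit_ops(), script)
}

# hand-built alignment blocks from a compact spec table
mk_blocks <- function(...) {
  df <- tibble::tribble(...)
  df$pct_identity <- df$pct_identity %||% rep(99, nrow(df))
  if (!"pct_identity" %in% names(df)) df$pct_identity <- 99
  if (!"strand" %in% names(df)) df$strand <- "+"
  df$is_unique_anchor <- NA
  df
}

# two consecutive anchors separated by the given gaps (strand +)
gap_blocks <- function(R_gap, Q_gap, anchor = 20000, ref0 = 0, qry0 = 0,
                       ref_chrom = "chr1", qry_chrom = "chr1") {
  l_re <- ref0 + anchor
  l_qe <- qry0 + anchor
  tibble::tibble(
    ref_chrom = ref_chrom,
    ref_start = c(ref0, l_re + R_gap),
    ref_end = c(l_re, l_re + R_gap + anchor),
    qry_chrom = qry_chrom,
    qry_start = c(qry0, l_qe + Q_gap),
    qry_end = c(l_qe, l_qe + Q_gap + anchor),
    strand = "+", pct_identity = 99, is_unique_anchor = NA)
}

feature_tbl <- function(chrom, start, end, strand = "+", kind = "gene",
                        feature_id = paste0(kind, seq_along(start)),
                        attrs = "") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, kind = kind,
                 feature_id = feature_id, attrs = attrs)
}

# a bare SV call row for merge/filter tests
mk_call <- function(sv_type = "deletion", chrom = "chr1", start = 1000,
                    end = 2000, size = end - start, support = c(s1 = 5),
                    filter = "PASS") {
  tibble::tibble(
    sv_type = sv_type, ref_chrom = chrom,
    ref_start = as.integer(start), ref_end = as.integer(end),
    qry_chrom = NA_character_, qry_start = NA_integer_, qry_end = NA_integer_,
    size = as.integer(size), source = "short_read",
    support = list(support), filter_status = filter, is_pav = TRUE,
    context = NA_character_, impact = NA_character_)
}

empty_sv_calls_for_test <- function() svpair:::empty_sv_calls()

# simple checkerboard compartment profile over one chromosome
mk_profile <- function(chrom = "chr1", n = 10, bin_size = 100000,
                       status = rep(c("A", "B"), length.out = n)) {
  starts <- (seq_len(n) - 1L) * bin_size
  tibble::tibble(
    chrom = chrom, bin = seq_len(n) - 1L,
    start = starts, end = starts + bin_size,
    value = ifelse(is.na(status), NA_real_, ifelse(status == "A", 1, -1)),
    status = status)
}
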
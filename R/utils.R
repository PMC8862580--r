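# Interval helpers. All internal coordinates are 0-based half-open [start, end).

# bp of overlap between [s1,e1) and [s2,e2); zero-length inputs give 0
interval_overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# does interval (or point, when start == end, widened to 1 bp) hit [s2, e2)?
interval_hits <- function(start, end, s2, e2) {
  end2 <- ifelse(end == start, start + 1L, end)
  interval_overlap_bp(start, end2, s2, e2) > 0
}

# merged (union) bp of a set of intervals clipped to [lo, hi)
merged_cover_bp <- function(starts, ends, lo, hi) {
  starts <- pmax(starts, lo)
  ends <- pmin(ends, hi)
  keep <- ends > starts
  if (!any(keep)) return(0)
  starts <- starts[keep]
  ends <- ends[keep]
  o <- order(starts, ends)
  starts <- starts[o]
  ends <- ends[o]
  total <- 0
  cur_s <- starts[1]
  cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]
      cur_e <- ends[i]
    } else {
      cur_e <- max(cur_e, ends[i])
    }
  }
  total + (cur_e - cur_s)
}

# remove all copies of `what` from x (setdiff drops duplicates of kept values)
setdiff_keep_dups <- function(x, what) x[x != what]

sv_types <- function() {
  c("insertion", "deletion", "repeat_expansion", "repeat_contraction",
    "tandem_expansion", "tandem_contraction", "inversion", "duplication",
    "translocation")
}

sv_contexts <- function() {
  c("exon", "splice_site", "transcript_ablation", "intron", "upstream",
    "downstream", "intergenic")
}

# empty call tibble with the full column set used across the package
empty_sv_calls <- function() {
  tibble::tibble(
    sv_type = character(), ref_chrom = character(),
    ref_start = integer(), ref_end = integer(),
    qry_chrom = character(), qry_start = integer(), qry_end = integer(),
    size = integer(), source = character(),
    support = list(), filter_status = character(), is_pav = logical(),
    context = character(), impact = character()
  )
}

# pad missing call columns with defaults so call sets from different sources bind
complete_sv_calls <- function(calls) {
  tmpl <- empty_sv_calls()
  for (nm in names(tmpl)) {
    if (!nm %in% names(calls)) {
      calls[[nm]] <- if (nm == "support") {
        rep(list(integer()), nrow(calls))
      } else if (is.character(tmpl[[nm]])) {
        NA_character_
      } else if (is.logical(tmpl[[nm]])) {
        NA
      } else {
        NA_integer_
      }
    }
  }
  dplyr::select(calls, dplyr::all_of(names(tmpl)), dplyr::everything())
}

empty_feature_tbl <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), kind = character(), feature_id = character(),
    attrs = character()
  )
}
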
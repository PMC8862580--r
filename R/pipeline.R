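# Config-driven pipeline wiring the modules into the full two-genome
# comparison workflow, with a provenance log and end-to-end determinism.

#' Default pipeline configuration
#'
#' Returns the full key set understood by [run_pipeline()]: simulator
#' settings (chromosome count/lengths, gene and TE density, per-class edit
#' counts, Hi-C parameters, short-read settings), every [sv_config()]
#' threshold, and the master `seed`. Writing this list as YAML gives a valid
#' config file.
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    outdir = "svpair_out",
    # simulator
    n_chrom = 2, chrom_length = 1000000, n_genes = 150, te_families = 3,
    te_density = 0.08, gc = 0.4,
    edits = list(insertion = 12, deletion = 12, repeat_expansion = 10,
                 repeat_contraction = 10, tandem_expansion = 10,
                 tandem_contraction = 10, te_insertion = 6, inversion = 1),
    sv_size_min = 60, sv_size_max = 2000, spacing = 15000,
    inversion_len = 60000,
    translocate = TRUE,
    breakpoint_jitter = 0,
    # Hi-C; switch_frac plants compartment-status switches in genome 2,
    # emulating the extensive A/B divergence seen between real ecotypes.
    # hic_bin_size is finer than the 100 kb analysis default because the
    # demo chromosomes are ~50x shorter than real ones: 25 kb bins keep the
    # per-chromosome bin count in the range eigenvector calling needs.
    hic_alpha = 1, hic_delta = 0.4, hic_base_c = 500, hic_visibility_sd = 0.2,
    switch_frac = 0.45, hic_bin_size = 25000,
    # short reads
    n_samples = 10, support_rate = 5, fp_count = 20, sr_jitter = 50,
    # thresholds (sv_config fields may all be overridden here)
    bin_size = 100000
  )
}

read_pipeline_config <- function(config) {
  defaults <- default_pipeline_config()
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), c(names(defaults), names(formals(sv_config))))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "\nvalid keys: ",
         paste(c(names(defaults), names(formals(sv_config))), collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user)
  cfg$sv <- as_sv_config(cfg)
  cfg
}

#' Run the comparison pipeline
#'
#' Runs the requested stage (and everything it depends on) of the synthetic
#' two-genome workflow: `simulate` writes genomes, annotations, the alignment
#' coordinate table, Hi-C matrices and short-read call sets plus truth tables;
#' `call-sv`, `call-te`, `compartments`, `synteny`, `switches`, `merge-sv` and
#' `concordance` each read their inputs from `outdir` and write their result
#' tables; `all` runs everything. Identical config and seed give byte-identical
#' outputs; a `provenance.txt` log records the seed, config hash and package
#' version.
#'
#' @param config Path to a YAML config file, or a named list (see
#'   [default_pipeline_config()]).
#' @param stage One of `simulate`, `call-sv`, `call-te`, `compartments`,
#'   `synteny`, `switches`, `merge-sv`, `concordance`, `all`.
#' @param outdir Output directory (overrides the config's `outdir`).
#' @return Invisibly, a named list of the stage results.
#' @export
run_pipeline <- function(config = list(),
                         stage = c("all", "simulate", "call-sv", "call-te",
                                   "compartments", "synteny", "switches",
                                   "merge-sv", "concordance"),
                         outdir = NULL) {
  stage <- match.arg(stage)
  cfg <- read_pipeline_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "call-sv", "call-te", "compartments", "synteny",
      "switches", "merge-sv", "concordance")
  } else {
    stage
  }
  res <- list()
  state <- new.env(parent = emptyenv())
  for (st in stages) {
    res[[st]] <- switch(
      st,
      "simulate" = stage_simulate(cfg, out, state),
      "call-sv" = stage_call_sv(cfg, out, state),
      "call-te" = stage_call_te(cfg, out, state),
      "compartments" = stage_compartments(cfg, out, state),
      "synteny" = stage_synteny(cfg, out, state),
      "switches" = stage_switches(cfg, out, state),
      "merge-sv" = stage_merge_sv(cfg, out, state),
      "concordance" = stage_concordance(cfg, out, state))
  }
  write_provenance(cfg, out, stages)
  invisible(res)
}

write_provenance <- function(cfg, out, stages) {
  cfg_flat <- cfg[setdiff(names(cfg), c("sv", "outdir"))]
  cfg_str <- paste(utils::capture.output(utils::str(cfg_flat)), collapse = "\n")
  hash <- sum(utf8ToInt(cfg_str) * (seq_len(nchar(cfg_str)) %% 997)) %% 1e9
  writeLines(c(
    sprintf("svpair %s", as.character(utils::packageVersion("svpair"))),
    sprintf("seed: %s", cfg$seed),
    sprintf("config_hash: %.0f", hash),
    sprintf("stages: %s", paste(stages, collapse = ","))),
    file.path(out, "provenance.txt"))
}

need_pair <- function(cfg, out, state) {
  if (!is.null(state$pair)) return(state$pair)
  f <- file.path(out, "pair.rds.unused")  # pair is always rebuilt from seed
  state$pair <- build_pair(cfg)
  state$pair
}

build_pair <- function(cfg) {
  anc <- generate_ancestor(
    n_chrom = cfg$n_chrom,
    chrom_lengths = rep(cfg$chrom_length, cfg$n_chrom),
    n_genes = cfg$n_genes, te_families = cfg$te_families,
    te_density = cfg$te_density, gc = cfg$gc, seed = cfg$seed)
  transloc <- NULL
  if (isTRUE(cfg$translocate) && cfg$n_chrom >= 2) {
    transloc <- list(chrom1 = "chr1", pos1 = round(cfg$chrom_length * 0.65),
                     chrom2 = "chr2", pos2 = round(cfg$chrom_length * 0.72))
  }
  script2 <- sample_edit_script(
    anc, counts = unlist(cfg$edits),
    size_range = c(cfg$sv_size_min, cfg$sv_size_max),
    spacing = cfg$spacing, inversion_len = cfg$inversion_len,
    translocation = transloc, seed = cfg$seed + 1)
  derive_pair(anc, edit_ops(), script2)
}

stage_simulate <- function(cfg, out, state) {
  pair <- need_pair(cfg, out, state)
  write_genome_fasta(pair$genome1, file.path(out, "genome1.fa"))
  write_genome_fasta(pair$genome2, file.path(out, "genome2.fa"))
  for (g in 1:2) {
    feats <- dplyr::bind_rows(pair[[paste0("genes", g)]],
                              pair[[paste0("exons", g)]],
                              pair[[paste0("tes", g)]])
    write_features(dplyr::arrange(feats, .data$chrom, .data$start),
                   file.path(out, sprintf("genome%d.gff3", g)), "gff3")
    write_features(pair[[paste0("tes", g)]],
                   file.path(out, sprintf("genome%d.te.bed", g)), "bed")
  }
  blocks <- simulate_alignment_blocks(pair, cfg$breakpoint_jitter,
                                      seed = cfg$seed + 2)
  write_alignment_coords(blocks, file.path(out, "alignment.coords"))
  readr::write_tsv(attr(blocks, "expected_calls"),
                   file.path(out, "truth_expected_calls.tsv"))
  readr::write_tsv(pair$truth, file.path(out, "truth_ops.tsv"))

  # Hi-C per genome: ancestor compartment truth lifted into each genome
  bin <- cfg$hic_bin_size
  anc_truth <- list()
  k <- 0L
  for (chrom in names(pair$ancestor$genome)) {
    k <- k + 1L
    n <- ceiling(nchar(pair$ancestor$genome[[chrom]]) / bin)
    sim0 <- simulate_contact_matrix(
      nchar(pair$ancestor$genome[[chrom]]), bin,
      hic_sim_params(cfg$hic_alpha, cfg$hic_delta, cfg$hic_base_c,
                     cfg$hic_visibility_sd, seed = cfg$seed + 10 + k))
    anc_truth[[chrom]] <- sim0$truth
  }
  truth_rows <- list()
  for (g in 1:2) {
    genome <- pair[[paste0("genome", g)]]
    map <- pair[[paste0("map", g)]]
    for (chrom in names(genome)) {
      k <- k + 1L
      ct <- lift_compartment_truth(map, anc_truth, chrom, nchar(genome[[chrom]]),
                                   bin)
      if (g == 2L && cfg$switch_frac > 0) {
        ct <- plant_switches(ct, cfg$switch_frac, seed = cfg$seed + 200 + k)
      }
      sim <- simulate_contact_matrix(
        nchar(genome[[chrom]]), bin,
        hic_sim_params(cfg$hic_alpha, cfg$hic_delta, cfg$hic_base_c,
                       cfg$hic_visibility_sd, seed = cfg$seed + 100 + k),
        compartment_truth = ct, chrom = chrom)
      write_contact_matrix(sim$matrix,
                           file.path(out, sprintf("hic_g%d_%s.txt", g, chrom)))
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        genome = g, chrom = chrom, bin = seq_along(ct) - 1L, truth = ct)
    }
  }
  readr::write_tsv(dplyr::bind_rows(truth_rows),
                   file.path(out, "truth_compartments.tsv"))

  callsets <- simulate_short_read_callset(
    pair, target_genome = 1, n_samples = cfg$n_samples,
    support_rate = cfg$support_rate, fp_count = cfg$fp_count,
    jitter = cfg$sr_jitter, seed = cfg$seed + 3)
  write_sv_table(callsets$callerA, file.path(out, "sr_callerA.tsv"))
  write_sv_table(callsets$callerB, file.path(out, "sr_callerB.tsv"))

  # gene anchor pairs for synteny: shared ancestor genes present in both
  shared <- intersect(pair$genes1$feature_id, pair$genes2$feature_id)
  readr::write_tsv(tibble::tibble(ref_gene = shared, qry_gene = shared),
                   file.path(out, "anchor_pairs.tsv"))
  invisible(pair)
}

require_input <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing input ", basename(path), "; run stage `", producer,
         "` first", call. = FALSE)
  }
  path
}

stage_call_sv <- function(cfg, out, state) {
  blocks <- read_alignment_coords(
    require_input(file.path(out, "alignment.coords"), "simulate"))
  anchors <- select_unique_anchors(blocks, cfg$sv)
  calls <- call_svs(anchors, cfg$sv)
  rearr <- detect_inversions_and_translocations(anchors)
  g1 <- read_features(file.path(out, "genome1.gff3"), "gff3")
  g2 <- read_features(file.path(out, "genome2.gff3"), "gff3")
  all_calls <- dplyr::bind_rows(calls, rearr)
  all_calls <- annotate_sv_context(
    all_calls, g1[g1$kind == "gene", ], g1[g1$kind == "exon", ],
    cfg$sv, side = "ref")
  all_calls <- annotate_sv_context(
    all_calls, g2[g2$kind == "gene", ], g2[g2$kind == "exon", ],
    cfg$sv, side = "qry")
  write_sv_table(all_calls, file.path(out, "wga_svs.tsv"))
  readr::write_tsv(summarize_sv_categories(all_calls),
                   file.path(out, "wga_sv_summary.tsv"))
  state$wga_calls <- all_calls
  invisible(all_calls)
}

stage_call_te <- function(cfg, out, state) {
  blocks <- read_alignment_coords(
    require_input(file.path(out, "alignment.coords"), "simulate"))
  anchors <- select_unique_anchors(blocks, cfg$sv)
  tes2 <- read_features(file.path(out, "genome2.te.bed"), "bed")
  tes2$kind <- "TE"
  calls <- call_te_insertions(anchors, tes2, cfg$sv)
  g1 <- read_features(file.path(out, "genome1.gff3"), "gff3")
  aff <- te_affected_genes(calls, g1[g1$kind == "gene", ], cfg$sv)
  te_only <- calls[calls$is_te_insertion, ]
  write_features(tibble::tibble(
    chrom = te_only$qry_chrom, start = te_only$qry_start,
    end = te_only$qry_end, strand = "+", kind = "region",
    feature_id = sprintf("tei%03d", seq_len(nrow(te_only))), attrs = ""),
    file.path(out, "te_insertions.bed"), "bed")
  writeLines(aff$genes, file.path(out, "te_affected_genes.txt"))
  state$te_calls <- calls
  invisible(list(calls = calls, affected = aff))
}

stage_compartments <- function(cfg, out, state) {
  files <- sort(list.files(out, pattern = "^hic_g[12]_.*\\.txt$",
                           full.names = TRUE))
  if (!length(files)) require_input(file.path(out, "hic_g1_chr1.txt"),
                                    "simulate")
  truth <- readr::read_tsv(file.path(out, "truth_compartments.tsv"),
                           show_col_types = FALSE)
  profiles <- list()
  for (f in files) {
    m <- read_contact_matrix(f)
    g <- as.integer(sub("^hic_g(\\d)_.*", "\\1", basename(f)))
    tr <- truth[truth$genome == g & truth$chrom == m$chrom, ]
    track <- tr$truth[order(tr$bin)]  # orientation track aligned with truth
    prof <- call_compartments(m, orientation_track = track)
    prof$genome <- g
    profiles[[length(profiles) + 1L]] <- prof
  }
  all_prof <- dplyr::bind_rows(profiles)
  readr::write_tsv(all_prof, file.path(out, "compartments.tsv"))
  state$profiles <- all_prof
  invisible(all_prof)
}

stage_synteny <- function(cfg, out, state) {
  pairs <- readr::read_tsv(
    require_input(file.path(out, "anchor_pairs.tsv"), "simulate"),
    show_col_types = FALSE)
  g1 <- read_features(file.path(out, "genome1.gff3"), "gff3")
  g2 <- read_features(file.path(out, "genome2.gff3"), "gff3")
  blocks <- chain_collinear_anchors(pairs, g1[g1$kind == "gene", ],
                                    g2[g2$kind == "gene", ])
  cls <- classify_block_rearrangements(blocks)
  readr::write_tsv(dplyr::select(cls$blocks, -"anchors"),
                   file.path(out, "syntenic_blocks.tsv"))
  readr::write_tsv(cls$pairing, file.path(out, "chromosome_pairing.tsv"))
  state$blocks <- cls
  invisible(cls)
}

stage_switches <- function(cfg, out, state) {
  if (is.null(state$profiles)) {
    state$profiles <- readr::read_tsv(
      require_input(file.path(out, "compartments.tsv"), "compartments"),
      show_col_types = FALSE)
  }
  blocks <- if (!is.null(state$blocks)) {
    state$blocks$blocks
  } else {
    readr::read_tsv(
      require_input(file.path(out, "syntenic_blocks.tsv"), "synteny"),
      show_col_types = FALSE)
  }
  prof <- state$profiles
  p1 <- prof[prof$genome == 1, ]
  p2 <- prof[prof$genome == 2, ]
  sw <- compartment_switch_summary(blocks, p1, p2, step = cfg$bin_size)
  readr::write_tsv(sw$totals, file.path(out, "switch_totals.tsv"))
  readr::write_tsv(sw$per_chromosome, file.path(out, "switch_per_chrom.tsv"))
  state$switches <- sw
  invisible(sw)
}

stage_merge_sv <- function(cfg, out, state) {
  a <- read_sv_table(require_input(file.path(out, "sr_callerA.tsv"),
                                   "simulate"))
  b <- read_sv_table(file.path(out, "sr_callerB.tsv"))
  merged <- merge_callsets(list(a, b), cfg$sv)
  kept <- filter_merged(merged, cfg$sv)
  write_sv_table(merged, file.path(out, "sr_merged.tsv"))
  write_sv_table(kept, file.path(out, "sr_filtered.tsv"))
  state$sr_filtered <- kept
  invisible(kept)
}

stage_concordance <- function(cfg, out, state) {
  if (is.null(state$wga_calls)) {
    state$wga_calls <- read_sv_table(
      require_input(file.path(out, "wga_svs.tsv"), "call-sv"))
  }
  if (is.null(state$sr_filtered)) {
    state$sr_filtered <- read_sv_table(
      require_input(file.path(out, "sr_filtered.tsv"), "merge-sv"))
  }
  pavs <- state$wga_calls[state$wga_calls$is_pav %in% TRUE, ]
  conc <- pav_concordance(pavs, state$sr_filtered, cfg$sv)
  readr::write_tsv(
    tibble::tibble(n_pavs = nrow(conc$calls),
                   n_confirmed = sum(conc$calls$confirmed),
                   fraction = conc$fraction),
    file.path(out, "pav_concordance.tsv"))
  state$concordance <- conc
  invisible(conc)
}
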
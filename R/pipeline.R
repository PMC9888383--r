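## Pipeline front-end tying the stages into the three headline analyses:
## occupancy classification, network construction/ranking, enhancer
## prioritization, and variant annotation. Each run_* function consumes a
## run_config of input paths plus parameters, writes its outputs under
## `out_dir`, serializes the effective configuration alongside them, and
## returns its main results invisibly. All runs are deterministic given the
## config and inputs.

#' Assemble a pipeline run configuration
#'
#' Every parameter has a documented default; the effective configuration is
#' serialized alongside each run's outputs.
#'
#' @param out_dir output directory.
#' @param peaks named character vector of the four peak BED paths
#'   (CM, SAN, AVN, VCS).
#' @param genome_fasta,pwm_file,gene_file,h3k27ac_beds,vista_bed,
#'   expression_file,contact_file,snp_file,block_map_file input paths as
#'   needed per stage.
#' @param cutoff_bp proximal/distal TSS cutoff (bp).
#' @param min_overlap_bp minimum overlap for presence calls.
#' @param min_score_bits PWM hit threshold (`NULL` = 0.8 of each PWM's
#'   maximum).
#' @param window_bp target-nomination window half-width.
#' @param enrichment_threshold expression-enrichment threshold.
#' @param genome_bp baseline genome size for landing frequencies.
#' @param seed seed recorded in the effective config (randomness lives only
#'   in the synthetic generator).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = ".", peaks = NULL, genome_fasta = NULL,
                       pwm_file = NULL, gene_file = NULL, h3k27ac_beds = NULL,
                       vista_bed = NULL, expression_file = NULL,
                       contact_file = NULL, snp_file = NULL,
                       block_map_file = NULL,
                       cutoff_bp = 2000, min_overlap_bp = 1,
                       min_score_bits = NULL, window_bp = 500000,
                       enrichment_threshold = 1.5, genome_bp = 2.7e9,
                       seed = 1) {
  structure(list(out_dir = out_dir, peaks = peaks, genome_fasta = genome_fasta,
                 pwm_file = pwm_file, gene_file = gene_file,
                 h3k27ac_beds = h3k27ac_beds, vista_bed = vista_bed,
                 expression_file = expression_file, contact_file = contact_file,
                 snp_file = snp_file, block_map_file = block_map_file,
                 cutoff_bp = cutoff_bp, min_overlap_bp = min_overlap_bp,
                 min_score_bits = min_score_bits, window_bp = window_bp,
                 enrichment_threshold = enrichment_threshold,
                 genome_bp = genome_bp, seed = seed),
            class = "run_config")
}

.require_inputs <- function(config, fields) {
  for (f in fields) {
    v <- config[[f]]
    if (is.null(v)) stop("run_config is missing required input: ", f)
    if (is.character(v) && !all(file.exists(v)))
      stop("input file not found for ", f, ": ", paste(v[!file.exists(v)], collapse = ", "))
  }
}

.write_effective_config <- function(config, stage) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config[!vapply(config, is.null, TRUE)]
  jsonlite::write_json(cfg, file.path(config$out_dir, paste0(stage, "_config.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

.read_peaks <- function(config) {
  if (length(config$peaks) != 4) stop("exactly 4 peak BEDs (CM, SAN, AVN, VCS) required")
  pk <- config$peaks
  if (is.null(names(pk))) names(pk) <- CCS_SAMPLES
  stats::setNames(lapply(CCS_SAMPLES, function(s) {
    x <- read_bed(pk[[s]], label = s)
    if (nrow(x) == 0) stop("empty peak BED for sample ", s, ": ", pk[[s]])
    x
  }), CCS_SAMPLES)
}

#' Run the occupancy classification stage
#'
#' Union of the four peak sets, presence matrix, category truth table and
#' summary; writes the occupancy TSV, one BED per category, and a summary
#' JSON.
#' @param config a `run_config` with `peaks` set.
#' @return invisibly, list with `occupancy` and `summary`.
#' @export
run_classify <- function(config) {
  .require_inputs(config, "peaks")
  samples <- .read_peaks(config)
  all_df <- do.call(rbind, lapply(samples, function(s) as.data.frame(s)[1:3]))
  master <- merge_intervals(interval_set(all_df, label = "master", normalize = FALSE))
  occ <- build_occupancy(master, samples, min_overlap_bp = config$min_overlap_bp)
  summ <- summarize_categories(occ)
  .write_effective_config(config, "classify")
  write_occupancy(occ, file.path(config$out_dir, "occupancy.tsv"))
  for (cat in CCS_CATEGORIES)
    export_category_regions(occ, cat,
                            file.path(config$out_dir,
                                      paste0("regions_", gsub(" ", "_", cat), ".bed")))
  jsonlite::write_json(list(n_regions = nrow(occ), counts = as.list(summ$counts),
                            fractions = as.list(summ$fractions),
                            open_closed = as.list(summ$open_closed)),
                       file.path(config$out_dir, "classify_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(occupancy = occ, summary = summ))
}

#' Run the network construction and TF-ranking stage
#'
#' Builds the motif-based network for each CCS component and for CM, ranks
#' TFs by connectivity gain, and writes edge/node TSVs plus the ranking TSV.
#' @param config a `run_config` with `peaks`, `genome_fasta`, `pwm_file`,
#'   `gene_file` set.
#' @return invisibly, list with `edges` (per component) and `rankings`.
#' @export
run_grn <- function(config) {
  .require_inputs(config, c("peaks", "genome_fasta", "pwm_file", "gene_file"))
  samples <- .read_peaks(config)
  genome <- read_genome_fasta(config$genome_fasta)
  pwms <- read_jaspar(config$pwm_file)
  genes <- read_gene_annotation(config$gene_file)
  .write_effective_config(config, "grn")
  edges <- stats::setNames(lapply(CCS_SAMPLES, function(s)
    suppressWarnings(build_grn(samples[[s]], genes, pwms, genome,
                               cutoff_bp = config$cutoff_bp,
                               min_score_bits = config$min_score_bits,
                               component = s))), CCS_SAMPLES)
  for (s in CCS_SAMPLES)
    write_network(edges[[s]],
                  file.path(config$out_dir, paste0("edges_", s, ".tsv")),
                  file.path(config$out_dir, paste0("nodes_", s, ".tsv")))
  rankings <- stats::setNames(lapply(c("SAN", "AVN", "VCS"), function(s) {
    r <- rank_tfs(edges[[s]], edges[["CM"]])
    utils::write.table(r, file.path(config$out_dir, paste0("tf_ranking_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    r
  }), c("SAN", "AVN", "VCS"))
  invisible(list(edges = edges, rankings = rankings))
}

#' Run the enhancer prioritization stage
#'
#' Candidate selection (distal, active-mark overlapping) per component,
#' validated-enhancer assignment, target nomination for every CCS-enriched
#' element, and the hit-rate Fisher comparison for user-supplied counts.
#' @param config a `run_config` with `peaks`, `gene_file`, `h3k27ac_beds`,
#'   `vista_bed`, `expression_file`, `contact_file` set.
#' @param hit_rate_counts optional numeric vector
#'   `c(observed_hits, observed_tested, control_hits, control_tested)` for
#'   the hit-rate JSON.
#' @return invisibly, list with `candidates`, `vista_assignment`,
#'   `nominations`, `hit_rate`.
#' @export
run_enhancers <- function(config, hit_rate_counts = NULL) {
  .require_inputs(config, c("peaks", "gene_file", "h3k27ac_beds", "vista_bed",
                            "expression_file", "contact_file"))
  samples <- .read_peaks(config)
  genes <- read_gene_annotation(config$gene_file)
  catalogs <- lapply(config$h3k27ac_beds, read_bed)
  vista <- read_bed(config$vista_bed, normalize = FALSE)
  expression <- read_expression_table(config$expression_file)
  contacts <- read_contacts(config$contact_file)
  .write_effective_config(config, "enhancers")
  cands <- stats::setNames(lapply(CCS_SAMPLES, function(s)
    select_candidate_enhancers(samples[[s]], genes, cutoff_bp = config$cutoff_bp,
                               h3k27ac_catalogs = catalogs)), CCS_SAMPLES)
  for (s in CCS_SAMPLES)
    write_bed(cands[[s]]$candidates,
              file.path(config$out_dir, paste0("candidates_", s, ".bed")))
  assignment <- assign_vista(lapply(cands, `[[`, "candidates"), vista)
  utils::write.table(assignment, file.path(config$out_dir, "vista_assignment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enriched <- assignment[assignment$ccs_enriched, , drop = FALSE]
  noms <- list()
  for (i in seq_len(nrow(enriched))) {
    comp <- intersect(c("SAN", "AVN", "VCS"),
                      strsplit(enriched$components[i], ",")[[1]])[1]
    nm <- nominate_targets(enriched[i, ], genes, window_bp = config$window_bp,
                           expression = expression, contacts = contacts,
                           component = comp,
                           enrichment_threshold = config$enrichment_threshold)
    if (nrow(nm)) noms[[length(noms) + 1L]] <- cbind(
      data.frame(vista_id = enriched$vista_id[i], component = comp,
                 stringsAsFactors = FALSE), nm)
  }
  nominations <- if (length(noms)) do.call(rbind, noms) else NULL
  if (!is.null(nominations))
    utils::write.table(nominations, file.path(config$out_dir, "nominations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  hr <- NULL
  if (!is.null(hit_rate_counts)) {
    hr <- hit_rate_comparison(hit_rate_counts[1], hit_rate_counts[2],
                              hit_rate_counts[3], hit_rate_counts[4])
    jsonlite::write_json(list(observed_hits = unname(hr$observed["hits"]),
                              observed_tested = unname(hr$observed["tested"]),
                              control_hits = unname(hr$control["hits"]),
                              control_tested = unname(hr$control["tested"]),
                              observed_pct = hr$observed_pct,
                              control_pct = hr$control_pct,
                              fisher_p = hr$fisher_p),
                         file.path(config$out_dir, "hit_rate.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(candidates = cands, vista_assignment = assignment,
                 nominations = nominations, hit_rate = hr))
}

#' Run the variant annotation stage
#'
#' Liftover with mapped/unmapped accounting, nested landing-frequency
#' enrichment with trend test, trait-by-component table, and optional
#' per-SNP allele-effect scoring.
#' @param config a `run_config` with `snp_file`, `block_map_file` and
#'   `peaks` (enhancer BEDs per sample: CM, SAN, AVN, VCS) set;
#'   `genome_fasta` and `pwm_file` enable allele-effect scoring.
#' @param allele_tf optional TF name from the PWM panel for allele scoring
#'   of every mapped SNP.
#' @return invisibly, list with `snps` (mapped table), `enrichment`,
#'   `trend`, `traits`, `allele_effects`.
#' @export
run_snps <- function(config, allele_tf = NULL) {
  .require_inputs(config, c("snp_file", "block_map_file", "peaks"))
  snps <- read_snp_table(config$snp_file)
  if (nrow(snps) == 0) stop("empty SNP table: ", config$snp_file)
  cmap <- read_block_map(config$block_map_file)
  sets <- .read_peaks(config)
  .write_effective_config(config, "snps")
  snps <- liftover_snps(snps, cmap)
  write_snp_table(snps, file.path(config$out_dir, "snps_mapped.tsv"))
  cm <- sets[["CM"]]
  ccs_df <- do.call(rbind, lapply(sets[c("SAN", "AVN", "VCS")],
                                  function(s) as.data.frame(s)[1:3]))
  ccs <- merge_intervals(interval_set(ccs_df, label = "CCS", normalize = FALSE))
  enr <- rbind(landing_frequency(snps, cm, genome_bp = config$genome_bp, label = "CM"),
               landing_frequency(snps, ccs, genome_bp = config$genome_bp, label = "CCS"))
  n_mapped <- sum(snps$mapped)
  genome_row <- data.frame(set_label = "genome", set_bp = config$genome_bp,
                           n_snps_total = n_mapped, n_snps_in_set = n_mapped,
                           landing_frequency = n_mapped / config$genome_bp,
                           baseline_frequency = n_mapped / config$genome_bp,
                           fold_vs_baseline = 1, stringsAsFactors = FALSE)
  enr_all <- rbind(genome_row, as.data.frame(enr))
  ## nested fold convention: CM vs genome, CCS additionally vs CM
  enr_all$fold_vs_cm <- enr_all$landing_frequency /
    enr_all$landing_frequency[enr_all$set_label == "CM"]
  trend <- enrichment_trend_test(enr_all)
  traits <- trait_component_analysis(snps, sets[c("SAN", "AVN", "VCS")], cm)
  jsonlite::write_json(list(
    n_snps = nrow(snps), n_mapped = n_mapped,
    baseline_frequency = n_mapped / config$genome_bp,
    enrichment = enr_all, p_trend = trend$p_trend,
    pairwise = trend$pairwise),
    file.path(config$out_dir, "snp_enrichment.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(enr_all, file.path(config$out_dir, "snp_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(traits))
    utils::write.table(traits, file.path(config$out_dir, "trait_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  ae <- NULL
  if (!is.null(allele_tf)) {
    .require_inputs(config, c("genome_fasta", "pwm_file"))
    genome <- read_genome_fasta(config$genome_fasta)
    p <- read_jaspar(config$pwm_file)[[allele_tf]]
    mapped <- snps[snps$mapped, , drop = FALSE]
    ae <- do.call(rbind, lapply(seq_len(nrow(mapped)), function(i) {
      eff <- allele_effect(p, genome, mapped[i, ], flank_bp = p$width)
      data.frame(snp_id = mapped$snp_id[i], tf_name = allele_tf,
                 best_ref_score = eff$best_ref_score,
                 best_alt_score = eff$best_alt_score,
                 delta_bits = eff$delta_bits, stringsAsFactors = FALSE)
    }))
    utils::write.table(ae, file.path(config$out_dir, "allele_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(snps = snps, enrichment = enr_all, trend = trend,
                 traits = traits, allele_effects = ae))
}

#' Run the synthetic-study generator as a pipeline stage
#' @param config a `run_config`; `out_dir` receives the generated files.
#' @param synth a `synth_config` (default uses `config$seed`).
#' @return invisibly, the simulation list from [simulate_study()].
#' @export
run_simulate <- function(config, synth = NULL) {
  if (is.null(synth)) synth <- synth_config(seed = config$seed)
  .write_effective_config(config, "simulate")
  invisible(simulate_study(synth, dir = config$out_dir))
}
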
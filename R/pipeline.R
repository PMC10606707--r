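## End-to-end orchestration: QC -> heterozygosity -> ROH catalog ->
## relationships -> AI-REML -> covariate -> per-segment scan -> summaries,
## from one flat configuration, with per-stage logging and a machine
## readable manifest of every parameter and seed used.

pipeline_defaults <- function() list(
  mode = "fixture",                 # "fixture" or "files"
  genotypes_prefix = NULL,
  genotype_format = "text",         # "text" or "binary"
  pedigree_file = NULL,
  phenotype_file = NULL,
  out_dir = "rohscan_out",
  seed = 1L,
  ## QC
  min_ind_call_rate = 0.95,
  min_snp_call_rate = 0.95,
  autosomes = NULL,                 # NULL = all chromosomes present
  ## ROH
  roh_min_snps = 16L,
  roh_max_het = 0L,
  roh_min_freq = 0.05,
  roh_max_freq = 0.95,
  ## relationships
  blend_alpha = 0.95,
  ## model
  scan_covariate = FALSE,
  scan_hys = TRUE,
  test_df = Inf,
  reml_tol = 1e-8,
  reml_max_iter = 200L,
  traits = c("tnb", "nba"),
  ## fixture mode: sim_config overrides (sim_* keys)
  sim = list())

#' Validate and normalize a pipeline configuration
#'
#' Accepts a named list, a YAML file path, or YAML text of flat
#' `key: value` pairs; fills defaults, checks ranges, and reports every
#' problem at once (with a nearest-key suggestion for unknown keys).
#' Fixture mode (`mode: fixture`) takes simulation parameters under
#' `sim_*` keys (or a `sim:` list); file mode (`mode: files`) requires
#' `genotypes_prefix`, `pedigree_file` and `phenotype_file` and forbids
#' `sim_*` keys.
#'
#' @param config A named list, a path to a YAML file, or YAML text.
#' @return A normalized `pipeline_config` list (every default filled).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (length(config) == 1L && file.exists(config))
      yaml::read_yaml(config) else yaml::yaml.load(paste(config, collapse = "\n"))
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a list, YAML file or YAML text")
  def <- pipeline_defaults()
  ## hoist sim_* keys into the sim sublist
  simkeys <- grep("^sim_", names(config), value = TRUE)
  sim <- config[["sim"]] %||% list()
  for (k in simkeys) sim[[sub("^sim_", "", k)]] <- config[[k]]
  config[simkeys] <- NULL
  config$sim <- NULL
  problems <- character(0)
  unknown <- setdiff(names(config), names(def))
  for (k in unknown) {
    sugg <- names(def)[which.min(utils::adist(k, names(def)))]
    problems <- c(problems,
                  sprintf("unknown key '%s' (did you mean '%s'?)", k, sugg))
  }
  cfg <- utils::modifyList(def, config[setdiff(names(config), unknown)])
  cfg$sim <- sim
  valid_sim <- names(formals(sim_config))
  bad_sim <- setdiff(names(sim), valid_sim)
  for (k in bad_sim) {
    sugg <- valid_sim[which.min(utils::adist(k, valid_sim))]
    problems <- c(problems,
                  sprintf("unknown key 'sim_%s' (did you mean 'sim_%s'?)",
                          k, sugg))
  }
  if (!cfg$mode %in% c("fixture", "files"))
    problems <- c(problems, "mode must be 'fixture' or 'files'")
  if (cfg$mode == "files") {
    for (k in c("genotypes_prefix", "pedigree_file", "phenotype_file"))
      if (is.null(cfg[[k]]))
        problems <- c(problems, sprintf("file mode requires '%s'", k))
    if (length(sim))
      problems <- c(problems, "sim_* keys are only valid in fixture mode")
  }
  for (k in c("min_ind_call_rate", "min_snp_call_rate"))
    if (cfg[[k]] < 0 || cfg[[k]] > 1)
      problems <- c(problems, sprintf("'%s' must lie in [0, 1]", k))
  if (cfg$roh_min_snps < 1)
    problems <- c(problems, "'roh_min_snps' must be positive")
  if (cfg$roh_min_freq > cfg$roh_max_freq)
    problems <- c(problems,
                  "carrier-frequency window empty: 'roh_min_freq' > 'roh_max_freq'")
  for (k in c("roh_min_freq", "roh_max_freq"))
    if (cfg[[k]] < 0 || cfg[[k]] > 1)
      problems <- c(problems, sprintf("'%s' must lie in [0, 1]", k))
  if (cfg$blend_alpha < 0 || cfg$blend_alpha > 1)
    problems <- c(problems, "'blend_alpha' must lie in [0, 1]")
  if (!all(tolower(cfg$traits) %in% c("tnb", "nba")))
    problems <- c(problems, "'traits' must be a subset of tnb, nba")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  cfg$traits <- tolower(cfg$traits)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log, line)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data loading (or simulation in fixture mode), QC,
#' heterozygosity, ROH run detection and shared-segment catalog,
#' relationship matrices, AI-REML variance components per trait, the
#' heterozygosity-covariate estimate, the per-segment carrier scan, and the
#' scan summaries. Each stage writes its table under `out_dir`, and a
#' `manifest.json` records every parameter, seed and stage count, so a rerun
#' with the identical configuration reproduces every output byte for byte.
#' On failure, outputs written so far are retained next to a `FAILED`
#' marker naming the stage and cause.
#'
#' @param config A `pipeline_config` from [validate_config()], or anything
#'   it accepts.
#' @return Invisibly, a list with every in-memory result (`qc`, `het`,
#'   `runs`, `catalog`, `summary`, `vc`, `covariate`, `scan`,
#'   `scan_summary`, `regions`, `manifest`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  stage <- "setup"
  manifest <- list(config = unclass(cfg)[setdiff(names(cfg), "sim")],
                   sim = cfg$sim, stages = list())
  res <- list()
  on_fail <- function(e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    ## ---- load or simulate
    stage <- "input"
    if (cfg$mode == "fixture") {
      scfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
      manifest$sim <- unclass(scfg)
      sim <- simulate_dataset(scfg, genotyped = "sows")
      gd <- sim$genotypes; ped <- sim$pedigree; phen <- sim$phenotypes
      res$sim_truth <- sim$truth
      log <- stage_log(log, stage, sprintf(
        "simulated %d pedigree members, %d genotyped sows, %d records",
        nrow(ped), length(gd$samples), nrow(phen)))
    } else {
      gd <- read_plink(cfg$genotypes_prefix, cfg$genotype_format)
      ped <- read_pedigree(cfg$pedigree_file)
      phen <- read_phenotypes(cfg$phenotype_file)
      log <- stage_log(log, stage, sprintf(
        "read %d samples x %d markers, %d pedigree members, %d records",
        length(gd$samples), nrow(gd$map), nrow(ped), nrow(phen)))
    }
    ## ---- QC + imputation
    stage <- "qc"
    gd <- qc_filter(gd, cfg$min_ind_call_rate, cfg$min_snp_call_rate,
                    autosomes = cfg$autosomes)
    gd <- impute_mode(gd)
    writeLines(gd$provenance, file.path(cfg$out_dir, "qc_report.txt"))
    phen <- phen[phen$sow %in% gd$samples, , drop = FALSE]
    class(phen) <- c("phenotype_table", "data.frame")
    manifest$stages$qc <- list(n_samples = length(gd$samples),
                               n_markers = nrow(gd$map),
                               n_records = nrow(phen))
    log <- stage_log(log, stage, sprintf(
      "%d samples x %d markers after QC; %d records retained",
      length(gd$samples), nrow(gd$map), nrow(phen)))
    ## ---- heterozygosity
    stage <- "heterozygosity"
    het <- heterozygosity_percent(gd)
    data.table::fwrite(data.table::data.table(sample_id = names(het),
                                              het_pct = het),
                       file.path(cfg$out_dir, "heterozygosity.tsv"),
                       sep = "\t")
    log <- stage_log(log, stage, sprintf("mean heterozygosity %.2f%%",
                                         mean(het)))
    ## ---- ROH catalog
    stage <- "roh"
    runs <- detect_runs(gd, min_snps = cfg$roh_min_snps,
                        max_het = cfg$roh_max_het)
    catalog <- build_catalog(runs, gd, cfg$roh_min_freq, cfg$roh_max_freq)
    summ <- summarize_catalog(runs, gd)
    data.table::fwrite(runs, file.path(cfg$out_dir, "runs.tsv"), sep = "\t")
    data.table::fwrite(catalog$segments,
                       file.path(cfg$out_dir, "catalog.tsv"), sep = "\t")
    data.table::fwrite(
      data.table::data.table(sample_id = names(summ$coverage_pct),
                             coverage_pct = summ$coverage_pct),
      file.path(cfg$out_dir, "coverage.tsv"), sep = "\t")
    manifest$stages$roh <- list(n_runs = summ$n_runs,
                                n_segments = nrow(catalog$segments),
                                mean_coverage_pct = mean(summ$coverage_pct),
                                mean_run_snps = unname(summ$snp_stats["mean"]))
    log <- stage_log(log, stage, sprintf(
      "%d runs; %d shared segments; mean genome coverage %.1f%%",
      summ$n_runs, nrow(catalog$segments), mean(summ$coverage_pct)))
    ## ---- relationships
    stage <- "relationships"
    hinv <- h_inverse(ped, gd, genotyped_ids = gd$samples,
                      blend_alpha = cfg$blend_alpha)
    log <- stage_log(log, stage, sprintf(
      "H-inverse over %d individuals (%d genotyped, blend %.2f)",
      length(hinv$ids), length(gd$samples), cfg$blend_alpha))
    ## ---- REML + covariate + scan per trait
    vc_list <- list(); cov_list <- list()
    scan <- NULL
    for (tr in cfg$traits) {
      stage <- paste0("reml_", tr)
      spec <- model_spec(trait = tr, covariate = TRUE, hys = TRUE,
                         df = cfg$test_df)
      vc <- ai_reml(phen, spec, hinv, het = het, tol = cfg$reml_tol,
                    max_iter = cfg$reml_max_iter)
      vc_list[[tr]] <- vc
      log <- stage_log(log, stage, sprintf(
        "a=%.3f p=%.3f h=%.3f e=%.3f (%d iterations)",
        vc$sigma2["a"], vc$sigma2["p"], vc$sigma2["h"], vc$sigma2["e"],
        vc$convergence$iterations))
      stage <- paste0("covariate_", tr)
      cov_list[[tr]] <- fit_het_covariate(phen, spec, hinv, vc, het)
      log <- stage_log(log, stage, sprintf(
        "d = %.4f +/- %.4f piglets/%%, one-sided p = %.3g",
        cov_list[[tr]]$estimate, cov_list[[tr]]$se, cov_list[[tr]]$p))
    }
    vc_tab <- data.table::rbindlist(lapply(names(vc_list), function(tr)
      data.table::data.table(trait = tr,
                             component = names(vc_list[[tr]]$sigma2),
                             estimate = unname(vc_list[[tr]]$sigma2),
                             sampling_var = unname(vc_list[[tr]]$sampling_var))))
    data.table::fwrite(vc_tab,
                       file.path(cfg$out_dir, "variance_components.tsv"),
                       sep = "\t")
    cov_tab <- data.table::rbindlist(lapply(names(cov_list), function(tr)
      data.table::data.table(trait = tr,
                             estimate = cov_list[[tr]]$estimate,
                             se = cov_list[[tr]]$se,
                             p_one_sided = cov_list[[tr]]$p)))
    data.table::fwrite(cov_tab,
                       file.path(cfg$out_dir, "het_covariate.tsv"),
                       sep = "\t")
    ## ---- scan (per trait, with that trait's components)
    stage <- "scan"
    scans <- lapply(cfg$traits, function(tr)
      scan_roh(catalog, phen, hinv, vc_list[[tr]], traits = tr,
               include_covariate = cfg$scan_covariate,
               include_hys = cfg$scan_hys, het = het, df = cfg$test_df))
    scan <- scans[[1L]]
    if (length(scans) > 1L)
      for (s in scans[-1L]) {
        newcols <- setdiff(names(s), names(scan))
        scan <- cbind(scan, s[, ..newcols])
        scan$skip_reason <- ifelse(is.na(scan$skip_reason), s$skip_reason,
                                   scan$skip_reason)
      }
    data.table::fwrite(scan, file.path(cfg$out_dir, "scan.tsv"), sep = "\t")
    n_skip <- sum(!is.na(scan$skip_reason))
    manifest$stages$scan <- list(n_segments = nrow(scan),
                                 n_skipped = n_skip)
    log <- stage_log(log, stage, sprintf("%d segments scanned, %d skipped",
                                         nrow(scan) - n_skip, n_skip))
    ## ---- summaries
    stage <- "summary"
    ssum <- summarize_scan(scan)
    data.table::fwrite(ssum$counts,
                       file.path(cfg$out_dir, "scan_summary.tsv"), sep = "\t")
    data.table::fwrite(ssum$by_chrom,
                       file.path(cfg$out_dir, "scan_by_chrom.tsv"),
                       sep = "\t")
    regions <- data.table::rbindlist(lapply(cfg$traits, function(tr) {
      r <- merge_regions(scan, trait = tr, alpha = 0.001)
      if (nrow(r)) cbind(data.table::data.table(trait = tr), r) else
        data.table::data.table(trait = character(), chrom = character(),
                               start_bp = integer(), end_bp = integer(),
                               best_p = numeric(), n_segments = integer(),
                               segment_ids = character())
    }), use.names = TRUE)
    data.table::fwrite(regions, file.path(cfg$out_dir, "regions.tsv"),
                       sep = "\t")
    manifest$stages$summary <- list(counts = ssum$counts,
                                    n_regions = nrow(regions))
    ## ---- manifest + log
    stage <- "manifest"
    writeLines(log, file.path(cfg$out_dir, "pipeline.log"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
    res <- c(res, list(qc = gd$provenance, genotypes = gd, phenotypes = phen,
                       pedigree = ped, het = het, runs = runs,
                       catalog = catalog, summary = summ, hinv = hinv,
                       vc = vc_list, covariate = cov_list, scan = scan,
                       scan_summary = ssum, regions = regions,
                       manifest = manifest))
    invisible(res)
  }, error = on_fail)
}
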
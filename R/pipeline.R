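# End-to-end pipeline driver: simulate (or load) -> quantify -> compare ->
# pathways -> biomarkers -> ml, with a deterministic machine-readable
# manifest (parameters, seeds, output file hashes). Stages whose inputs are
# absent are skipped; a stage failure aborts the run with the stage name and
# leaves a FAILED marker next to the partial outputs.

#' Run the full analysis pipeline from a single configuration
#'
#' The configuration is a named list (or a path to a YAML/JSON file) with
#' optional blocks:
#' \describe{
#'   \item{seed}{Global seed (default 1); stage seeds derive from it.}
#'   \item{sim}{[sim_config()] fields for a synthetic run; alternatively
#'     `counts`/`meta` paths to load a real PSM experiment.}
#'   \item{quant}{`pseudocount` (0.5), `scale` (1e4).}
#'   \item{compare}{`p_max` (0.05), `lfc_min` (5).}
#'   \item{pathways}{`gmt` path, or `n_pathways`/`size_range` to simulate;
#'     `z_cut` (0.5), `logp_cut` (1.3), `p_max` (0.05).}
#'   \item{biomarkers}{`panel` path, or `simulate: true` to use the synthetic
#'     human panel; `alpha` (0.05).}
#'   \item{ml}{`contrasts` (default all three), `folds` (10), `repeats` (10),
#'     `cost` (1).}
#' }
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @param outdir Output directory (overrides `config$outdir`).
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`). The manifest contains no timestamps, so reruns with the
#'   same configuration produce byte-identical manifests.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  outdir <- outdir %||% config$outdir %||% stop("an output directory is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  outputs <- character(0)
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 failed_marker)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- stage: acquire PSM experiment -----------------------------------
  sim_blk <- config$sim
  experiment <- NULL; truth <- NULL; scfg <- NULL
  if (!is.null(sim_blk$counts)) {
    experiment <- stage("load", read_psm_counts(sim_blk$counts, sim_blk$meta))
  } else if (!is.null(sim_blk)) {
    scfg <- stage("simulate", do.call(sim_config, c(
      sim_blk[intersect(names(sim_blk), names(formals(sim_config)))],
      if (is.null(sim_blk$seed)) list(seed = seed) else NULL)))
    sim <- stage("simulate", simulate_psm_experiment(scfg))
    experiment <- sim$experiment
    truth <- sim$truth
    p <- stage("simulate", write_simulation(sim, file.path(outdir, "sim")))
    outputs <- c(outputs, p)
  }

  diffs <- list()
  if (!is.null(experiment)) {
    q <- config$quant %||% list()
    pseudocount <- q$pseudocount %||% 0.5
    scale <- q$scale %||% 1e4
    strata <- unique(experiment$meta[, c("tissue", "age_months")])
    message(sprintf("quant: %d strata, pseudocount=%g (fold-change only), scale=%g",
                    nrow(strata), pseudocount, scale))
    for (i in seq_len(nrow(strata))) {
      nm <- sprintf("%s_%dm", strata$tissue[i], strata$age_months[i])
      diffs[[nm]] <- stage("quant", differential_analysis(
        experiment, strata$tissue[i], strata$age_months[i],
        pseudocount = pseudocount, scale = scale))
      f <- file.path(outdir, sprintf("diff_%s.tsv", nm))
      write_differential(diffs[[nm]], f)
      outputs <- c(outputs, stats::setNames(f, paste0("diff_", nm)))
    }
  }

  if (length(diffs)) {
    cmp <- config$compare %||% list()
    sets <- stage("compare", altered_protein_sets(
      diffs, p_max = cmp$p_max %||% 0.05, lfc_min = cmp$lfc_min %||% 5))
    p <- stage("compare", write_compare(
      sets, file.path(outdir, "altered_sets.tsv"),
      file.path(outdir, "intersections.json")))
    outputs <- c(outputs, p)
  }

  pw_blk <- config$pathways
  if (length(diffs) && !is.null(pw_blk)) {
    pathways <- if (!is.null(pw_blk$gmt)) {
      stage("pathways", read_gmt(pw_blk$gmt))
    } else if (!is.null(truth)) {
      pws <- stage("pathways", simulate_pathway_sets(
        pw_blk$n_pathways %||% 50L,
        pw_blk$size_range %||% c(5L, 15L), truth, seed = seed + 2L))
      f <- file.path(outdir, "pathways.gmt")
      write_gmt(pws$pathways, f)
      outputs <- c(outputs, pathways_gmt = f)
      pws$pathways
    } else NULL
    if (!is.null(pathways)) {
      calls <- stage("pathways", pathway_calls(
        diffs, pathways, p_max = pw_blk$p_max %||% 0.05,
        z_cut = pw_blk$z_cut %||% 0.5, logp_cut = pw_blk$logp_cut %||% 1.3))
      f <- file.path(outdir, "pathway_calls.tsv")
      utils::write.table(calls, f, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, pathway_calls = f)
      summ <- stage("pathways", cross_summary(calls))
      f <- file.path(outdir, "pathway_summary.json")
      jsonlite::write_json(
        list(counts = as.list(summ$counts), percent = as.list(summ$percent),
             denominator = summ$denominator),
        f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      outputs <- c(outputs, pathway_summary = f)
    }
  }

  bm_blk <- config$biomarkers
  panel <- NULL
  if (!is.null(bm_blk)) {
    if (!is.null(bm_blk$panel)) {
      panel <- stage("biomarkers", read_panel(bm_blk$panel))
    } else if (isTRUE(bm_blk$simulate)) {
      hcfg <- scfg %||% sim_config(seed = seed)
      hp <- stage("biomarkers", simulate_human_panel(hcfg))
      panel <- hp$panel
      f <- file.path(outdir, "human_panel.tsv")
      utils::write.table(panel, f, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, human_panel = f)
    }
    if (!is.null(panel)) {
      flags <- stage("biomarkers", group_compare_all(
        panel, alpha = bm_blk$alpha %||% 0.05))
      classes <- stage("biomarkers", classify_pattern(flags))
      f <- file.path(outdir, "biomarker_classes.tsv")
      utils::write.table(merge(flags, classes, by = "protein_id"), f,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, biomarker_classes = f)
    }
  }

  ml_blk <- config$ml
  if (!is.null(panel) && !is.null(ml_blk)) {
    universe <- ml_blk$universe %||%
      setdiff(names(panel), c("subject_id", "group", "mmse"))
    contrasts <- ml_blk$contrasts %||%
      c("healthy_vs_early", "healthy_vs_late", "early_vs_late")
    for (ct in contrasts) {
      perf <- stage("ml", accumulate_cv(
        panel, ct, universe, folds = ml_blk$folds %||% 10L,
        repeats = ml_blk$repeats %||% 10L, seed = seed + 3L,
        cost = ml_blk$cost %||% 1))
      p <- stage("ml", write_performance(perf, file.path(outdir, "ml")))
      outputs <- c(outputs, stats::setNames(p, paste0(ct, "_", names(p))))
    }
  }

  # --- manifest (deterministic: no timestamps) --------------------------
  rel <- function(p) sub(paste0(normalizePath(outdir, mustWork = FALSE), "/"),
                         "", normalizePath(p, mustWork = FALSE), fixed = TRUE)
  hashes <- tools::md5sum(outputs)
  manifest <- list(
    package = "evpanel",
    version = as.character(utils::packageVersion("evpanel")),
    seed = seed,
    parameters = config[setdiff(names(config), "outdir")],
    outputs = stats::setNames(as.list(unname(hashes)), rel(outputs))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
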
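# Synthetic experiment generator: PSM-count experiments, human plasma-EV
# panels and directional pathway sets with planted, machine-readable truth.
# The sampling models are deliberately simple stand-ins chosen so that the
# downstream statistics' assumptions approximately hold (see the methods
# vignette); they are not calibrated to any instrument.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with validation.
#' Identical configurations (including `seed`) produce bit-identical output
#' from every `simulate_*()` function.
#'
#' @param n_proteins Number of proteins in the mouse PSM experiment.
#' @param n_tech_replicates Technical replicates per genotype within each
#'   tissue-by-age stratum.
#' @param mean_depth Expected total PSM count per sample.
#' @param n_de Number of planted differentially abundant proteins
#'   (must not exceed `n_proteins`).
#' @param effect_log2 Planted log2 fold change (5xFAD relative to WT) carried
#'   by every planted protein; the generating group-mean ratio is
#'   `2^effect_log2`.
#' @param human_n_per_group Subjects per diagnostic group (healthy, early,
#'   late) in the human panel; the emulated cohorts enrolled 39-47 per group,
#'   hence the default 40.
#' @param human_effect_d Standardized (units of the log-scale noise sd) mean
#'   shift planted for human biomarker classes.
#' @param human_sigma_log Log-scale standard deviation of the lognormal
#'   measurement noise on human band intensities.
#' @param depth_sigma_log Log-scale sd of the per-sample depth factor in the
#'   PSM count model.
#' @param abundance_decades Width (in log10 units) of the log-uniform
#'   per-protein abundance distribution.
#' @param seed Integer random seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_proteins = 2000L,
                       n_tech_replicates = 3L,
                       mean_depth = 1e5,
                       n_de = 20L,
                       effect_log2 = 3,
                       human_n_per_group = 40L,
                       human_effect_d = 2,
                       human_sigma_log = 0.4,
                       depth_sigma_log = 0.1,
                       abundance_decades = 2,
                       seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_tech_replicates = as.integer(n_tech_replicates),
    mean_depth = as.numeric(mean_depth),
    n_de = as.integer(n_de),
    effect_log2 = as.numeric(effect_log2),
    human_n_per_group = as.integer(human_n_per_group),
    human_effect_d = as.numeric(human_effect_d),
    human_sigma_log = as.numeric(human_sigma_log),
    depth_sigma_log = as.numeric(depth_sigma_log),
    abundance_decades = as.numeric(abundance_decades),
    seed = as.integer(seed)
  )
  if (cfg$n_proteins < 1L || cfg$n_tech_replicates < 1L)
    stop("n_proteins and n_tech_replicates must be positive integers")
  if (!is.finite(cfg$mean_depth) || cfg$mean_depth <= 0)
    stop("mean_depth must be strictly positive")
  if (cfg$n_de < 0L || cfg$n_de > cfg$n_proteins)
    stop("n_de must satisfy 0 <= n_de <= n_proteins")
  if (cfg$human_n_per_group < 3L)
    stop("human_n_per_group must be >= 3 (pairwise tests are undefined below that)")
  if (cfg$human_sigma_log <= 0 || cfg$depth_sigma_log < 0)
    stop("noise scales must be positive")
  if (is.na(cfg$seed)) stop("seed must be an integer")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# MMSE intervals per diagnostic stage (late <16, early 16-23, healthy >=24).
.mmse_intervals <- list(
  healthy = c(24L, 30L),
  early   = c(16L, 23L),
  late    = c(0L, 15L)
)

.human_candidates <- function() {
  data.frame(
    protein_id = c("A2M", "CKM", "FLNA", "ITGA2B", "ORM2", "PLTP",
                   "HP", "QSOX1", "TGM2",
                   "FLNC", "HSP70", "MAN2B1",
                   "PF4", "TLN1"),
    class = c(rep("class1", 6), rep("class2", 3), rep("class3", 3),
              rep("null", 2)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a mouse PSM-count experiment with planted differential proteins
#'
#' Counts follow a Poisson model: each protein draws a relative abundance from
#' a log-uniform distribution spanning `abundance_decades` decades, each sample
#' draws a lognormal depth factor (sd `depth_sigma_log` on the log scale), and
#' planted proteins carry a multiplicative `2^effect_log2` shift in the 5xFAD
#' genotype. The planted protein set is shared across all strata, so
#' cross-proteome recapitulation is non-trivial by construction.
#'
#' @param config A [sim_config()].
#' @param tissues Tissues to generate (default all three proteomes).
#' @param ages Ages in months to generate (default 3 and 6).
#'
#' @return A list with elements `experiment` (a [psm_experiment()]) and
#'   `truth` (protein ids, the planted set with true log2 folds, and the
#'   generating relative abundances).
#' @export
simulate_psm_experiment <- function(config,
                                    tissues = c("hippocampus", "cortex", "plasma_EV"),
                                    ages = c(3L, 6L)) {
  stopifnot(inherits(config, "sim_config"))
  tissues <- match.arg(tissues, c("hippocampus", "cortex", "plasma_EV"),
                       several.ok = TRUE)
  set.seed(config$seed)

  n <- config$n_proteins
  protein_ids <- sprintf("P%05d", seq_len(n))
  abundance <- 10^stats::runif(n, 0, config$abundance_decades)
  weight <- abundance / sum(abundance)

  de_idx <- if (config$n_de > 0L) sort(sample.int(n, config$n_de)) else integer(0)
  ratio <- rep(1, n)
  ratio[de_idx] <- 2^config$effect_log2

  design <- expand.grid(
    replicate_id = seq_len(config$n_tech_replicates),
    genotype = c("WT", "5xFAD"),
    age_months = as.integer(ages),
    tissue = tissues,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  design$sample_id <- sprintf("%s_%dm_%s_r%d", design$tissue, design$age_months,
                              design$genotype, design$replicate_id)

  counts <- matrix(0L, nrow = n, ncol = nrow(design),
                   dimnames = list(protein_ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    f <- stats::rlnorm(1, 0, config$depth_sigma_log)
    lam <- config$mean_depth * f * weight
    if (design$genotype[j] == "5xFAD") lam <- lam * ratio
    counts[, j] <- stats::rpois(n, lam)
  }

  truth <- list(
    protein_ids = protein_ids,
    de_proteins = data.frame(
      protein_id = protein_ids[de_idx],
      true_log2_fold = rep(config$effect_log2, length(de_idx)),
      stringsAsFactors = FALSE
    ),
    relative_abundance = stats::setNames(weight, protein_ids),
    note = paste("Sampling model is a synthetic stand-in (Poisson counts,",
                 "log-uniform abundances, lognormal depth factors); no",
                 "instrument noise characteristics were available to emulate.")
  )
  list(experiment = psm_experiment(counts, design[, c("sample_id", "tissue",
                                                      "age_months", "genotype",
                                                      "replicate_id")]),
       truth = truth)
}

#' Simulate a human plasma-EV biomarker panel with planted class patterns
#'
#' Generates three diagnostic groups (healthy / early / late) of
#' `human_n_per_group` subjects over the 14 candidate proteins, planting the
#' class patterns observed in stage-divided patients: class 1 proteins are
#' elevated only in early-stage disease (late returns to the healthy level),
#' class 2 proteins are elevated early with an intermediate late mean (set
#' midway between the healthy and early means), class 3 proteins are elevated
#' in both early and late disease, and null proteins have identical group
#' means. Intensities carry lognormal noise (`human_sigma_log` on the log
#' scale); MMSE scores are uniform over each group's admissible integer
#' interval.
#'
#' @param config A [sim_config()]. `human_effect_d` is the planted shift in
#'   units of `human_sigma_log`.
#'
#' @return A list with `panel` (data.frame: subject_id, group, mmse, one
#'   column per protein) and `truth` (per-protein class, generating log-scale
#'   group means, and the class label the default rule table implies under
#'   full power, `expected_class`).
#' @export
simulate_human_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)

  cand <- .human_candidates()
  d <- config$human_effect_d * config$human_sigma_log
  groups <- c("healthy", "early", "late")
  log_means <- matrix(0, nrow = nrow(cand), ncol = 3,
                      dimnames = list(cand$protein_id, groups))
  log_means[cand$class == "class1", "early"] <- d
  log_means[cand$class == "class2", "early"] <- d
  log_means[cand$class == "class2", "late"]  <- d / 2
  log_means[cand$class == "class3", "early"] <- d
  log_means[cand$class == "class3", "late"]  <- d

  n <- config$human_n_per_group
  group <- rep(groups, each = n)
  subject_id <- sprintf("S%03d", seq_along(group))
  mmse <- unlist(lapply(groups, function(g) {
    iv <- .mmse_intervals[[g]]
    sample(seq(iv[1], iv[2]), n, replace = TRUE)
  }), use.names = FALSE)

  intens <- vapply(seq_len(nrow(cand)), function(i) {
    mu <- log_means[i, match(group, groups)]
    exp(stats::rnorm(length(group), mu, config$human_sigma_log))
  }, numeric(length(group)))
  colnames(intens) <- cand$protein_id

  panel <- data.frame(subject_id = subject_id, group = group, mmse = mmse,
                      intens, stringsAsFactors = FALSE, check.names = FALSE)

  truth <- list(
    human_class_truth = stats::setNames(cand$class, cand$protein_id),
    group_means_log = log_means,
    expected_class = .expected_class_under_full_power(log_means),
    effect_d = config$human_effect_d,
    note = paste("Lognormal intensity noise and uniform MMSE sampling are",
                 "synthetic stand-ins; class-2 late means are set midway",
                 "between healthy and early means.")
  )
  list(panel = panel, truth = truth)
}

# Label each protein by applying the default rule table to the significance
# flags its generating means imply when every nonzero mean difference is
# detected (the full-power limit). Used by round-trip recovery tests.
.expected_class_under_full_power <- function(log_means) {
  flag <- function(delta) {
    if (delta > 0) "up" else if (delta < 0) "down" else "ns"
  }
  flags <- data.frame(
    protein_id = rownames(log_means),
    he = vapply(rownames(log_means),
                function(p) flag(log_means[p, "early"] - log_means[p, "healthy"]), ""),
    hl = vapply(rownames(log_means),
                function(p) flag(log_means[p, "late"] - log_means[p, "healthy"]), ""),
    el = vapply(rownames(log_means),
                function(p) flag(log_means[p, "late"] - log_means[p, "early"]), ""),
    stringsAsFactors = FALSE
  )
  cls <- classify_pattern(flags)
  stats::setNames(cls$class, cls$protein_id)
}

#' Simulate a two-group panel with a planted informative feature subset
#'
#' Convenience generator for classifier benchmarking: two groups of subjects
#' over `n_features` proteins of which the first `n_informative` carry a
#' standardized log-scale mean shift `effect_d`; the remainder are pure noise.
#'
#' @param n_per_group Subjects per group.
#' @param n_features Total number of features.
#' @param n_informative Number of shifted features (the planted panel).
#' @param effect_d Standardized mean shift for informative features.
#' @param sigma_log Log-scale noise sd.
#' @param groups Two group labels, second is the elevated (positive) class.
#' @param seed Integer seed.
#'
#' @return List with `panel` (data.frame: subject_id, group, features) and
#'   `truth$informative` (the planted feature names).
#' @export
simulate_binary_panel <- function(n_per_group = 40L, n_features = 9L,
                                  n_informative = 5L, effect_d = 1.5,
                                  sigma_log = 0.4,
                                  groups = c("healthy", "early"),
                                  seed = 1L) {
  stopifnot(n_informative <= n_features, length(groups) == 2L, n_per_group >= 2L)
  set.seed(seed)
  features <- sprintf("F%02d", seq_len(n_features))
  group <- rep(groups, each = n_per_group)
  shift <- ifelse(group == groups[2], effect_d * sigma_log, 0)
  X <- vapply(seq_len(n_features), function(i) {
    mu <- if (i <= n_informative) shift else 0
    exp(stats::rnorm(length(group), mu, sigma_log))
  }, numeric(length(group)))
  colnames(X) <- features
  panel <- data.frame(subject_id = sprintf("S%03d", seq_along(group)),
                      group = group, X,
                      stringsAsFactors = FALSE, check.names = FALSE)
  list(panel = panel,
       truth = list(informative = features[seq_len(n_informative)]))
}

#' Simulate directional pathway definitions over a generated proteome
#'
#' Roughly half of the pathways are coherently regulated: their members are
#' drawn from the planted differential proteins and their expected directions
#' match the planted signs, so a correct activation score calls them in the
#' planted direction. The rest draw members uniformly from the proteome with
#' random expected directions.
#'
#' @param n_pathways Number of pathways to generate.
#' @param size_range Integer interval (length 2) of pathway sizes.
#' @param truth Truth record from [simulate_psm_experiment()].
#' @param seed Integer seed (independent stream from count generation).
#'
#' @return List with `pathways` (a list of `name`/`members`/`directions`
#'   records) and `truth` (data.frame: name, coherent, planted_direction).
#' @export
simulate_pathway_sets <- function(n_pathways, size_range, truth, seed = 1L) {
  if (length(size_range) != 2L || any(size_range < 2L) ||
      size_range[1] > size_range[2])
    stop("size_range must be an interval [lo, hi] with lo >= 2")
  if (size_range[2] > length(truth$protein_ids))
    stop("size_range exceeds the number of proteins in the universe")
  set.seed(seed)

  de_ids <- truth$de_proteins$protein_id
  de_sign <- sign(truth$de_proteins$true_log2_fold)
  n_coherent <- if (length(de_ids) >= 2L) floor(n_pathways / 2) else 0L

  pathways <- vector("list", n_pathways)
  coherent <- logical(n_pathways)
  planted_dir <- character(n_pathways)
  for (i in seq_len(n_pathways)) {
    size <- sample(seq(size_range[1], size_range[2]), 1L)
    if (i <= n_coherent) {
      size <- min(size, length(de_ids))
      pick <- sample(seq_along(de_ids), size)
      members <- de_ids[pick]
      directions <- de_sign[pick]  # consistent with planted change
      coherent[i] <- TRUE
      # directions match planted signs, so the pathway is activated by construction
      planted_dir[i] <- "activated"
    } else {
      members <- sample(truth$protein_ids, size)
      directions <- sample(c(-1L, 1L), size, replace = TRUE)
      coherent[i] <- FALSE
      planted_dir[i] <- "none"
    }
    pathways[[i]] <- list(name = sprintf("PW%03d", i),
                          members = members,
                          directions = as.integer(directions))
  }
  list(pathways = pathways,
       truth = data.frame(name = vapply(pathways, `[[`, "", "name"),
                          coherent = coherent,
                          planted_direction = planted_dir,
                          stringsAsFactors = FALSE))
}

#' Write simulated tables to disk
#'
#' Writes the PSM count matrix and sample metadata as tab-separated tables,
#' the truth record as JSON, and (optionally) pathways as GMT and the human
#' panel as TSV.
#'
#' @param sim Output of [simulate_psm_experiment()].
#' @param dir Output directory (created if absent).
#' @param human Optional output of [simulate_human_panel()].
#' @param pathways Optional output of [simulate_pathway_sets()].
#' @return Invisibly, the named vector of written file paths.
#' @export
write_simulation <- function(sim, dir, human = NULL, pathways = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "psm_counts.tsv"),
    meta = file.path(dir, "sample_meta.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_psm_counts(sim$experiment, paths[["counts"]], paths[["meta"]])
  truth_out <- sim$truth
  truth_out$relative_abundance <- NULL  # bulky; derivable from the seed
  jsonlite::write_json(truth_out, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(human)) {
    paths[["human_panel"]] <- file.path(dir, "human_panel.tsv")
    utils::write.table(human$panel, paths[["human_panel"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[["human_truth"]] <- file.path(dir, "human_truth.json")
    ht <- human$truth
    ht$group_means_log <- as.data.frame(ht$group_means_log)
    jsonlite::write_json(ht, paths[["human_truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(pathways)) {
    paths[["pathways"]] <- file.path(dir, "pathways.gmt")
    write_gmt(pathways$pathways, paths[["pathways"]])
    paths[["pathway_truth"]] <- file.path(dir, "pathway_truth.tsv")
    utils::write.table(pathways$truth, paths[["pathway_truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
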
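#' Simulation configuration for a synthetic expression cohort
#'
#' Builds and validates the configuration of [simulate_cohort()]. The
#' defaults emulate the statistical structure of a two-tissue profiling
#' cohort: 49 tumor and 15 non-neoplastic samples with continuous ages at
#' day resolution, 1,710 miRNA and 18,531 gene features of which a minority
#' carry a monotone age signal, a subset of age signals present in tumor
#' only, and planted miRNA-to-target repression. The planted counts default
#' to 29 positive + 20 negative age-correlated features in both tissues plus
#' 10 tumor-only features, so that the tumor-tissue screen sees 39 positive
#' and 20 negative planted signals.
#'
#' @param n_tumor,n_normal Sample counts per tissue class.
#' @param n_mirna,n_gene Feature counts of the two matrices.
#' @param n_planted_pos,n_planted_neg Features with a planted positive /
#'   negative age correlation in both tissue classes.
#' @param n_tumor_only Features with an age signal in tumor columns and pure
#'   noise in normal columns (signs alternate positive/negative).
#' @param planted_rho Target expected sample Spearman correlation of planted
#'   features against age, in (0, 1].
#' @param targets_per_mirna Mean out-degree of the planted repression map
#'   (Poisson, at least 1 target per planted miRNA).
#' @param repression_strength Monotone effect size of a planted miRNA on its
#'   planted targets, in units of `noise_sd` (1 = signal sd equals noise sd).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param age_range_years Length-2 numeric, (min, max) of simulated ages.
#' @param seed Integer master seed; all sub-streams are derived from it by
#'   fixed offsets.
#' @return A validated list of class `sim_config`.
#' @seealso [sim_config_small()] for a scaled-down preset used in tests.
#' @export
sim_config <- function(n_tumor = 49L, n_normal = 15L,
                       n_mirna = 1710L, n_gene = 18531L,
                       n_planted_pos = 29L, n_planted_neg = 20L,
                       n_tumor_only = 10L,
                       planted_rho = 0.6,
                       targets_per_mirna = 5,
                       repression_strength = 1,
                       noise_sd = 1,
                       age_range_years = c(1, 35),
                       seed = 1L) {
  cfg <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_mirna = as.integer(n_mirna), n_gene = as.integer(n_gene),
              n_planted_pos = as.integer(n_planted_pos),
              n_planted_neg = as.integer(n_planted_neg),
              n_tumor_only = as.integer(n_tumor_only),
              planted_rho = planted_rho,
              targets_per_mirna = targets_per_mirna,
              repression_strength = repression_strength,
              noise_sd = noise_sd,
              age_range_years = as.numeric(age_range_years),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Scaled-down simulation preset
#'
#' Same structure as [sim_config()] at a fraction of the size (200 miRNAs,
#' 2,000 genes by default), for fast tests and examples. Sample sizes and
#' effect sizes keep their cohort-scale defaults so the per-feature
#' statistical behavior is unchanged.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A validated `sim_config`.
#' @export
sim_config_small <- function(...) {
  defaults <- list(n_mirna = 200L, n_gene = 2000L,
                   n_planted_pos = 10L, n_planted_neg = 6L, n_tumor_only = 8L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_tumor", "n_normal", "n_mirna", "n_gene",
              "n_planted_pos", "n_planted_neg", "n_tumor_only")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop_usage("invalid config: %s must be a non-negative count", f)
  }
  planted <- cfg$n_planted_pos + cfg$n_planted_neg + cfg$n_tumor_only
  if (planted > cfg$n_mirna)
    stop_usage("invalid config: n_planted_pos + n_planted_neg + n_tumor_only (%d) exceeds n_mirna (%d)",
               planted, cfg$n_mirna)
  if (planted > cfg$n_gene)
    stop_usage("invalid config: n_planted_pos + n_planted_neg + n_tumor_only (%d) exceeds n_gene (%d)",
               planted, cfg$n_gene)
  if (!(cfg$planted_rho > 0 && cfg$planted_rho <= 1))
    stop_usage("invalid config: planted_rho must lie in (0, 1], got %g", cfg$planted_rho)
  if (cfg$noise_sd < 0)
    stop_usage("invalid config: noise_sd must be >= 0, got %g", cfg$noise_sd)
  if (length(cfg$age_range_years) != 2L ||
      !(cfg$age_range_years[1] < cfg$age_range_years[2]))
    stop_usage("invalid config: age_range_years must satisfy min < max")
  if (cfg$targets_per_mirna < 0)
    stop_usage("invalid config: targets_per_mirna must be >= 0")
  invisible(cfg)
}

# Signal-to-noise calibration: find the noise scale sigma such that
# x = z + sigma * eps (z the Gaussian scores of the age ranks) has expected
# SAMPLE Spearman correlation `target` with age at sample size n. The
# bivariate-normal identity E[r_s] = 6/(pi (n+1)) (asin(r) + (n-2) asin(r/2))
# with r = 1/sqrt(1 + sigma^2) provides the starting value; a seeded
# Monte-Carlo bisection then removes the residual bias of conditioning on
# the fixed score vector z. Memoized per (target, n).
calibrate_signal_sigma <- function(target, n, reps = 500L, iters = 10L) {
  key <- sprintf("cal_%0.4f_%d", target, n)
  hit <- .agemirnet_cache[[key]]
  if (!is.null(hit)) return(hit)
  e_rs <- function(r) 6 / (pi * (n + 1)) * (asin(r) + (n - 2) * asin(r / 2))
  r0 <- stats::uniroot(function(r) e_rs(r) - target,
                       c(1e-9, 1 - 1e-9))$root
  sigma0 <- sqrt(1 / r0^2 - 1)
  z <- stats::qnorm((seq_len(n) - 0.5) / n)
  mean_rs <- function(sigma, eps) {
    rs <- apply(eps, 1L, function(e) stats::cor(rank(z + sigma * e), seq_len(n)))
    mean(rs)
  }
  sigma <- with_local_seed(70317 + n, {
    eps <- matrix(stats::rnorm(reps * n), nrow = reps)
    lo <- sigma0 / 3
    hi <- sigma0 * 3
    if (mean_rs(lo, eps) < target) lo <- 1e-6
    if (mean_rs(hi, eps) > target) hi <- sigma0 * 10
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (mean_rs(mid, eps) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
  .agemirnet_cache[[key]] <- sigma
  sigma
}

# Gaussian scores of the ranks of v (a rank-preserving monotone transform,
# under which Spearman correlation is invariant).
gauss_scores <- function(v) stats::qnorm((rank(v) - 0.5) / length(v))

#' Simulate a two-tissue expression cohort with planted structure
#'
#' Generates a miRNA matrix, a gene matrix, per-sample clinical metadata,
#' a miRNA-to-gene target table and the ground truth of everything planted:
#' \itemize{
#'   \item Ages are drawn at day resolution (distinct integer day counts,
#'     divided by 365), so the age covariate is strictly tie-free.
#'   \item Planted age-correlated features are a monotone (Gaussian-score)
#'     transform of age plus Gaussian noise, with the signal-to-noise ratio
#'     calibrated so the expected sample Spearman correlation against age is
#'     `planted_rho`; tumor-only features carry the signal in tumor columns
#'     and pure noise in normal columns.
#'   \item Planted targets of each planted miRNA receive a decreasing
#'     monotone dependence on that miRNA's values with effect size
#'     `repression_strength`; the emitted target table contains every
#'     planted pair plus decoy pairs with no dependence.
#'   \item All remaining entries are i.i.d. Gaussian noise around a
#'     feature-specific baseline.
#' }
#' The output is deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `mirna`, `gene` (matrices as from
#'   [read_expression()]), `samples` (data frame as from [read_samples()]),
#'   `targets` (data frame `mirna`/`gene`) and `truth` (list with
#'   `mirna_planted`, `gene_planted` — data frames of feature id, sign,
#'   scope — and `repression`, the planted pair table).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config

  # --- stream 1: ages, dates, sample ids ---------------------------------
  set.seed(cfg$seed)
  n_samp <- cfg$n_tumor + cfg$n_normal
  dmin <- max(1L, ceiling(cfg$age_range_years[1] * 365))
  dmax <- floor(cfg$age_range_years[2] * 365)
  if (dmax - dmin + 1L < n_samp)
    stop_usage("invalid config: age range too narrow for %d distinct day-resolution ages", n_samp)
  days <- sample(dmin:dmax, n_samp)  # without replacement: no tied ages
  diagnosis <- as.Date("2016-06-30")
  samples <- data.frame(
    sample_id = c(sprintf("T%03d", seq_len(cfg$n_tumor)),
                  sprintf("N%03d", seq_len(cfg$n_normal))),
    birth_date = diagnosis - days,
    diagnosis_date = diagnosis,
    tissue = rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal)),
    stringsAsFactors = FALSE
  )
  samples$age_years <- days / 365
  samples$age_group <- ifelse(samples$age_years < 15, "PEDS", "AYA")
  tum_cols <- which(samples$tissue == "tumor")
  nor_cols <- which(samples$tissue == "normal")
  age_t <- samples$age_years[tum_cols]
  age_n <- samples$age_years[nor_cols]

  mirna_ids <- sprintf("mir-%04d", seq_len(cfg$n_mirna))
  gene_ids <- sprintf("gene-%05d", seq_len(cfg$n_gene))

  # --- stream 2: choice of planted features ------------------------------
  set.seed(cfg$seed + 1L)
  n_planted <- cfg$n_planted_pos + cfg$n_planted_neg + cfg$n_tumor_only
  plant_one <- function(ids) {
    sel <- if (n_planted > 0L) sample(ids, n_planted) else character(0)
    sign <- c(rep(1, cfg$n_planted_pos), rep(-1, cfg$n_planted_neg),
              rep_len(c(1, -1), cfg$n_tumor_only))
    scope <- rep(c("both", "tumor_only"),
                 c(cfg$n_planted_pos + cfg$n_planted_neg, cfg$n_tumor_only))
    data.frame(feature_id = sel, sign = sign, scope = scope,
               stringsAsFactors = FALSE)
  }
  mirna_planted <- plant_one(mirna_ids)
  gene_planted <- plant_one(gene_ids)

  # --- stream 3: matrices -------------------------------------------------
  set.seed(cfg$seed + 2L)
  amp_t <- if (n_planted > 0L && cfg$noise_sd > 0) {
    cfg$noise_sd / calibrate_signal_sigma(cfg$planted_rho, cfg$n_tumor)
  } else 1
  amp_n <- if (n_planted > 0L && cfg$noise_sd > 0 && cfg$n_normal >= 3L) {
    cfg$noise_sd / calibrate_signal_sigma(cfg$planted_rho, cfg$n_normal)
  } else amp_t
  z_t <- gauss_scores(age_t)
  z_n <- gauss_scores(age_n)

  gen_matrix <- function(ids, planted) {
    m <- matrix(stats::rnorm(length(ids) * n_samp, sd = cfg$noise_sd),
                nrow = length(ids), ncol = n_samp,
                dimnames = list(ids, samples$sample_id))
    m <- m + stats::runif(length(ids), 6, 12)  # feature baselines, recycled by row
    for (i in seq_len(nrow(planted))) {
      f <- planted$feature_id[i]
      m[f, tum_cols] <- m[f, tum_cols] + planted$sign[i] * amp_t * z_t
      if (planted$scope[i] == "both")
        m[f, nor_cols] <- m[f, nor_cols] + planted$sign[i] * amp_n * z_n
    }
    m
  }
  mirna <- gen_matrix(mirna_ids, mirna_planted)
  gene <- gen_matrix(gene_ids, gene_planted)
  attr(mirna, "kind") <- "mirna"
  attr(gene, "kind") <- "gene"

  # --- stream 4: planted repression and the target table ------------------
  set.seed(cfg$seed + 3L)
  free_genes <- setdiff(gene_ids, gene_planted$feature_id)
  repression <- data.frame(mirna = character(0), gene = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(mirna_planted) > 0L && cfg$targets_per_mirna > 0) {
    for (i in seq_len(nrow(mirna_planted))) {
      k <- max(1L, stats::rpois(1L, cfg$targets_per_mirna))
      k <- min(k, length(free_genes))
      if (k == 0L) break
      tg <- sample(free_genes, k)
      free_genes <- setdiff(free_genes, tg)
      mid <- mirna_planted$feature_id[i]
      cols <- if (mirna_planted$scope[i] == "both") seq_len(n_samp) else tum_cols
      zm <- gauss_scores(mirna[mid, cols])
      for (g in tg) {
        # background noise is already in the baseline draw of the gene row
        gene[g, cols] <- gene[g, cols] -
          cfg$repression_strength * cfg$noise_sd * zm
      }
      repression <- rbind(repression,
                          data.frame(mirna = mid, gene = tg,
                                     stringsAsFactors = FALSE))
    }
  }

  # decoy pairs: annotated targets with no planted dependence, both for
  # planted and for unplanted miRNAs, exercising the sign/significance filter
  targets <- repression
  if (cfg$targets_per_mirna > 0 && length(free_genes) > 0L) {
    decoy_mirnas <- c(mirna_planted$feature_id,
                      utils::head(setdiff(mirna_ids, mirna_planted$feature_id), 5L))
    for (mid in decoy_mirnas) {
      k <- min(max(1L, stats::rpois(1L, cfg$targets_per_mirna / 2)),
               length(free_genes))
      if (k == 0L) break
      tg <- sample(free_genes, k)
      free_genes <- setdiff(free_genes, tg)
      targets <- rbind(targets,
                       data.frame(mirna = mid, gene = tg, stringsAsFactors = FALSE))
    }
  }
  targets <- unique(targets)
  rownames(targets) <- NULL

  list(mirna = mirna, gene = gene, samples = samples, targets = targets,
       truth = list(mirna_planted = mirna_planted,
                    gene_planted = gene_planted,
                    repression = repression),
       config = cfg)
}

#' Write a simulated cohort to disk
#'
#' Writes the five pipeline input files in the same formats consumed by
#' [read_expression()], [read_samples()] and [read_targets()]:
#' `mirna_expression.tsv`, `gene_expression.tsv`, `samples.tsv`,
#' `targets.tsv`, plus `ground_truth.json`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mirna = file.path(dir, "mirna_expression.tsv"),
    gene = file.path(dir, "gene_expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    targets = file.path(dir, "targets.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_expression(cohort$mirna, paths[["mirna"]])
  write_expression(cohort$gene, paths[["gene"]])
  write_samples(cohort$samples, paths[["samples"]])
  write_targets(cohort$targets, paths[["targets"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]],
                       dataframe = "columns", pretty = TRUE)
  invisible(paths)
}
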
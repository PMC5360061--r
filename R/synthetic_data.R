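DAYS_PER_YEAR <- 365.25

#' Planted gene-level ground truth
#'
#' Assigns every gene to a planted class and records its true standardized
#' clinical effect and its true prediagnostic effect at the moment of
#' diagnosis. Null genes carry effect 0 in both arms; `dissimilar` genes are
#' planted with opposite directions in the two arms (up clinically, down
#' prediagnostically).
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `gene_id`, `planted_class`,
#'   `true_clinical_effect`, `true_prediag_effect_at_diagnosis`; one row per
#'   simulated gene.
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  classes <- sample(names(config$class_fractions), config$n_genes,
                    replace = TRUE, prob = config$class_fractions)
  clin_sign <- c(shared_up = 1, shared_down = -1, prediag_only_up = 0,
                 prediag_only_down = 0, clinical_only_up = 1,
                 clinical_only_down = -1, dissimilar = 1, null = 0)
  pre_sign <- c(shared_up = 1, shared_down = -1, prediag_only_up = 1,
                prediag_only_down = -1, clinical_only_up = 0,
                clinical_only_down = 0, dissimilar = -1, null = 0)
  data.frame(
    gene_id = sprintf("G%05d", seq_len(config$n_genes)),
    planted_class = classes,
    true_clinical_effect = unname(clin_sign[classes]) * config$delta_clinical,
    true_prediag_effect_at_diagnosis =
      unname(pre_sign[classes]) * config$delta_prediag_max,
    stringsAsFactors = FALSE
  )
}

#' Disease-progression weight of the prediagnostic signal
#'
#' Scales the planted case effect by proximity to diagnosis: weight 1 at
#' diagnosis (`t = 0`) decaying with time-to-diagnosis `t`. The linear model
#' uses `1 - t/t_max` (0 at the far end of follow-up); the exponential model
#' uses `exp(-t/t_med)` with `t_med` the midpoint of the follow-up interval.
#' Both are non-increasing in `t`.
#'
#' @param t_days time to diagnosis, days (non-negative).
#' @param config a [sim_config()] supplying the follow-up interval and model.
#' @return numeric weights in `[0, 1]`.
#' @export
progression_weight <- function(t_days, config) {
  stopifnot(all(t_days >= 0, na.rm = TRUE))
  t_max <- config$followup_range_years[2] * DAYS_PER_YEAR
  if (config$progression_model == "linear") {
    pmax(0, 1 - t_days / t_max)
  } else {
    t_med <- mean(config$followup_range_years) * DAYS_PER_YEAR
    exp(-t_days / t_med)
  }
}

## Expand a genes x samples matrix to probe level: each gene gets 1-3 probes
## with an additive per-probe offset constant. Returns matrix + probe map.
.expand_to_probes <- function(gene_mat, config, prefix) {
  k <- sample(1:3, nrow(gene_mat), replace = TRUE,
              prob = config$probe_multiplicity)
  gene_rep <- rep(seq_len(nrow(gene_mat)), k)
  probe_id <- sprintf("%s_%s_p%d", prefix, rownames(gene_mat)[gene_rep],
                      sequence(k))
  offsets <- rnorm(length(gene_rep), 0, config$probe_offset_sd)
  probe_mat <- gene_mat[gene_rep, , drop = FALSE] + offsets
  rownames(probe_mat) <- probe_id
  list(expr = probe_mat,
       probe_map = data.frame(probe_id = probe_id,
                              gene = rownames(gene_mat)[gene_rep],
                              stringsAsFactors = FALSE))
}

#' Simulate a set of clinical case-control expression studies
#'
#' Each study draws its own probe set (1-3 probes per gene with additive
#' probe offsets), omits a configurable fraction of genes to exercise the
#' common-universe intersection, and generates gene-level values as
#' `baseline noise + per-study effect x case`, where the per-study effect of
#' a clinical-signal gene is its true effect perturbed by
#' `Normal(0, tau^2)` between-study heterogeneity. Noise is unit-variance
#' Gaussian.
#'
#' @param config a [sim_config()].
#' @param truth optional ground-truth table; regenerated from `config` when
#'   missing.
#' @return list with `studies` (one list per study: `expr` probe matrix,
#'   `probe_map`, `pheno` with `sample_id`/`case`, `tissue`, `study_id`) and
#'   `truth`.
#' @export
simulate_clinical_studies <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- make_ground_truth(config)
  set.seed(config$seed + 1L)
  studies <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    nc <- config$n_cases[s]
    nm <- config$n_controls[s]
    if (nc < 1L || nm < 1L)
      stop(sprintf("study %d has zero cases or controls", s))
    study_id <- sprintf("study%02d", s)
    keep <- runif(config$n_genes) >= config$missing_fraction
    if (!any(keep)) stop(sprintf("study %d lost all genes to masking", s))
    genes <- truth$gene_id[keep]
    base_eff <- truth$true_clinical_effect[keep]
    study_eff <- base_eff +
      rnorm(sum(keep), 0, config$tau) * (base_eff != 0)
    case <- c(rep(1L, nc), rep(0L, nm))
    sample_id <- sprintf("%s_%s%02d", study_id,
                         ifelse(case == 1L, "case", "ctrl"),
                         c(seq_len(nc), seq_len(nm)))
    gmat <- matrix(rnorm(sum(keep) * (nc + nm)), nrow = sum(keep),
                   dimnames = list(genes, sample_id))
    gmat <- gmat + outer(study_eff, as.numeric(case))
    pr <- .expand_to_probes(gmat, config, study_id)
    studies[[s]] <- list(expr = pr$expr, probe_map = pr$probe_map,
                         pheno = data.frame(sample_id = sample_id,
                                            case = case,
                                            stringsAsFactors = FALSE),
                         tissue = config$tissues[s], study_id = study_id)
  }
  list(studies = studies, truth = truth)
}

#' Simulate the prediagnostic cohort
#'
#' Generates one probe-level matrix for a cohort of future cases and healthy
#' controls. Cases receive the planted prediagnostic effect scaled by
#' [progression_weight()] of their time to diagnosis. All samples carry
#' per-gene fixed-covariate effects (two continuous and three categorical
#' stand-ins: age, BMI, sex, country, experimental phase) and per-gene random
#' intercepts for three batch-date factors (RNA isolation, hybridization,
#' dye labeling).
#'
#' @inheritParams simulate_clinical_studies
#' @return list with `expr` (probe matrix), `probe_map`, `pheno` (sample_id,
#'   case, time_to_diagnosis_days with `NA` for controls, covariates, batch
#'   factors) and `truth`.
#' @export
simulate_prediag_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- make_ground_truth(config)
  if (diff(config$followup_range_years) <= 0)
    stop("degenerate follow-up interval")
  set.seed(config$seed + 2L)
  nca <- config$n_prediag_cases
  nco <- config$n_prediag_controls
  n <- nca + nco
  case <- c(rep(1L, nca), rep(0L, nco))
  sample_id <- sprintf("pre_%s%03d", ifelse(case == 1L, "case", "ctrl"),
                       c(seq_len(nca), seq_len(nco)))
  t_days <- rep(NA_real_, n)
  t_days[case == 1L] <- runif(nca, config$followup_range_years[1],
                              config$followup_range_years[2]) * DAYS_PER_YEAR

  pheno <- data.frame(
    sample_id = sample_id,
    case = case,
    time_to_diagnosis_days = t_days,
    age = rnorm(n, 55, 7),
    bmi = rnorm(n, 26, 4),
    sex = sample(c("F", "M"), n, replace = TRUE),
    country = sample(c("italy", "sweden"), n, replace = TRUE),
    phase = sample(c("A", "B"), n, replace = TRUE),
    isolation_date = sample(sprintf("iso%02d",
      seq_len(config$batch_counts[["isolation"]])), n, replace = TRUE),
    hybridization_date = sample(sprintf("hyb%02d",
      seq_len(config$batch_counts[["hybridization"]])), n, replace = TRUE),
    labeling_date = sample(sprintf("lab%02d",
      seq_len(config$batch_counts[["labeling"]])), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  G <- config$n_genes
  gmat <- matrix(rnorm(G * n), nrow = G,
                 dimnames = list(truth$gene_id, sample_id))

  # planted case signal scaled by proximity to diagnosis
  w <- ifelse(case == 1L, progression_weight(ifelse(is.na(t_days), 0, t_days),
                                             config), 0)
  gmat <- gmat + outer(truth$true_prediag_effect_at_diagnosis, w)

  # per-gene fixed covariate effects (standardized continuous, 0/1 indicators)
  X <- cbind(scale(pheno$age)[, 1], scale(pheno$bmi)[, 1],
             as.numeric(pheno$sex == "M"),
             as.numeric(pheno$country == "sweden"),
             as.numeric(pheno$phase == "B"))
  B <- matrix(rnorm(G * ncol(X), 0, config$covariate_effect_sd), nrow = G)
  gmat <- gmat + B %*% t(X)

  # per-gene random intercepts for each batch-date factor level
  for (bf in c("isolation_date", "hybridization_date", "labeling_date")) {
    lev <- sort(unique(pheno[[bf]]))
    U <- matrix(rnorm(G * length(lev), 0, config$batch_sd), nrow = G,
                dimnames = list(NULL, lev))
    gmat <- gmat + U[, pheno[[bf]], drop = FALSE]
  }

  pr <- .expand_to_probes(gmat, config, "pre")
  list(expr = pr$expr, probe_map = pr$probe_map, pheno = pheno,
       truth = truth)
}
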
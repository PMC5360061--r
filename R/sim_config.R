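#' Configuration for the synthetic clinical/prediagnostic simulator
#'
#' Builds and validates the parameter set that drives both simulators. The
#' defaults emulate the setting the analysis is designed for: nine clinical
#' case-control studies (six peripheral-blood, two bone-marrow, one
#' lymph-node) of moderate size on heterogeneous platforms, and a single
#' prediagnostic cohort of 39 future CLL cases and 438 healthy controls whose
#' case signal strengthens as blood draw approaches diagnosis and is
#' confounded by fixed covariates and three batch-date factors.
#'
#' @param n_genes number of simulated genes.
#' @param n_studies number of clinical studies.
#' @param n_cases,n_controls per-study group sizes; recycled to `n_studies`.
#' @param tissues character vector of per-study tissue labels in
#'   `c("blood", "bone_marrow", "lymph_node")`. Default: six blood studies,
#'   two bone marrow, one lymph node when `n_studies >= 4`, else all blood.
#' @param probe_multiplicity named probabilities over 1, 2 or 3 probes per
#'   gene.
#' @param class_fractions named proportions over the planted gene classes
#'   `shared_up`, `shared_down`, `prediag_only_up`, `prediag_only_down`,
#'   `clinical_only_up`, `clinical_only_down`, `dissimilar`, `null`; must sum
#'   to 1.
#' @param delta_clinical standardized effect magnitude (units of the
#'   within-group SD) planted in cases of the clinical studies for
#'   clinical-signal classes.
#' @param delta_prediag_max prediagnostic effect magnitude at the moment of
#'   diagnosis; the realized per-sample effect is
#'   `delta_prediag_max * progression_weight(t)`.
#' @param tau between-study heterogeneity SD added to the per-study true
#'   effect of clinical-signal genes.
#' @param n_prediag_cases,n_prediag_controls prediagnostic cohort sizes.
#' @param followup_range_years interval (years) from which case
#'   time-to-diagnosis is drawn uniformly.
#' @param progression_model `"linear"` (weight `1 - t/t_max`) or
#'   `"exponential"` (weight `exp(-t/t_med)`).
#' @param batch_counts named counts of distinct levels for the RNA isolation,
#'   hybridization and dye-labeling date factors.
#' @param batch_sd SD of the per-gene random batch intercepts.
#' @param covariate_effect_sd SD of the per-gene fixed-covariate
#'   coefficients.
#' @param missing_fraction fraction of genes omitted (unmeasured) from each
#'   clinical study, to force a nontrivial common-universe intersection.
#' @param probe_offset_sd SD of the additive per-probe offset constants.
#' @param seed integer seed; all simulator randomness derives from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_clinical_studies()], [simulate_prediag_cohort()]
#' @export
sim_config <- function(n_genes = 2000L,
                       n_studies = 9L,
                       n_cases = 30L,
                       n_controls = 30L,
                       tissues = NULL,
                       probe_multiplicity = c(`1` = 0.5, `2` = 0.3, `3` = 0.2),
                       class_fractions = c(shared_up = 0.02,
                                           shared_down = 0.02,
                                           prediag_only_up = 0.02,
                                           prediag_only_down = 0.02,
                                           clinical_only_up = 0.02,
                                           clinical_only_down = 0.02,
                                           dissimilar = 0.01,
                                           null = 0.87),
                       delta_clinical = 1.2,
                       delta_prediag_max = 1.5,
                       tau = 0.2,
                       n_prediag_cases = 39L,
                       n_prediag_controls = 438L,
                       followup_range_years = c(1, 17),
                       progression_model = c("linear", "exponential"),
                       batch_counts = c(isolation = 8L, hybridization = 8L,
                                        labeling = 4L),
                       batch_sd = 0.3,
                       covariate_effect_sd = 0.1,
                       missing_fraction = 0.1,
                       probe_offset_sd = 0.25,
                       seed = 1L) {
  progression_model <- match.arg(progression_model)
  n_genes <- as.integer(n_genes)
  n_studies <- as.integer(n_studies)
  n_cases <- rep_len(as.integer(n_cases), n_studies)
  n_controls <- rep_len(as.integer(n_controls), n_studies)
  if (is.null(tissues)) {
    tissues <- if (n_studies >= 4L) {
      c(rep("blood", n_studies - 3L), "bone_marrow", "bone_marrow",
        "lymph_node")
    } else {
      rep("blood", n_studies)
    }
  }
  tissues <- rep_len(tissues, n_studies)

  stopifnot(n_genes >= 1L, n_studies >= 1L,
            n_prediag_cases >= 1L, n_prediag_controls >= 1L,
            delta_clinical >= 0, delta_prediag_max >= 0, tau >= 0,
            batch_sd >= 0, covariate_effect_sd >= 0,
            missing_fraction >= 0, missing_fraction < 1,
            probe_offset_sd >= 0)
  if (any(n_cases < 1L) || any(n_controls < 1L))
    stop("every clinical study needs at least one case and one control")
  if (!all(tissues %in% c("blood", "bone_marrow", "lymph_node")))
    stop("unknown tissue label")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1 (tolerance 1e-9)")
  classes <- c("shared_up", "shared_down", "prediag_only_up",
               "prediag_only_down", "clinical_only_up", "clinical_only_down",
               "dissimilar", "null")
  if (!setequal(names(class_fractions), classes))
    stop("class_fractions must be named over the eight planted classes")
  if (any(class_fractions < 0)) stop("class_fractions must be non-negative")
  if (!setequal(names(probe_multiplicity), c("1", "2", "3")) ||
      any(probe_multiplicity < 0) ||
      abs(sum(probe_multiplicity) - 1) > 1e-9)
    stop("probe_multiplicity must be probabilities over 1, 2, 3")
  if (length(followup_range_years) != 2L ||
      any(followup_range_years <= 0) ||
      followup_range_years[1] >= followup_range_years[2])
    stop("followup_range_years must be an increasing positive interval")
  if (!setequal(names(batch_counts),
                c("isolation", "hybridization", "labeling")) ||
      any(batch_counts < 1L))
    stop("batch_counts must name isolation, hybridization, labeling")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L || seed > .Machine$integer.max - 10L)
    stop("seed must be a non-negative 32-bit integer")

  structure(list(
    n_genes = n_genes, n_studies = n_studies,
    n_cases = n_cases, n_controls = n_controls, tissues = tissues,
    probe_multiplicity = probe_multiplicity[c("1", "2", "3")],
    class_fractions = class_fractions[classes],
    delta_clinical = delta_clinical,
    delta_prediag_max = delta_prediag_max, tau = tau,
    n_prediag_cases = as.integer(n_prediag_cases),
    n_prediag_controls = as.integer(n_prediag_controls),
    followup_range_years = as.numeric(followup_range_years),
    progression_model = progression_model,
    batch_counts = vapply(batch_counts[c("isolation", "hybridization",
                                         "labeling")], as.integer, 1L),
    batch_sd = batch_sd,
    covariate_effect_sd = covariate_effect_sd,
    missing_fraction = missing_fraction,
    probe_offset_sd = probe_offset_sd,
    seed = seed
  ), class = "sim_config")
}
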
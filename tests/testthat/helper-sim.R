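# Shared fixtures, built in code and memoised for the duration of a run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small, fast configuration used by most unit tests
small_config <- function(overrides = list()) {
  defaults <- list(
    n_genes = 250L, n_studies = 4L, n_cases = 25L, n_controls = 25L,
    n_prediag_cases = 20L, n_prediag_controls = 80L,
    batch_counts = c(isolation = 4L, hybridization = 4L, labeling = 2L),
    seed = 42L
  )
  do.call(sim_config, utils::modifyList(defaults, overrides))
}

# a tiny harmonized two-arm dataset shared across overlap/downstream tests
small_pipeline_fixture <- function() {
  cached("small_pipeline", {
    cfg <- small_config(list(
      n_genes = 300L,
      tissues = c("blood", "blood", "bone_marrow", "lymph_node"),
      class_fractions = c(shared_up = 0.08, shared_down = 0.08,
                          prediag_only_up = 0.06, prediag_only_down = 0.06,
                          clinical_only_up = 0.05, clinical_only_down = 0.05,
                          dissimilar = 0.02, null = 0.6),
      delta_clinical = 1.5, delta_prediag_max = 2,
      n_prediag_cases = 30L, n_prediag_controls = 120L
    ))
    truth <- make_ground_truth(cfg)
    cl <- simulate_clinical_studies(cfg, truth)
    co <- simulate_prediag_cohort(cfg, truth)
    res <- suppressWarnings(run_pipeline(cl$studies, co))
    list(cfg = cfg, truth = truth, clinical = cl, cohort = co, res = res)
  })
}

# brute-force enumeration oracle for one- and two-sided 2x2 Fisher tests
fisher_enum_oracle <- function(a, b, c, d, sided = "one") {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  n <- r1 + r2
  xs <- max(0, k - r2):min(r1, k)
  pr <- exp(lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(n, k))
  if (sided == "one") {
    sum(pr[xs >= a])
  } else {
    p_obs <- pr[xs == a]
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
}

# hypergeometric enrichment oracle by full enumeration
enrichment_enum_oracle <- function(q, K, N, k) {
  xs <- max(0, k - (N - K)):min(k, K)
  pr <- exp(lchoose(K, xs) + lchoose(N - K, k - xs) - lchoose(N, k))
  sum(pr[xs >= q])
}
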
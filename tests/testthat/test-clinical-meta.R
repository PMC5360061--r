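test_that("Hedges-corrected standardized effect matches direct arithmetic", {
  # groups with equal means: d = 0, v = (n1+n2)/(n1*n2)
  x <- c(1, 2, 3, 4)
  y <- c(4, 3, 2, 1)
  eff <- standardized_effect(x, y)
  expect_equal(unname(eff["d"]), 0)
  expect_equal(unname(eff["v"]), 8 / 16)

  # means 1 vs 0, pooled SD exactly 1, n1 = n2 = 10:
  # d = (1 - 3/71) * 1 = 0.9577, v = 20/100 + d^2/40 = 0.2229
  set.seed(3)
  ctrl <- as.numeric(scale(rnorm(10)))
  case <- ctrl + 1
  eff <- standardized_effect(case, ctrl)
  expect_equal(round(unname(eff["d"]), 4), 0.9577)
  expect_equal(round(unname(eff["v"]), 4), 0.2229)

  # antisymmetry under label swap
  swapped <- standardized_effect(ctrl, case)
  expect_equal(unname(swapped["d"]), -unname(eff["d"]))
  expect_equal(unname(swapped["v"]), unname(eff["v"]))

  # zero pooled SD is flagged, not fabricated
  flat <- standardized_effect(c(1, 1, 1), c(1, 1, 1))
  expect_true(is.na(flat["d"]) && is.na(flat["v"]))
  expect_error(standardized_effect(1, c(1, 2)), ">= 2")
})

test_that("DerSimonian-Laird pooling matches hand arithmetic", {
  # homogeneous: Q = 0, tau2 = 0, mu = 0.5, se = sqrt(1/20) = 0.2236
  r <- dl_random_effects(c(0.5, 0.5), c(0.1, 0.1))
  expect_equal(r$Q, 0)
  expect_equal(r$tau2, 0)
  expect_equal(r$mu, 0.5)
  expect_equal(r$se, 0.2236, tolerance = 1e-4)
  expect_equal(r$p_Q, 1)  # chi-square upper tail at 0

  # maximally heterogeneous: w = (10, 10), d_FE = 0, Q = 20,
  # tau2 = (20 - 1)/(20 - 200/20) = 1.9, mu = 0
  r <- dl_random_effects(c(1, -1), c(0.1, 0.1))
  expect_equal(r$Q, 20)
  expect_equal(r$tau2, 1.9)
  expect_equal(r$mu, 0)
  expect_equal(r$S, 2L)

  # fewer than two valid effects: missing meta fields
  r <- dl_random_effects(c(0.5, NA), c(0.1, NA))
  expect_true(is.na(r$mu) && is.na(r$p))
  expect_equal(r$S, 1L)
})

test_that("DL pooling agrees with metafor on random instances", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (i in 1:25) {
    S <- sample(2:8, 1)
    d <- rnorm(S, 0, 1.5)
    v <- runif(S, 0.02, 0.5)
    ours <- dl_random_effects(d, v)
    ref <- metafor::rma(yi = d, vi = v, method = "DL")
    expect_equal(ours$mu, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(ours$se, ref$se, tolerance = 1e-10)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(ours$Q, ref$QE, tolerance = 1e-10)
    expect_equal(ours$p_Q, ref$QEp, tolerance = 1e-10)
  }
})

test_that("with tau2 = 0 the random-effects pool equals the fixed-effects pool", {
  set.seed(21)
  hits <- 0
  for (i in 1:50) {
    d <- rnorm(4, 0.3, 0.05)
    v <- runif(4, 0.1, 0.3)
    r <- dl_random_effects(d, v)
    if (r$tau2 == 0) {
      hits <- hits + 1
      w <- 1 / v
      expect_equal(r$mu, sum(w * d) / sum(w), tolerance = 1e-12)
      expect_equal(r$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
    }
  }
  expect_gt(hits, 5)  # the homogeneous regime was actually exercised
})

test_that("the gene-wise meta-analysis matches a per-gene scalar recomputation", {
  fx <- small_pipeline_fixture()
  gms <- lapply(fx$clinical$studies, function(st) {
    suppressWarnings(harmonize_study(st$expr, st$probe_map, st$pheno,
                                     st$tissue, st$study_id))
  })
  meta <- run_meta_analysis(gms)
  ig <- intersect_gene_universe(gms)
  for (g in sample(ig$universe, 12)) {
    effs <- vapply(ig$studies, function(s) {
      standardized_effect(s$expr[g, s$pheno$case == 1],
                          s$expr[g, s$pheno$case == 0])[c("d", "v")]
    }, c(d = 0, v = 0))
    ref <- dl_random_effects(effs["d", ], effs["v", ])
    row <- meta[meta$gene == g, ]
    expect_equal(row$mu, ref$mu, tolerance = 1e-12)
    expect_equal(row$se, ref$se, tolerance = 1e-12)
    expect_equal(row$Q, ref$Q, tolerance = 1e-12)
    expect_equal(row$tau2, ref$tau2, tolerance = 1e-12)
    expect_equal(row$p_Q, ref$p_Q, tolerance = 1e-12)
  }
  # invariance under permutation of the study list
  meta_perm <- run_meta_analysis(gms[c(3, 1, 4, 2)])
  expect_equal(meta_perm$mu, meta$mu)
  expect_equal(meta_perm$gene, meta$gene)
})

test_that("tissue filtering pools exactly the requested studies", {
  fx <- small_pipeline_fixture()
  gms <- lapply(fx$clinical$studies, function(st) {
    suppressWarnings(harmonize_study(st$expr, st$probe_map, st$pheno,
                                     st$tissue, st$study_id))
  })
  n_blood <- sum(vapply(gms, function(g) g$tissue == "blood", TRUE))
  meta_blood <- run_meta_analysis(gms, tissue_filter = "blood")
  expect_equal(attr(meta_blood, "n_studies"), n_blood)
  expect_true(all(meta_blood$S <= n_blood))
  expect_error(run_meta_analysis(gms, tissue_filter = "lymph_node"),
               "fewer than two")
})

test_that("between-study heterogeneity concentrates Q on the planted subset", {
  cfg <- small_config(list(
    n_genes = 400L, n_studies = 6L, n_cases = 40L, n_controls = 40L,
    class_fractions = c(shared_up = 0.25, shared_down = 0, prediag_only_up = 0,
                        prediag_only_down = 0, clinical_only_up = 0,
                        clinical_only_down = 0, dissimilar = 0, null = 0.75),
    delta_clinical = 0.5, tau = 0.8, missing_fraction = 0, seed = 5L
  ))
  cl <- simulate_clinical_studies(cfg)
  gms <- lapply(cl$studies, function(st) {
    suppressWarnings(harmonize_study(st$expr, st$probe_map, st$pheno,
                                     st$tissue, st$study_id))
  })
  meta <- run_meta_analysis(gms)
  planted <- cl$truth$gene_id[cl$truth$planted_class == "shared_up"]
  frac_sig <- function(genes) {
    mean(meta$p_Q[meta$gene %in% genes] < 0.05)
  }
  expect_gt(frac_sig(planted), 0.5)
  expect_lt(frac_sig(setdiff(meta$gene, planted)), 0.15)
})
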
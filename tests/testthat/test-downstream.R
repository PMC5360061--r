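test_that("gene-set PCA retains >5% components with a fixed sign convention", {
  set.seed(2)
  n <- 40
  base <- rnorm(n)
  # two perfectly correlated genes: PC1 carries all the variance
  expr <- rbind(gA = base, gB = 2 * base + 3)
  colnames(expr) <- sprintf("s%02d", 1:n)
  pc <- pca_gene_set(expr)
  expect_equal(pc$var_frac[1], 1, tolerance = 1e-12)
  expect_equal(length(pc$retained), 1L)
  expect_true(sum(pc$loadings[, 1]) > 0)  # deterministic orientation
  # variance fractions sum to 1 when nothing is dropped
  expr2 <- matrix(rnorm(10 * n), nrow = 10,
                  dimnames = list(sprintf("g%d", 1:10), colnames(expr)))
  pc2 <- pca_gene_set(expr2)
  expect_equal(sum(pc2$var_frac), 1)
  # constant rows are dropped with a warning; too few genes is an error
  expr3 <- rbind(expr2, flat = rep(1, n))
  expect_warning(pc3 <- pca_gene_set(expr3), "constant")
  expect_equal(pc3$dropped_genes, "flat")
  expect_error(pca_gene_set(expr2[1, , drop = FALSE]), "2 usable genes")
  expect_error(suppressWarnings(pca_gene_set(rbind(a = c(1, 2), b = c(2, 1)))),
               "3 samples")
})

test_that("a planted latent factor dominates PC1 and survives gene reordering", {
  set.seed(4)
  n <- 60
  latent <- rnorm(n)
  expr <- t(sapply(1:15, function(i) latent + rnorm(n)))  # SNR 1
  dimnames(expr) <- list(sprintf("g%02d", 1:15), sprintf("s%02d", 1:n))
  pc <- pca_gene_set(expr)
  expect_gt(pc$var_frac[1], max(pc$var_frac[-1]))
  perm <- sample(15)
  pc_perm <- pca_gene_set(expr[perm, ])
  expect_equal(abs(cor(pc$scores[, 1], pc_perm$scores[, 1])), 1,
               tolerance = 1e-9)
})

test_that("PC cross-correlations find shared latent structure", {
  set.seed(5)
  n <- 80
  shared <- rnorm(n)
  mk <- function(k, factor) {
    m <- t(sapply(1:k, function(i) factor + rnorm(n)))
    dimnames(m) <- list(sprintf("s%d_g%02d", k, 1:k), sprintf("s%02d", 1:n))
    pca_gene_set(m)
  }
  a <- mk(10, shared)
  b <- mk(12, shared)
  expect_gt(abs(pc_cross_correlation(a, b)[1, 1]), 0.8)
  # orthogonal factors: near-zero leading correlation
  c_ <- mk(12, rnorm(n))
  expect_lt(abs(pc_cross_correlation(a, c_)[1, 1]), 0.4)
  # self-correlation is the identity on the diagonal
  expect_equal(unname(diag(pc_cross_correlation(a, a))),
               rep(1, ncol(a$scores)))
  bad <- b
  rownames(bad$scores) <- rev(rownames(bad$scores))
  expect_error(pc_cross_correlation(a, bad), "different samples")
})

test_that("time-to-diagnosis association recovers planted progression", {
  cfg <- small_config(list(
    n_genes = 120L,
    class_fractions = c(shared_up = 0.25, shared_down = 0.25,
                        prediag_only_up = 0, prediag_only_down = 0,
                        clinical_only_up = 0, clinical_only_down = 0,
                        dissimilar = 0, null = 0.5),
    delta_prediag_max = 2.5, n_prediag_cases = 35L,
    n_prediag_controls = 140L
  ))
  co <- simulate_prediag_cohort(cfg)
  gm <- suppressWarnings(harmonize_study(co$expr, co$probe_map))
  shared <- co$truth$gene_id[co$truth$planted_class %in%
                               c("shared_up", "shared_down")]
  pcs <- pca_gene_set(gm$expr, shared)
  assoc <- pc_time_association(pcs, co$pheno)
  # orient PC1 toward the case signal, then the slope must be negative
  ph <- co$pheno[match(rownames(pcs$scores), co$pheno$sample_id), ]
  orient <- sign(mean(pcs$scores[ph$case == 1, 1]) -
                   mean(pcs$scores[ph$case == 0, 1]))
  expect_lt(orient * assoc$slope[1], 0)
  expect_lt(assoc$p[1], 0.05)
  # constant scores give slope 0
  flat <- pcs
  flat$scores[, 1] <- 0
  expect_equal(pc_time_association(flat, co$pheno)$slope[1], 0)
  no_time <- co$pheno
  no_time$time_to_diagnosis_days <- NA_real_
  expect_error(pc_time_association(pcs, no_time), "3 cases")
})

test_that("gene-set enrichment equals the hypergeometric enumeration oracle", {
  universe <- sprintf("G%03d", 1:150)
  set.seed(6)
  significant <- sample(universe, 25)
  sets <- list(all = universe,
               hit = significant,
               none = setdiff(universe, significant)[1:30])
  for (i in 1:20) sets[[sprintf("rnd%02d", i)]] <- sample(universe,
                                                          sample(5:60, 1))
  enr <- geneset_enrichment(significant, universe, sets)
  for (j in seq_len(nrow(enr))) {
    row <- enr[j, ]
    expect_equal(row$p,
                 enrichment_enum_oracle(row$n_set_significant, 25, 150,
                                        row$n_set_universe),
                 tolerance = 1e-9, info = row$set_id)
  }
  # set == universe: no enrichment possible
  expect_equal(enr$p[enr$set_id == "all"], 1)
  # set containing all and only the significant genes: single point mass
  expect_equal(enr$p[enr$set_id == "hit"],
               exp(lchoose(25, 25) + lchoose(125, 0) - lchoose(150, 25)))
  expect_error(geneset_enrichment("X", universe, sets), "subset")
  expect_error(geneset_enrichment(character(0), character(0), sets),
               "empty universe")
})

test_that("category composition testing is conservation-consistent", {
  fx <- small_pipeline_fixture()
  calls <- fx$res$calls
  signal <- calls$gene[calls$category != "null"]
  res <- category_composition_test(signal[seq_len(min(30, length(signal)))],
                                   calls)
  expect_false(res$skipped)
  expect_true(res$p >= 0 && res$p <= 1)
  # inside + outside = per-category totals over the signal universe
  expect_equal(colSums(res$counts),
               table(factor(calls$category[calls$category != "null"],
                            levels = colnames(res$counts)))[
                              colnames(res$counts)],
               ignore_attr = TRUE)
  # identical in/out proportions: p = 1
  cats <- c("similar", "prediag_exclusive")
  balanced <- data.frame(gene = sprintf("b%02d", 1:40),
                         category = rep(rep(cats, each = 10), 2))
  res_b <- category_composition_test(balanced$gene[1:20], balanced)
  expect_equal(res_b$p, 1, tolerance = 1e-9)
  # concentration of a set in one category yields a small p
  res_c <- category_composition_test(
    balanced$gene[balanced$category == "similar"][1:10],
    balanced)
  expect_lt(res_c$p, 0.01)
  # fewer than two non-empty categories: skipped
  res_s <- category_composition_test(
    "b01", data.frame(gene = "b01", category = "similar"))
  expect_true(res_s$skipped)
})

test_that("driver-gene lookup annotates presence, significance and labels", {
  fx <- small_pipeline_fixture()
  calls <- fx$res$calls
  drivers <- c(calls$gene[1:5], "NOT_A_GENE", "ALSO_ABSENT")
  out <- driver_gene_lookup(drivers, calls)
  expect_equal(nrow(out$table), 7L)
  expect_equal(sum(out$table$present), 5L)
  expect_true(all(is.na(out$table$label[!out$table$present])))
  expect_equal(out$summary$n_present, 5L)
  # absent genes are excluded from the significance counts
  expect_lte(out$summary$n_nominal_prediag, 5L)
  # empty driver list
  empty <- driver_gene_lookup(character(0), calls)
  expect_equal(empty$summary$n_drivers, 0L)
})

test_that("GMT round-trip preserves sets and descriptions", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst pathway\tG1\tG2\tG3\tG3",
               "setB\tsecond pathway\tG2\tG9"), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("G1", "G2", "G3"))  # deduplicated
  expect_equal(unname(attr(sets, "descriptions")["setB"]), "second pathway")
})

test_that("correlation structure ordering is a permutation of the input genes", {
  fx <- small_pipeline_fixture()
  gm <- suppressWarnings(harmonize_study(fx$cohort$expr,
                                         fx$cohort$probe_map))
  genes <- rownames(gm$expr)[1:20]
  out <- gene_correlation_structure(gm$expr, genes)
  expect_setequal(out$order, genes)
  expect_equal(dim(out$cor), c(20L, 20L))
  expect_equal(unname(diag(out$cor)), rep(1, 20))
})
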
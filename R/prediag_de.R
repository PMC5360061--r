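## Build the model data.frame: case + covariates + batch factors, aligned to
## the expression columns. Covariates/batches missing from the phenotype or
## with a single observed level are dropped (logged via attributes).
.build_model_frame <- function(pheno, covariates, batch_factors) {
  use_cov <- character(0)
  dropped <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(pheno)) {
      dropped <- c(dropped, cv)
    } else if (is.numeric(pheno[[cv]])) {
      use_cov <- c(use_cov, cv)
    } else if (length(unique(pheno[[cv]])) >= 2L) {
      use_cov <- c(use_cov, cv)
    } else {
      dropped <- c(dropped, cv)
    }
  }
  use_batch <- character(0)
  for (bf in batch_factors) {
    if (bf %in% names(pheno) && length(unique(pheno[[bf]])) >= 2L) {
      use_batch <- c(use_batch, bf)
    } else {
      dropped <- c(dropped, bf)
    }
  }
  mf <- pheno[, unique(c("case", use_cov, use_batch)), drop = FALSE]
  for (cl in names(mf)) {
    if (is.character(mf[[cl]])) mf[[cl]] <- factor(mf[[cl]])
  }
  attr(mf, "covariates") <- use_cov
  attr(mf, "batch_factors") <- use_batch
  attr(mf, "dropped_terms") <- dropped
  mf
}

.de_formula <- function(covariates, batch_factors) {
  fixed <- paste(c("case", covariates), collapse = " + ")
  re <- if (length(batch_factors)) {
    paste(sprintf("(1 | %s)", batch_factors), collapse = " + ")
  } else {
    NULL
  }
  stats::as.formula(paste("y ~", paste(c(fixed, re), collapse = " + ")))
}

## Extract the case coefficient from an lmerMod or lm fit.
.case_coef <- function(fit) {
  if (inherits(fit, "merMod")) {
    fe <- lme4::fixef(fit)
    b <- fe[["case"]]
    se <- sqrt(diag(as.matrix(stats::vcov(fit)))[which(names(fe) == "case")])
  } else {
    cf <- summary(fit)$coefficients
    b <- cf["case", "Estimate"]
    se <- cf["case", "Std. Error"]
  }
  z <- b / se
  list(beta_case = unname(b), se = unname(se),
       p = 2 * stats::pnorm(-abs(z)))
}

## Names of random-effect groups whose variance is (numerically) zero.
.zero_variance_groups <- function(fit) {
  vc <- lme4::VarCorr(fit)
  vars <- vapply(vc, function(m) m[1, 1], 1.0)
  names(vars)[vars < 1e-8]
}

#' Fit the prediagnostic mixed model for a single gene
#'
#' Models normalized expression as a function of case status and fixed
#' covariates, with independent random intercepts for the batch-date
#' factors, estimated by REML. The case coefficient is tested with a
#' two-sided Wald z-test. When a random-intercept variance estimates at
#' zero, the gene is refit with that component removed (down to ordinary
#' least squares when all components vanish) so the reported fit equals the
#' reduced model exactly.
#'
#' @param y numeric expression vector, aligned to `pheno` rows.
#' @param pheno phenotype data.frame with `case` (0/1) plus covariates and
#'   batch factors.
#' @param covariates fixed-covariate column names.
#' @param batch_factors random-intercept column names.
#' @return list: `beta_case`, `se`, `p`, `converged`, `degenerate`,
#'   `re_dropped` (names of removed variance components).
#' @export
fit_gene_mixed_model <- function(y, pheno,
                                 covariates = c("age", "sex", "country",
                                                "phase", "bmi"),
                                 batch_factors = c("isolation_date",
                                                   "hybridization_date",
                                                   "labeling_date")) {
  stopifnot(length(y) == nrow(pheno))
  mf <- .build_model_frame(pheno, covariates, batch_factors)
  if (stats::sd(y, na.rm = TRUE) == 0 || all(is.na(y))) {
    return(list(beta_case = 0, se = NA_real_, p = NA_real_,
                converged = TRUE, degenerate = TRUE,
                re_dropped = character(0)))
  }
  dat <- cbind(y = y, mf)
  fit_with <- function(batches) {
    fml <- .de_formula(attr(mf, "covariates"), batches)
    if (length(batches)) {
      lme4::lmer(fml, data = dat, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    } else {
      stats::lm(fml, data = dat)
    }
  }
  batches <- attr(mf, "batch_factors")
  dropped <- character(0)
  fit <- try(suppressMessages(suppressWarnings(fit_with(batches))), silent = TRUE)
  while (!inherits(fit, "try-error") && inherits(fit, "merMod")) {
    zero <- .zero_variance_groups(fit)
    if (!length(zero)) break
    dropped <- c(dropped, zero)
    batches <- setdiff(batches, zero)
    fit <- try(suppressMessages(suppressWarnings(fit_with(batches))), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    return(list(beta_case = NA_real_, se = NA_real_, p = NA_real_,
                converged = FALSE, degenerate = FALSE,
                re_dropped = dropped))
  }
  c(.case_coef(fit), list(converged = TRUE, degenerate = FALSE,
                          re_dropped = dropped))
}

#' Gene-wise mixed-model differential expression of the prediagnostic cohort
#'
#' Fits [fit_gene_mixed_model()] to every gene of a harmonized gene matrix.
#' For speed a single model template is fitted and refit with each gene's
#' expression vector (identical estimation; the template is re-estimated
#' from scratch whenever a variance component hits zero and the reduced
#' model is required). The Bonferroni threshold is `alpha / G_pre` with
#' `G_pre` the number of genes attempted, including non-converged and
#' degenerate genes (conservative universe accounting).
#'
#' @param expr genes x samples matrix (collapsed and INT-transformed).
#' @param pheno phenotype data.frame with `sample_id` matching the matrix
#'   columns.
#' @inheritParams fit_gene_mixed_model
#' @param alpha significance level, default 0.05.
#' @return data.frame `gene`, `beta_case`, `se`, `p`, `converged`,
#'   `bonferroni`, `nominal`, sorted by `p` ascending (ties by gene).
#'   Attributes: `n_genes` (`G_pre`), `alpha_bonferroni`, `dropped_terms`.
#' @export
run_prediag_de <- function(expr, pheno,
                           covariates = c("age", "sex", "country", "phase",
                                          "bmi"),
                           batch_factors = c("isolation_date",
                                             "hybridization_date",
                                             "labeling_date"),
                           alpha = 0.05) {
  if (!"sample_id" %in% names(pheno)) stop("pheno needs a sample_id column")
  missing_samp <- setdiff(colnames(expr), pheno$sample_id)
  extra_samp <- setdiff(pheno$sample_id, colnames(expr))
  if (length(missing_samp) || length(extra_samp))
    stop("expression/phenotype sample mismatch: ",
         paste(c(missing_samp, extra_samp), collapse = ", "))
  pheno <- pheno[match(colnames(expr), pheno$sample_id), , drop = FALSE]

  mf <- .build_model_frame(pheno, covariates, batch_factors)
  use_cov <- attr(mf, "covariates")
  use_batch <- attr(mf, "batch_factors")
  G <- nrow(expr)

  ## cached model templates, one per retained-batch subset
  templates <- new.env(parent = emptyenv())
  get_fit <- function(y, batches) {
    key <- paste(batches, collapse = "+")
    dat <- cbind(y = y, mf)
    if (!length(batches)) {
      return(stats::lm(.de_formula(use_cov, character(0)), data = dat))
    }
    if (is.null(templates[[key]])) {
      templates[[key]] <- lme4::lmer(
        .de_formula(use_cov, batches), data = dat, REML = TRUE,
        control = lme4::lmerControl(calc.derivs = FALSE,
                                    check.conv.singular = "ignore"))
      return(templates[[key]])
    }
    lme4::refit(templates[[key]], newresp = y)
  }

  out <- data.frame(gene = rownames(expr), beta_case = NA_real_,
                    se = NA_real_, p = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(G)) {
    y <- expr[i, ]
    if (anyNA(y) || stats::sd(y) == 0) {
      deg <- fit_gene_mixed_model(y[!is.na(y)],
                                  pheno[!is.na(y), , drop = FALSE],
                                  covariates, batch_factors)
      out$beta_case[i] <- deg$beta_case
      out$se[i] <- deg$se
      out$p[i] <- deg$p
      out$converged[i] <- deg$converged
      next
    }
    batches <- use_batch
    fit <- try(suppressMessages(suppressWarnings(get_fit(y, batches))), silent = TRUE)
    while (!inherits(fit, "try-error") && inherits(fit, "merMod")) {
      zero <- .zero_variance_groups(fit)
      if (!length(zero)) break
      batches <- setdiff(batches, zero)
      fit <- try(suppressMessages(suppressWarnings(get_fit(y, batches))), silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    cc <- .case_coef(fit)
    out$beta_case[i] <- cc$beta_case
    out$se[i] <- cc$se
    out$p[i] <- cc$p
    out$converged[i] <- TRUE
  }
  alpha_bonf <- alpha / G
  out$bonferroni <- !is.na(out$p) & out$p < alpha_bonf
  out$nominal <- !is.na(out$p) & out$p < alpha
  ord <- order(out$p, out$gene, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_genes") <- G
  attr(out, "alpha_bonferroni") <- alpha_bonf
  attr(out, "dropped_terms") <- attr(mf, "dropped_terms")
  out
}

#' Write a differential-expression result table as TSV
#'
#' @param res result of [run_prediag_de()].
#' @param path output file.
#' @export
write_de_results <- function(res, path) {
  .write_table_tsv(res, path)
}
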
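#' Hedges-corrected standardized mean difference for one gene in one study
#'
#' Computes `d = J * (mean_case - mean_control) / s_pooled` with the
#' small-sample correction `J = 1 - 3/(4(n1 + n2 - 2) - 1)`, and its
#' large-sample variance `v = (n1 + n2)/(n1 n2) + d^2 / (2(n1 + n2))`.
#'
#' @param case,control numeric vectors of expression values (>= 2 each;
#'   missing values dropped).
#' @return named numeric vector `c(d, v, n_case, n_control)`; `d` and `v`
#'   are `NA` when the pooled SD is zero (the effect is flagged, not
#'   fabricated).
#' @export
standardized_effect <- function(case, control) {
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  n1 <- length(case)
  n2 <- length(control)
  if (n1 < 2L || n2 < 2L)
    stop("standardized_effect needs >= 2 non-missing values per group")
  sp2 <- ((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(control)) /
    (n1 + n2 - 2)
  if (sp2 <= 0)
    return(c(d = NA_real_, v = NA_real_, n_case = n1, n_control = n2))
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  d <- J * (mean(case) - mean(control)) / sqrt(sp2)
  v <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  c(d = d, v = v, n_case = n1, n_control = n2)
}

#' DerSimonian-Laird random-effects pooling of one gene's study effects
#'
#' Pools standardized effects with inverse-variance fixed weights to obtain
#' Cochran's `Q`, estimates the between-study variance by the
#' DerSimonian-Laird moment estimator
#' `tau2 = max(0, (Q - (S-1)) / (sum(w) - sum(w^2)/sum(w)))`, and re-pools
#' with weights `1/(v + tau2)`. The pooled z-test is two-sided normal and
#' `Q` is referred to a chi-square with `S - 1` degrees of freedom.
#'
#' @param d numeric vector of per-study standardized effects.
#' @param v their variances (same length, positive).
#' @return list with `mu`, `se`, `z`, `p`, `Q`, `p_Q`, `tau2`, `S`. All
#'   meta fields are `NA` when fewer than two valid effects remain.
#' @export
dl_random_effects <- function(d, v) {
  ok <- !is.na(d) & !is.na(v) & v > 0
  d <- d[ok]
  v <- v[ok]
  S <- length(d)
  if (S < 2L) {
    return(list(mu = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                Q = NA_real_, p_Q = NA_real_, tau2 = NA_real_, S = S))
  }
  w <- 1 / v
  d_fe <- sum(w * d) / sum(w)
  Q <- sum(w * (d - d_fe)^2)
  tau2 <- max(0, (Q - (S - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  mu <- sum(ws * d) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- mu / se
  list(mu = mu, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       Q = Q, p_Q = stats::pchisq(Q, df = S - 1, lower.tail = FALSE),
       tau2 = tau2, S = S)
}

## Vectorized per-study effects: D and V columns for one gene matrix.
.study_effect_columns <- function(expr, case_flag) {
  ca <- expr[, case_flag == 1L, drop = FALSE]
  co <- expr[, case_flag == 0L, drop = FALSE]
  n1 <- rowSums(!is.na(ca))
  n2 <- rowSums(!is.na(co))
  m1 <- rowMeans(ca, na.rm = TRUE)
  m2 <- rowMeans(co, na.rm = TRUE)
  ss1 <- rowSums((ca - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((co - m2)^2, na.rm = TRUE)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  d <- J * (m1 - m2) / sqrt(sp2)
  v <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  bad <- !is.finite(d) | sp2 <= 0 | n1 < 2L | n2 < 2L
  d[bad] <- NA_real_
  v[bad] <- NA_real_
  list(d = d, v = v, n_excluded = sum(bad))
}

## Vectorized DL pooling over a genes x studies effect matrix.
.dl_pool_matrix <- function(D, V) {
  W <- 1 / V
  S <- rowSums(!is.na(D) & !is.na(V))
  sw <- rowSums(W, na.rm = TRUE)
  d_fe <- rowSums(W * D, na.rm = TRUE) / sw
  Q <- rowSums(W * (D - d_fe)^2, na.rm = TRUE)
  sw2 <- rowSums(W^2, na.rm = TRUE)
  tau2 <- pmax(0, (Q - (S - 1)) / (sw - sw2 / sw))
  Ws <- 1 / (V + tau2)  # tau2 recycles down columns (per gene)
  mu <- rowSums(Ws * D, na.rm = TRUE) / rowSums(Ws, na.rm = TRUE)
  se <- 1 / sqrt(rowSums(Ws, na.rm = TRUE))
  z <- mu / se
  res <- data.frame(
    mu = mu, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
    Q = Q, p_Q = stats::pchisq(Q, df = pmax(S - 1, 1), lower.tail = FALSE),
    tau2 = tau2, S = S
  )
  res[S < 2L, c("mu", "se", "z", "p", "Q", "p_Q", "tau2")] <- NA_real_
  res
}

#' Gene-wise random-effects meta-analysis across clinical studies
#'
#' Restricts the studies to their common gene universe, computes a
#' Hedges-corrected standardized mean difference (case minus control) per
#' gene and study, and pools by DerSimonian-Laird random effects with
#' Cochran Q heterogeneity assessment. Bonferroni significance is assessed
#' at `alpha / G` where `G` is the universe size.
#'
#' @param studies list of harmonized `"gene_matrix"` objects with `pheno`
#'   containing a binary `case` column.
#' @param tissue_filter optional character vector; only studies whose
#'   `tissue` is in this set are pooled (the peripheral-blood sensitivity
#'   analysis uses `"blood"`).
#' @param alpha significance level, default 0.05.
#' @return data.frame with columns `gene`, `mu`, `se`, `z`, `p`, `Q`,
#'   `p_Q`, `tau2`, `S`, `bonferroni`, `nominal`, sorted by `p` (ties by
#'   gene). Attributes: `universe_size`, `universe`, `n_studies`,
#'   `alpha_bonferroni`, `het_bonferroni_fraction` (fraction of genes with
#'   Bonferroni-significant Q) and `n_zero_sd_excluded`.
#' @export
run_meta_analysis <- function(studies, tissue_filter = NULL, alpha = 0.05) {
  if (!is.null(tissue_filter)) {
    studies <- Filter(function(s) s$tissue %in% tissue_filter, studies)
  }
  if (length(studies) < 2L)
    stop("fewer than two studies remain after tissue filtering")
  ig <- intersect_gene_universe(studies)
  G <- length(ig$universe)
  D <- V <- matrix(NA_real_, nrow = G, ncol = length(ig$studies))
  n_excl <- 0L
  for (j in seq_along(ig$studies)) {
    st <- ig$studies[[j]]
    eff <- .study_effect_columns(st$expr, st$pheno$case)
    D[, j] <- eff$d
    V[, j] <- eff$v
    n_excl <- n_excl + eff$n_excluded
  }
  res <- .dl_pool_matrix(D, V)
  res <- cbind(gene = ig$universe, res, stringsAsFactors = FALSE)
  alpha_bonf <- alpha / G
  res$bonferroni <- !is.na(res$p) & res$p < alpha_bonf
  res$nominal <- !is.na(res$p) & res$p < alpha
  ord <- order(res$p, res$gene, na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "universe_size") <- G
  attr(res, "universe") <- ig$universe
  attr(res, "n_studies") <- length(ig$studies)
  attr(res, "alpha_bonferroni") <- alpha_bonf
  attr(res, "het_bonferroni_fraction") <-
    mean(res$p_Q < alpha_bonf, na.rm = TRUE)
  attr(res, "n_zero_sd_excluded") <- n_excl
  res
}

#' Write a meta-analysis result table as TSV
#'
#' @param res result of [run_meta_analysis()].
#' @param path output file.
#' @export
write_meta_results <- function(res, path) {
  .write_table_tsv(res, path)
}
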
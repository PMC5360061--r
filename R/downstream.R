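#' Read gene sets from a GMT file
#'
#' @param path GMT file (tab-separated: set id, description, members...).
#' @return named list of deduplicated member-gene character vectors, with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  desc <- vapply(lines, function(x) if (length(x) >= 2) x[2] else "", "")
  names(desc) <- vapply(lines, `[`, "", 1)
  sets <- lapply(sets, unique)
  attr(sets, "descriptions") <- desc[names(sets)]
  sets
}

#' Principal components of a gene-set expression submatrix
#'
#' Restricts the (prediagnostic) gene matrix to a gene set, centers and
#' unit-scales each gene across samples, and extracts components by
#' singular value decomposition of the samples x genes matrix. Components
#' explaining more than 5% of total variance (among the first 10) are
#' retained. Each component is given a deterministic orientation: its
#' loading vector must have a positive sum (flipped otherwise).
#'
#' @param expr genes x samples matrix.
#' @param genes optional character vector restricting the rows; default all.
#' @param var_threshold retained-component variance-fraction threshold
#'   (exclusive), default 0.05.
#' @param max_components most components examined, default 10.
#' @return list of class `"pc_result"`: `scores` (samples x retained),
#'   `var_frac` (all components), `retained` (indices), `loadings`
#'   (genes x retained), `dropped_genes` (constant rows removed).
#' @export
pca_gene_set <- function(expr, genes = NULL, var_threshold = 0.05,
                         max_components = 10L) {
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(expr))
    expr <- expr[genes, , drop = FALSE]
  }
  const <- apply(expr, 1L, function(v) stats::sd(v, na.rm = TRUE) == 0)
  dropped <- rownames(expr)[const]
  if (any(const)) {
    warning(sprintf("%d constant gene row(s) dropped before PCA",
                    sum(const)))
    expr <- expr[!const, , drop = FALSE]
  }
  if (nrow(expr) < 2L) stop("need at least 2 usable genes for PCA")
  if (ncol(expr) < 3L) stop("need at least 3 samples for PCA")
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = TRUE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  retained <- intersect(which(var_frac > var_threshold),
                        seq_len(max_components))
  flip <- colSums(pc$rotation) < 0
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  structure(list(scores = pc$x[, retained, drop = FALSE],
                 var_frac = var_frac,
                 retained = retained,
                 loadings = pc$rotation[, retained, drop = FALSE],
                 dropped_genes = dropped),
            class = "pc_result")
}

#' Association of retained components with time to diagnosis
#'
#' Among cases only, regresses each retained component score on time to
#' diagnosis (days) adjusting for the fixed covariates of the
#' prediagnostic model. Covariates without variation among cases are
#' dropped automatically.
#'
#' @param pcs a [pca_gene_set()] result whose score rows match
#'   `pheno$sample_id`.
#' @param pheno phenotype table with `case` and `time_to_diagnosis_days`.
#' @param covariates fixed covariates to adjust for.
#' @return data.frame `component`, `slope` (score units per day), `se`,
#'   `p`.
#' @export
pc_time_association <- function(pcs, pheno,
                                covariates = c("age", "sex", "country",
                                               "phase", "bmi")) {
  stopifnot(inherits(pcs, "pc_result"))
  idx <- match(rownames(pcs$scores), pheno$sample_id)
  if (anyNA(idx)) stop("score rows missing from the phenotype table")
  ph <- pheno[idx, , drop = FALSE]
  cases <- ph$case == 1L & !is.na(ph$time_to_diagnosis_days)
  if (sum(cases) < 3L) stop("need at least 3 cases with time to diagnosis")
  ph <- ph[cases, , drop = FALSE]
  sc <- pcs$scores[cases, , drop = FALSE]
  use_cov <- Filter(function(cv) {
    cv %in% names(ph) && length(unique(ph[[cv]])) >= 2L
  }, covariates)
  res <- lapply(seq_len(ncol(sc)), function(k) {
    dat <- cbind(data.frame(score = sc[, k],
                            time = ph$time_to_diagnosis_days),
                 ph[, use_cov, drop = FALSE])
    fml <- stats::as.formula(paste("score ~",
                                   paste(c("time", use_cov),
                                         collapse = " + ")))
    if (stats::sd(dat$score) == 0) {
      return(data.frame(component = colnames(sc)[k], slope = 0,
                        se = NA_real_, p = NA_real_))
    }
    cf <- summary(stats::lm(fml, data = dat))$coefficients
    data.frame(component = colnames(sc)[k],
               slope = cf["time", "Estimate"],
               se = cf["time", "Std. Error"],
               p = cf["time", "Pr(>|t|)"])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pearson correlations between retained components of two gene sets
#'
#' @param a,b [pca_gene_set()] results over the same samples.
#' @return matrix of correlations, components of `a` in rows.
#' @export
pc_cross_correlation <- function(a, b) {
  stopifnot(inherits(a, "pc_result"), inherits(b, "pc_result"))
  if (!identical(rownames(a$scores), rownames(b$scores)))
    stop("the two PCA results cover different samples")
  stats::cor(a$scores, b$scores)
}

#' Gene-set enrichment of a significant gene list by Fisher exact tests
#'
#' For each supplied set, intersects its members with the analysis universe
#' and performs a one-sided hypergeometric test of over-representation of
#' the significant genes. Bonferroni correction is over the number of sets
#' with a non-empty universe intersection.
#'
#' @param significant character vector of significant genes (subset of
#'   `universe`).
#' @param universe character vector of all analyzed genes.
#' @param sets named list of member-gene vectors (see [read_gmt()]).
#' @param alpha significance level for the Bonferroni flag, default 0.05.
#' @return data.frame `set_id`, `n_set_universe`, `n_set_significant`, `p`,
#'   `bonferroni`, sorted by `p`; attribute `n_sets_tested`.
#' @export
geneset_enrichment <- function(significant, universe, sets, alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  if (!all(significant %in% universe))
    stop("significant genes must be a subset of the universe")
  K <- length(significant)
  N <- length(universe)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], universe)
    if (!length(members)) return(NULL)
    k <- length(members)
    q <- length(intersect(members, significant))
    data.frame(set_id = id, n_set_universe = k, n_set_significant = q,
               p = stats::phyper(q - 1, K, N - K, k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("no set intersects the universe")
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$bonferroni <- out$p < alpha / m
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sets_tested") <- m
  out
}

#' Category composition of a gene set against the rest of the universe
#'
#' Counts the members of a gene set falling in the four signal roll-up
#' categories (similar `++`/`--`, prediagnostic-exclusive `o+`/`o-`,
#' clinical-exclusive `+o`/`-o`, dissimilar `+-`/`-+`), compares them with
#' the same counts outside the set, and tests the 2 x k table with a Fisher
#' exact test after dropping categories empty on both sides.
#'
#' @param set_genes character vector of member genes.
#' @param calls [classify_genes()] result.
#' @return list: `counts` (2 x k matrix, rows in/out), `p`, `skipped`
#'   (TRUE when fewer than two categories are non-empty).
#' @export
category_composition_test <- function(set_genes, calls) {
  cats <- c("similar", "prediag_exclusive", "clinical_exclusive",
            "dissimilar")
  sub <- calls[calls$category %in% cats, , drop = FALSE]
  inside <- sub$gene %in% set_genes
  counts <- rbind(
    in_set = table(factor(sub$category[inside], levels = cats)),
    out_set = table(factor(sub$category[!inside], levels = cats))
  )
  nonzero <- colSums(counts) > 0
  counts_t <- counts[, nonzero, drop = FALSE]
  if (ncol(counts_t) < 2L || any(rowSums(counts_t) == 0)) {
    return(list(counts = counts, p = NA_real_, skipped = TRUE))
  }
  p <- stats::fisher.test(counts_t, workspace = 2e6)$p.value
  list(counts = counts, p = p, skipped = FALSE)
}

#' Annotate a driver-gene list against both analysis arms
#'
#' @param drivers character vector of driver gene symbols.
#' @param calls [classify_genes()] result over the common universe.
#' @return list: `table` (per driver: `gene`, `present`, `label`,
#'   `p_clinical`, `p_prediag`, `bonferroni_side`, per-arm nominal flags)
#'   and `summary` (n_drivers, n_present, per-arm Bonferroni and nominal
#'   counts, n_concordant among present genes).
#' @export
driver_gene_lookup <- function(drivers, calls) {
  drivers <- unique(drivers)
  if (!length(drivers)) {
    return(list(table = data.frame(gene = character(0)),
                summary = list(n_drivers = 0L, n_present = 0L)))
  }
  idx <- match(drivers, calls$gene)
  present <- !is.na(idx)
  tab <- data.frame(
    gene = drivers,
    present = present,
    label = ifelse(present, as.character(calls$label[idx]), NA_character_),
    p_clinical = ifelse(present, calls$p_clinical[idx], NA_real_),
    p_prediag = ifelse(present, calls$p_prediag[idx], NA_real_),
    bonferroni_side = ifelse(present,
                             calls$bonferroni_side[idx], NA_character_),
    nominal_clinical = present & calls$clinical_symbol[idx] != "o",
    nominal_prediag = present & calls$prediag_symbol[idx] != "o",
    stringsAsFactors = FALSE
  )
  summary <- list(
    n_drivers = length(drivers),
    n_present = sum(present),
    n_bonferroni_clinical = sum(tab$bonferroni_side %in%
                                  c("clinical", "both"), na.rm = TRUE),
    n_bonferroni_prediag = sum(tab$bonferroni_side %in%
                                 c("prediag", "both"), na.rm = TRUE),
    n_nominal_clinical = sum(tab$nominal_clinical),
    n_nominal_prediag = sum(tab$nominal_prediag),
    n_concordant = sum(tab$label %in% c("++", "--"), na.rm = TRUE)
  )
  list(table = tab, summary = summary)
}

#' Gene-gene correlation structure of selected genes
#'
#' Pearson correlation matrix across samples for a union of gene sets,
#' reordered by average-linkage hierarchical clustering of the correlation
#' distance, as a descriptive check for cluster structure separating
#' clinically-replicated from prediagnostic-exclusive genes.
#'
#' @param expr genes x samples matrix.
#' @param genes genes to include (>= 3).
#' @return list: `cor` (reordered correlation matrix), `order` (gene order).
#' @export
gene_correlation_structure <- function(expr, genes) {
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 3L) stop("need at least 3 genes")
  cm <- stats::cor(t(expr[genes, , drop = FALSE]))
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  list(cor = cm[hc$order, hc$order], order = genes[hc$order])
}
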
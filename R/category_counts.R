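#' Bundled reference category counts
#'
#' Loads the packaged category-count table summarizing a published
#' genome-wide comparison of prediagnostic CLL blood markers with a
#' meta-analysis of clinical-stage CLL studies: per-label counts at each
#' significance tier plus the per-arm Bonferroni totals and the common gene
#' universe size. These counts drive the worked examples of
#' [summarize_category_counts()] without requiring any expression data.
#'
#' @return list with `universe`, `clinical_bonferroni_total`,
#'   `prediag_bonferroni_total` and a `categories` data.frame (`label`,
#'   `tier`, `count`).
#' @export
reference_category_counts <- function() {
  path <- system.file("extdata", "cll_reference_category_counts.json",
                      package = "prediagmeta", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Derived summaries from a category-count table alone
#'
#' Recomputes, from category counts only, (i) the percentage of
#' clinical-arm Bonferroni genes replicated at nominal-or-better
#' significance with concordant direction in the prediagnostic arm, (ii)
#' the Bonferroni-tier overlap 2x2 table and its Fisher exact p-value, and
#' (iii) the directional Venn layers (up/down x Bonferroni/nominal). This
#' enables count-level verification of an overlap analysis without
#' expression data.
#'
#' @param counts a list shaped like [reference_category_counts()].
#' @param sided sidedness of the overlap Fisher test, default one-sided.
#' @return list: `replication_pct`, `overlap_table` (a/b/c/d),
#'   `overlap_p`, `venn` (data.frame direction x tier counts),
#'   `prediag_bonferroni_in_universe`.
#' @export
summarize_category_counts <- function(counts, sided = c("one", "two")) {
  sided <- match.arg(sided)
  cat_df <- as.data.frame(counts$categories)
  stopifnot(all(c("label", "tier", "count") %in% names(cat_df)))
  if (any(cat_df$count < 0)) stop("negative category count")
  if (sum(cat_df$count) > counts$universe)
    stop("category counts exceed the stated universe")
  if (counts$clinical_bonferroni_total < 0 || counts$universe <= 0)
    stop("inconsistent totals")
  pick <- function(labels, tiers) {
    sum(cat_df$count[cat_df$label %in% labels & cat_df$tier %in% tiers])
  }
  conc <- c("++", "--")

  ## replication: clinical Bonferroni genes that are at least nominal and
  ## direction-concordant in the prediagnostic arm
  replicated <- pick(conc, c("both_bonferroni", "clinical_bonferroni"))
  replication_pct <- 100 * replicated / counts$clinical_bonferroni_total

  ## Bonferroni-tier 2x2 on the common universe
  a <- pick(conc, "both_bonferroni")
  prediag_bonf_universe <- pick(conc, c("both_bonferroni",
                                        "prediag_bonferroni")) +
    pick("o+|o-", "prediag_bonferroni")
  b <- counts$clinical_bonferroni_total - a
  c_ <- prediag_bonf_universe - a
  d <- counts$universe - a - b - c_
  if (min(a, b, c_, d) < 0) stop("inconsistent counts: negative 2x2 cell")
  overlap_p <- fisher_overlap_test(a, b, c_, d, sided = sided)

  venn <- data.frame(
    direction = c("up", "down"),
    bonferroni = c(pick("++", c("both_bonferroni", "prediag_bonferroni",
                                "clinical_bonferroni")),
                   pick("--", c("both_bonferroni", "prediag_bonferroni",
                                "clinical_bonferroni"))),
    nominal = c(pick("++", "nominal_only"), pick("--", "nominal_only"))
  )

  list(replication_pct = replication_pct,
       overlap_table = c(a = a, b = b, c = c_, d = d),
       overlap_p = overlap_p,
       venn = venn,
       prediag_bonferroni_in_universe = prediag_bonf_universe)
}
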
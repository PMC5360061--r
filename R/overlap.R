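OVERLAP_LABELS <- c("++", "--", "+o", "-o", "o+", "o-", "+-", "-+", "oo")

.arm_symbol <- function(p, effect, alpha = 0.05) {
  sym <- rep("o", length(p))
  sig <- !is.na(p) & p < alpha & !is.na(effect)
  if (any(sig & effect == 0)) {
    warning("nominally significant gene(s) with zero effect: direction ",
            "undefined, classified 'o'")
  }
  sym[sig & effect > 0] <- "+"
  sym[sig & effect < 0] <- "-"
  sym
}

.rollup <- function(label) {
  c(`++` = "similar", `--` = "similar",
    `+o` = "clinical_exclusive", `-o` = "clinical_exclusive",
    `o+` = "prediag_exclusive", `o-` = "prediag_exclusive",
    `+-` = "dissimilar", `-+` = "dissimilar",
    oo = "null")[label]
}

#' Classify genes into the nine clinical/prediagnostic overlap categories
#'
#' Each arm contributes a symbol: `+` (nominally significant, effect up),
#' `-` (nominally significant, effect down) or `o` (not nominally
#' significant); the label concatenates the clinical symbol first and the
#' prediagnostic symbol second. Concordant genes (`++`/`--`) additionally
#' carry a significance tier: `"bonferroni"` when at least one arm reaches
#' its Bonferroni threshold (the other being at least nominal by
#' construction), `"nominal"` otherwise; discordant or one-armed labels get
#' tier `"none"`. `bonferroni_side` records which arm(s) reached Bonferroni
#' regardless of concordance, and `null_finding` flags genes reaching
#' Bonferroni in neither arm.
#'
#' @param meta [run_meta_analysis()] result (clinical arm).
#' @param de [run_prediag_de()] result (prediagnostic arm).
#' @param alpha nominal significance level, default 0.05.
#' @param alpha_bonf_clinical,alpha_bonf_prediag per-arm Bonferroni
#'   thresholds; default to the `alpha_bonferroni` attribute of each input.
#' @return data.frame over the genes common to both arms: `gene`,
#'   `clinical_symbol`, `prediag_symbol`, `label`, `tier`,
#'   `bonferroni_side`, `null_finding`, `category` (four-way roll-up plus
#'   null), and the underlying `mu`, `p_clinical`, `beta_case`,
#'   `p_prediag`.
#' @export
classify_genes <- function(meta, de, alpha = 0.05,
                           alpha_bonf_clinical = attr(meta,
                                                      "alpha_bonferroni"),
                           alpha_bonf_prediag = attr(de,
                                                     "alpha_bonferroni")) {
  stopifnot(!is.null(alpha_bonf_clinical), !is.null(alpha_bonf_prediag))
  genes <- intersect(meta$gene, de$gene)
  if (!length(genes)) stop("no genes shared between the two arms")
  mi <- match(genes, meta$gene)
  di <- match(genes, de$gene)
  p_c <- meta$p[mi]
  e_c <- meta$mu[mi]
  p_p <- de$p[di]
  e_p <- de$beta_case[di]

  cs <- .arm_symbol(p_c, e_c, alpha)
  ps <- .arm_symbol(p_p, e_p, alpha)
  label <- paste0(cs, ps)

  bonf_c <- !is.na(p_c) & p_c < alpha_bonf_clinical
  bonf_p <- !is.na(p_p) & p_p < alpha_bonf_prediag
  concordant <- label %in% c("++", "--")
  tier <- rep("none", length(genes))
  tier[concordant] <- ifelse(bonf_c[concordant] | bonf_p[concordant],
                             "bonferroni", "nominal")
  side <- rep("none", length(genes))
  side[bonf_c & !bonf_p] <- "clinical"
  side[!bonf_c & bonf_p] <- "prediag"
  side[bonf_c & bonf_p] <- "both"

  out <- data.frame(
    gene = genes, clinical_symbol = cs, prediag_symbol = ps,
    label = factor(label, levels = OVERLAP_LABELS),
    tier = tier, bonferroni_side = side,
    null_finding = side == "none",
    category = unname(.rollup(label)),
    mu = e_c, p_clinical = p_c, beta_case = e_p, p_prediag = p_p,
    stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  attr(out, "alpha_bonf_clinical") <- alpha_bonf_clinical
  attr(out, "alpha_bonf_prediag") <- alpha_bonf_prediag
  out
}

#' Category, tier and directional Venn counts of an overlap classification
#'
#' Summarizes [classify_genes()] output into the nine-label count table,
#' the per-label significance-tier breakdown (both arms Bonferroni, one arm
#' Bonferroni, nominal only) and the directional Venn layers (up/down x
#' Bonferroni/nominal concordant genes).
#'
#' @param calls result of [classify_genes()].
#' @return list of class `"overlap_counts"`: `label_counts` (named vector
#'   over the nine labels), `tier_table` (label x tier matrix for
#'   concordant labels), `venn` (data.frame direction, bonferroni,
#'   nominal), `universe` (gene count).
#' @export
build_category_counts <- function(calls) {
  label_counts <- table(calls$label)
  tier_detail <- with(calls, ifelse(bonferroni_side == "both",
                                    "both_bonferroni",
                             ifelse(bonferroni_side == "prediag",
                                    "prediag_bonferroni",
                             ifelse(bonferroni_side == "clinical",
                                    "clinical_bonferroni",
                                    "nominal_only"))))
  conc <- calls$label %in% c("++", "--")
  tier_table <- table(factor(as.character(calls$label[conc]),
                             levels = c("++", "--")),
                      factor(tier_detail[conc],
                             levels = c("both_bonferroni",
                                        "prediag_bonferroni",
                                        "clinical_bonferroni",
                                        "nominal_only")))
  venn <- data.frame(
    direction = c("up", "down"),
    bonferroni = c(sum(calls$label == "++" & calls$tier == "bonferroni"),
                   sum(calls$label == "--" & calls$tier == "bonferroni")),
    nominal = c(sum(calls$label == "++" & calls$tier == "nominal"),
                sum(calls$label == "--" & calls$tier == "nominal"))
  )
  structure(list(label_counts = label_counts,
                 tier_table = tier_table,
                 venn = venn,
                 universe = nrow(calls)),
            class = "overlap_counts")
}

#' Fisher exact test for overlap of two significant gene sets
#'
#' Tests a 2x2 contingency table `[a, b; c, d]` where `a` counts genes
#' significant in both arms, `b` clinical-only, `c` prediagnostic-only and
#' `d` neither. One-sided = hypergeometric upper tail `P(X >= a)`;
#' two-sided = the usual point-probability-sum Fisher test.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param sided `"one"` (enrichment, default) or `"two"`.
#' @return the p-value; degenerate margins (an all-zero row or column)
#'   return 1 with a warning.
#' @export
fisher_overlap_test <- function(a, b, c, d, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)) {
    warning("degenerate margin: overlap p-value set to 1")
    return(1)
  }
  if (sided == "one") {
    stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
  }
}

#' Signed -log10 p-value score
#'
#' @param p p-values in `(0, 1]`; exact zeros are capped at magnitude 320
#'   with a warning.
#' @param effect_sign numeric effects (only the sign is used).
#' @return `sign(effect) * (-log10(p))`.
#' @export
signed_log10p <- function(p, effect_sign) {
  stopifnot(length(p) == length(effect_sign))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  lp <- -log10(p)
  if (any(p == 0, na.rm = TRUE)) {
    warning("p = 0 capped at -log10 p = 320")
    lp[!is.na(p) & p == 0] <- 320
  }
  sign(effect_sign) * lp
}

#' Spearman concordance of signed significance scores between the two arms
#'
#' @param clinical_scores,prediag_scores paired signed `-log10 p` vectors
#'   over the common universe.
#' @return list with `rho` and `p` from the asymptotic Spearman test
#'   (mid-rank ties).
#' @export
signed_p_concordance <- function(clinical_scores, prediag_scores) {
  ok <- !is.na(clinical_scores) & !is.na(prediag_scores)
  x <- clinical_scores[ok]
  y <- prediag_scores[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant score vector: Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Overlap significance and concordance summary for both tiers
#'
#' Builds the Bonferroni-tier and nominal-tier 2x2 overlap tables from a
#' classification (per-arm significance regardless of direction, within the
#' common universe), tests each with [fisher_overlap_test()], and computes
#' the Spearman concordance of signed `-log10 p` scores.
#'
#' @param calls result of [classify_genes()].
#' @param sided sidedness of the overlap tests, default one-sided.
#' @return list with `bonferroni` and `nominal` (each: `table` = named
#'   counts a/b/c/d, `p`), and `spearman` (rho, p).
#' @export
overlap_test_summary <- function(calls, sided = c("one", "two")) {
  sided <- match.arg(sided)
  alpha <- attr(calls, "alpha")
  bonf_c <- calls$bonferroni_side %in% c("both", "clinical")
  bonf_p <- calls$bonferroni_side %in% c("both", "prediag")
  nom_c <- calls$clinical_symbol != "o"
  nom_p <- calls$prediag_symbol != "o"
  tab <- function(sc, sp) {
    c(a = sum(sc & sp), b = sum(sc & !sp), c = sum(!sc & sp),
      d = sum(!sc & !sp))
  }
  tb <- tab(bonf_c, bonf_p)
  tn <- tab(nom_c, nom_p)
  scores_c <- signed_log10p(calls$p_clinical, calls$mu)
  scores_p <- signed_log10p(calls$p_prediag, calls$beta_case)
  list(
    bonferroni = list(table = tb,
                      p = fisher_overlap_test(tb["a"], tb["b"], tb["c"],
                                              tb["d"], sided)),
    nominal = list(table = tn,
                   p = fisher_overlap_test(tn["a"], tn["b"], tn["c"],
                                           tn["d"], sided)),
    spearman = signed_p_concordance(scores_c, scores_p)
  )
}
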
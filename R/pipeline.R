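#' Run the full comparison pipeline on raw study bundles
#'
#' Orchestrates harmonization of every clinical study and the prediagnostic
#' cohort, the gene-wise random-effects meta-analysis, the mixed-model
#' differential-expression analysis, the nine-category overlap
#' classification with Fisher overlap tests and signed-p concordance, and
#' the downstream characterization (PCA of the similar and
#' prediagnostic-exclusive gene sets versus time to diagnosis, cross-set PC
#' correlations, gene-set enrichment with category composition, driver-gene
#' lookup). The pipeline is fully deterministic given its inputs.
#'
#' @param studies list of raw clinical studies (as from
#'   [simulate_clinical_studies()]`$studies` or [read_fixture_bundle()]), or
#'   a path to a fixture bundle directory (in which case `cohort` is taken
#'   from the same bundle).
#' @param cohort raw prediagnostic bundle (`expr`, `probe_map`, `pheno`).
#' @param gene_sets optional named list of gene sets (see [read_gmt()]) for
#'   enrichment.
#' @param drivers optional character vector of driver gene symbols.
#' @param alpha nominal significance level, default 0.05.
#' @param tissue_filter optional tissue subset for the meta-analysis.
#' @param int_axis inverse-normal-transform axis, `"gene"` or `"sample"`.
#' @param sided sidedness of the overlap tests.
#' @param out_dir optional directory; when given, all stage tables are
#'   written as TSV and the summary as `report.json`.
#' @return list of class `"pipeline_result"` with elements `meta`, `de`,
#'   `calls`, `counts`, `overlap`, `downstream`, `report` (the JSON-ready
#'   summary list).
#' @export
run_pipeline <- function(studies, cohort = NULL, gene_sets = NULL,
                         drivers = NULL, alpha = 0.05,
                         tissue_filter = NULL,
                         int_axis = c("gene", "sample"),
                         sided = c("one", "two"), out_dir = NULL) {
  int_axis <- match.arg(int_axis)
  sided <- match.arg(sided)
  if (is.character(studies)) {
    bundle <- read_fixture_bundle(studies)
    studies <- bundle$studies
    cohort <- bundle$cohort
  }
  if (is.null(cohort)) stop("a prediagnostic cohort is required")

  gms <- lapply(studies, function(st) {
    suppressWarnings(harmonize_study(st$expr, st$probe_map, st$pheno,
                                     st$tissue, st$study_id,
                                     int_axis = int_axis))
  })
  cohort_gm <- suppressWarnings(
    harmonize_study(cohort$expr, cohort$probe_map, cohort$pheno,
                    tissue = "blood", study_id = "prediag",
                    int_axis = int_axis))

  meta <- run_meta_analysis(gms, tissue_filter = tissue_filter,
                            alpha = alpha)
  de <- run_prediag_de(cohort_gm$expr, cohort$pheno, alpha = alpha)
  calls <- classify_genes(meta, de, alpha = alpha)
  counts <- build_category_counts(calls)
  ov <- overlap_test_summary(calls, sided = sided)

  similar <- calls$gene[calls$label %in% c("++", "--")]
  pre_excl <- calls$gene[calls$label %in% c("o+", "o-")]
  downstream <- list()
  pca_block <- function(genes) {
    if (length(intersect(genes, rownames(cohort_gm$expr))) < 2L) return(NULL)
    pcs <- suppressWarnings(pca_gene_set(cohort_gm$expr, genes))
    assoc <- if (ncol(pcs$scores) > 0L) {
      pc_time_association(pcs, cohort$pheno)
    } else {
      NULL
    }
    list(pcs = pcs, time_association = assoc)
  }
  downstream$similar <- pca_block(similar)
  downstream$prediag_exclusive <- pca_block(pre_excl)
  if (!is.null(downstream$similar) &&
      !is.null(downstream$prediag_exclusive) &&
      ncol(downstream$similar$pcs$scores) > 0L &&
      ncol(downstream$prediag_exclusive$pcs$scores) > 0L) {
    downstream$cross_correlation <-
      pc_cross_correlation(downstream$similar$pcs,
                           downstream$prediag_exclusive$pcs)
  }
  if (!is.null(gene_sets)) {
    sig <- calls$gene[calls$bonferroni_side != "none"]
    downstream$enrichment <- geneset_enrichment(sig, calls$gene, gene_sets,
                                                alpha = alpha)
    enriched <- downstream$enrichment$set_id[downstream$enrichment$bonferroni]
    downstream$composition <- lapply(enriched, function(id) {
      category_composition_test(gene_sets[[id]], calls)
    })
    names(downstream$composition) <- enriched
  }
  if (!is.null(drivers)) {
    downstream$drivers <- driver_gene_lookup(drivers, calls)
  }

  report <- list(
    alpha = alpha,
    universe_size = attr(meta, "universe_size"),
    n_studies = attr(meta, "n_studies"),
    prediag_genes = attr(de, "n_genes"),
    clinical_bonferroni = sum(meta$bonferroni),
    clinical_nominal = sum(meta$nominal),
    prediag_bonferroni = sum(de$bonferroni),
    prediag_nominal = sum(de$nominal),
    het_bonferroni_fraction = attr(meta, "het_bonferroni_fraction"),
    label_counts = as.list(counts$label_counts),
    tier_table = as.data.frame.matrix(counts$tier_table),
    venn = counts$venn,
    overlap_p_bonferroni = unname(ov$bonferroni$p),
    overlap_table_bonferroni = as.list(ov$bonferroni$table),
    overlap_p_nominal = unname(ov$nominal$p),
    overlap_table_nominal = as.list(ov$nominal$table),
    spearman_rho = ov$spearman$rho,
    spearman_p = ov$spearman$p
  )
  add_pc <- function(name, block) {
    if (is.null(block)) return(NULL)
    list(var_frac = block$pcs$var_frac[seq_len(min(10,
                                           length(block$pcs$var_frac)))],
         retained = block$pcs$retained,
         time_association = block$time_association)
  }
  report$pca_similar <- add_pc("similar", downstream$similar)
  report$pca_prediag_exclusive <- add_pc("prediag_exclusive",
                                         downstream$prediag_exclusive)
  if (!is.null(downstream$enrichment)) {
    report$enrichment <- downstream$enrichment
  }
  if (!is.null(downstream$drivers)) {
    report$driver_summary <- downstream$drivers$summary
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_meta_results(meta, file.path(out_dir, "clinical_meta.tsv"))
    write_de_results(de, file.path(out_dir, "prediag_de.tsv"))
    .write_table_tsv(calls, file.path(out_dir, "category_calls.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(meta = meta, de = de, calls = calls, counts = counts,
                 overlap = ov, downstream = downstream, report = report),
            class = "pipeline_result")
}
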
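#' Rank-based inverse normal transformation (Blom scores)
#'
#' Maps a numeric vector to normal scores `qnorm((r - 3/8)/(n + 1/4))` where
#' `r` is the mid-rank among the `n` non-missing values. Ties receive equal
#' scores; missing values stay missing. A constant vector has no defined
#' ranking beyond ties, so it maps to all zeros with a warning.
#'
#' @param x numeric vector with at least 2 non-missing values.
#' @param offset rank offset (Blom constant), default `3/8`.
#' @return numeric vector of normal scores, same length as `x`.
#' @export
rank_inverse_normal <- function(x, offset = 3 / 8) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2L) stop("rank_inverse_normal needs >= 2 non-missing values")
  out <- rep(NA_real_, length(x))
  if (length(unique(x[ok])) == 1L) {
    warning("constant input: normal scores undefined up to ties, returning 0")
    out[ok] <- 0
    return(out)
  }
  r <- rank(x[ok])
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Apply the inverse normal transformation over a matrix
#'
#' @param mat numeric matrix (probes or genes x samples).
#' @param axis `"gene"` transforms each row across samples (default);
#'   `"sample"` transforms each column across rows.
#' @return transformed matrix; attribute `n_constant` counts constant
#'   rows/columns that were set to zero.
#' @export
int_normalize <- function(mat, axis = c("gene", "sample")) {
  axis <- match.arg(axis)
  n_const <- 0L
  tf <- function(v) {
    withCallingHandlers(rank_inverse_normal(v),
                        warning = function(w) {
                          n_const <<- n_const + 1L
                          invokeRestart("muffleWarning")
                        })
  }
  out <- if (axis == "gene") {
    t(apply(mat, 1L, tf))
  } else {
    apply(mat, 2L, tf)
  }
  dimnames(out) <- dimnames(mat)
  if (n_const > 0L)
    warning(sprintf("%d constant %s vector(s) set to all-zero scores",
                    n_const, axis))
  attr(out, "n_constant") <- n_const
  out
}

#' Collapse probe-level rows to gene-level rows by the median
#'
#' For every gene the per-sample value is the median across its probes
#' (missing probes excluded; a cell with all probes missing is missing).
#' Probes absent from the map are dropped and counted.
#'
#' @param mat probes x samples numeric matrix with probe row names.
#' @param map data.frame with columns `probe_id` and `gene` (many-to-one).
#' @return genes x samples matrix, rows sorted by gene symbol; attribute
#'   `n_unmapped` counts dropped probes.
#' @export
collapse_probes_to_genes <- function(mat, map) {
  stopifnot(all(c("probe_id", "gene") %in% names(map)))
  idx <- match(rownames(mat), map$probe_id)
  mapped <- !is.na(idx)
  n_unmapped <- sum(!mapped)
  if (!any(mapped))
    stop("no probe in the matrix is present in the probe map")
  gene <- map$gene[idx[mapped]]
  dt <- data.table::as.data.table(mat[mapped, , drop = FALSE])
  dt[, .gene__ := gene]
  med <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  }
  coll <- dt[, lapply(.SD, med), by = .gene__]
  data.table::setorder(coll, .gene__)
  out <- as.matrix(coll[, -1])
  rownames(out) <- coll[[".gene__"]]
  colnames(out) <- colnames(mat)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Harmonize one probe-level study into an analysis-ready gene matrix
#'
#' Applies the rank-based inverse normal transformation (per gene across the
#' study's samples by default) and then collapses probes to genes by the
#' median, mirroring the normalize-then-collapse order of the analysis this
#' package implements.
#'
#' @param expr probes x samples matrix.
#' @param probe_map probe-to-gene map (`probe_id`, `gene`).
#' @param pheno optional per-sample phenotype data.frame (kept as-is).
#' @param tissue optional tissue label.
#' @param study_id optional study identifier.
#' @param int_axis `"gene"` (default) or `"sample"`; see [int_normalize()].
#' @return list of class `"gene_matrix"`: `expr` (genes x samples), `pheno`,
#'   `tissue`, `study_id`.
#' @export
harmonize_study <- function(expr, probe_map, pheno = NULL, tissue = NA,
                            study_id = NA, int_axis = c("gene", "sample")) {
  int_axis <- match.arg(int_axis)
  norm <- int_normalize(expr, axis = int_axis)
  gm <- collapse_probes_to_genes(norm, probe_map)
  structure(list(expr = gm, pheno = pheno, tissue = tissue,
                 study_id = study_id),
            class = "gene_matrix")
}

#' Restrict a list of gene matrices to their common gene universe
#'
#' @param studies list of `"gene_matrix"` objects (or bare matrices with
#'   gene row names).
#' @return list with `universe` (sorted character vector) and `studies`
#'   (inputs restricted to the universe, identical row order).
#' @export
intersect_gene_universe <- function(studies) {
  if (length(studies) < 2L) stop("need at least two studies to intersect")
  gene_sets <- lapply(studies, function(s) {
    rownames(if (inherits(s, "gene_matrix")) s$expr else s)
  })
  universe <- sort(Reduce(intersect, gene_sets))
  if (!length(universe)) stop("empty common gene universe")
  restricted <- lapply(studies, function(s) {
    if (inherits(s, "gene_matrix")) {
      s$expr <- s$expr[universe, , drop = FALSE]
      s
    } else {
      s[universe, , drop = FALSE]
    }
  })
  list(universe = universe, studies = restricted)
}
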
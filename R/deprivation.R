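# Sequential principal-component deprivation index.
#
# The index mirrors the construction of area-level socioeconomic deprivation
# scores from census indicators: PCA on all candidate indicators, Spearman
# screening of each indicator against the first component, then a second PCA
# restricted to the survivors whose first component -- oriented so that
# higher means more deprived -- is the index.

#' Sequential-PCA deprivation index
#'
#' Computes a census-tract deprivation index from a tracts x indicators
#' matrix in five steps: (1) standardise the columns (PCA is performed on
#' the correlation matrix, since indicators are percentages on different
#' scales); (2) PCA on all indicators; (3) Spearman-correlate each indicator
#' with the first-component scores; (4) drop indicators whose absolute
#' correlation falls below `threshold` (absolute value, inclusive boundary:
#' the sign of a principal component is arbitrary); (5) re-run the PCA on
#' the survivors.  The index is the first-component score of step 5, scaled
#' to zero mean and unit variance and sign-oriented so that it correlates
#' positively with the `orient_by` indicator (unemployment by default, which
#' rises with deprivation); if `orient_by` was screened out, the orientation
#' falls back to the mean of the standardised retained indicators.
#'
#' Missing values are imputed by the column median before standardisation.
#'
#' @param ind numeric matrix or data frame of indicators (tracts in rows).
#'   A `tract_id` character column, if present, is used for row names.
#' @param threshold Spearman screening threshold, default 0.5.
#' @param orient_by indicator name used to orient the index sign.
#' @return Object of class `deprivation_result`: a list with `index`
#'   (named numeric, zero mean), `retained` (character), `correlations`
#'   (Spearman rho of every indicator with the step-2 first component) and
#'   `threshold`.
#' @examples
#' tr <- generate_landscape(100, seed = 1)
#' M <- generate_indicators(tr, 6, 4, seed = 2)
#' res <- sequential_pca_index(M)
#' res$retained
#' @export
sequential_pca_index <- function(ind, threshold = 0.5,
                                 orient_by = "p_unemployed") {
  if (is.data.frame(ind)) {
    ids <- if ("tract_id" %in% names(ind)) as.character(ind$tract_id) else NULL
    ind <- as.matrix(ind[, setdiff(names(ind), "tract_id"), drop = FALSE])
    if (!is.null(ids)) rownames(ind) <- ids
  }
  stopifnot(is.matrix(ind), is.numeric(ind))
  if (nrow(ind) < 3L) stop("sequential_pca_index: need at least 3 tracts")
  if (ncol(ind) < 2L) stop("sequential_pca_index: need at least 2 indicators")
  if (is.null(colnames(ind)))
    colnames(ind) <- paste0("ind", seq_len(ncol(ind)))

  # median imputation
  for (j in seq_len(ncol(ind))) {
    miss <- !is.finite(ind[, j])
    if (all(miss))
      stop("sequential_pca_index: indicator '", colnames(ind)[j],
           "' has no finite values")
    if (any(miss)) ind[miss, j] <- stats::median(ind[!miss, j])
  }
  sds <- apply(ind, 2, stats::sd)
  if (any(sds == 0))
    stop("sequential_pca_index: constant indicator(s): ",
         paste(colnames(ind)[sds == 0], collapse = ", "))

  first_pc <- function(M) {
    # first principal component scores of the correlation-matrix PCA
    Z <- scale(M)
    sv <- svd(Z, nu = 1, nv = 1)
    drop(Z %*% sv$v[, 1])
  }

  pc1 <- first_pc(ind)
  rho <- apply(ind, 2, function(col)
    stats::cor(col, pc1, method = "spearman"))
  retained <- colnames(ind)[abs(rho) >= threshold]
  if (length(retained) < 2L)
    stop("sequential_pca_index: fewer than 2 indicators survive the ",
         sprintf("|rho| >= %g screen (survivors: %s)", threshold,
                 if (length(retained)) paste(retained, collapse = ", ")
                 else "none"))

  idx <- first_pc(ind[, retained, drop = FALSE])
  idx <- as.vector(scale(idx))          # zero mean, unit variance

  ref <- if (orient_by %in% retained) ind[, orient_by]
         else rowMeans(scale(ind[, retained, drop = FALSE]))
  if (stats::cor(idx, ref) < 0) idx <- -idx
  names(idx) <- rownames(ind)

  structure(list(index = idx, retained = retained, correlations = rho,
                 threshold = threshold),
            class = "deprivation_result")
}

#' @export
print.deprivation_result <- function(x, ...) {
  cat(sprintf("Deprivation index over %d tracts; %d/%d indicators retained (|rho| >= %g):\n",
              length(x$index), length(x$retained), length(x$correlations),
              x$threshold))
  cat(" ", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Empirical quintile coding
#'
#' Assigns labels 1..5 by the empirical quintile cut points of `values`
#' (quantile type 7).  Label 1 is the lowest fifth -- for a deprivation
#' index, the least deprived tracts, used as the reference category.  Ties
#' on a cut point are assigned the lower quintile.
#'
#' @param values numeric vector, length >= 5.
#' @return Integer vector of quintile labels in 1..5.
#' @examples
#' quintile_categorise(1:10)  # 1 1 2 2 3 3 4 4 5 5
#' @export
quintile_categorise <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (length(values) < 5L) stop("quintile_categorise: need at least 5 values")
  cuts <- stats::quantile(values, probs = c(0.2, 0.4, 0.6, 0.8), type = 7,
                          names = FALSE)
  if (length(unique(values)) == 1L) {
    warning("quintile_categorise: all values identical; assigning quintile 1")
    return(rep(1L, length(values)))
  }
  labels <- rep(1L, length(values))
  for (cut in cuts) labels <- labels + (values > cut)
  labels
}
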
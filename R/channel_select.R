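#' Principal component analysis over fNIRS channels
#'
#' Fits PCA to a `time x channel` HbO matrix (columns centered) and returns
#' the top-two loading vectors with a deterministic sign convention: each
#' loading column is flipped so its largest-magnitude entry is positive
#' (eigenvectors are otherwise sign-ambiguous).
#'
#' @param hbo numeric `time x channel` matrix with at least 2 rows and 2
#'   columns.
#' @return list of class `pca_result` with `loadings` (`channel x 2`,
#'   unit-norm columns), `explained_variance_ratio` (first two components),
#'   and `n_channels`.
#' @export
fit_pca <- function(hbo) {
  hbo <- as.matrix(hbo)
  if (nrow(hbo) < 2 || ncol(hbo) < 2)
    stop("PCA needs at least 2 time points and 2 channels")
  if (any(!is.finite(hbo))) stop("non-finite values in PCA input")
  if (all(apply(hbo, 2, stats::sd) == 0))
    stop("constant input: channel covariance is zero")
  p <- stats::prcomp(hbo, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$rotation))
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  if (k < 2L)  # degenerate single-component case
    loadings <- cbind(loadings, 0)
  for (j in 1:2) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  evr <- p$sdev^2 / sum(p$sdev^2)
  evr <- c(evr, 0, 0)[1:2]
  structure(list(loadings = loadings,
                 explained_variance_ratio = evr,
                 n_channels = ncol(hbo)),
            class = "pca_result")
}

#' Select the dominant channel from a PCA fit
#'
#' The default rule `"pc1_abs"` picks the channel with the largest absolute
#' loading on the first principal component (the direction of maximum
#' variance). Rule `"pc12_norm"` instead ranks channels by the Euclidean norm
#' of their projections on the first two components. Ties resolve to the
#' lowest channel index.
#'
#' @param p a `pca_result` from [fit_pca()].
#' @param rule selection rule.
#' @return integer channel index (1-based).
#' @export
select_channel <- function(p, rule = c("pc1_abs", "pc12_norm")) {
  rule <- match.arg(rule)
  if (!inherits(p, "pca_result")) stop("p must be a pca_result")
  score <- switch(rule,
                  pc1_abs = abs(p$loadings[, 1]),
                  pc12_norm = sqrt(p$loadings[, 1]^2 + p$loadings[, 2]^2))
  as.integer(which.max(score))  # which.max breaks ties toward the lowest index
}
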
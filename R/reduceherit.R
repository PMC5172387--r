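#' Full PCA of a vertex-wise shape measure
#'
#' Principal components of the centered subjects x vertices matrix, on the
#' covariance (not correlation) scale since measures share units within a
#' structure. All `min(n_subjects - 1, n_vertices)` components are
#' returned, sorted in descending order of the eigenvalues (explained
#' shape variance). Component signs are fixed by forcing the
#' largest-magnitude loading of each component positive, so runs are
#' comparable.
#'
#' @param y subjects x vertices matrix ([shape_measures()] or plain).
#' @return A `shape_pca` list: `loadings` (vertices x components,
#'   orthonormal), `scores` (subjects x components), `eigenvalues`
#'   (descending), `explained` (variance fractions).
#' @export
pca_components <- function(y) {
  y <- as.matrix(y)
  if (nrow(y) < 2) stop("PCA needs at least 2 subjects")
  if (all(apply(y, 2, stats::sd) == 0)) stop("constant matrix has no components")
  pc <- stats::prcomp(y, center = TRUE, scale. = FALSE)
  ncomp <- min(nrow(y) - 1L, ncol(y))
  load <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  ev <- pc$sdev[seq_len(ncomp)]^2
  # deterministic sign: largest |loading| positive
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(apply(y, 2, stats::var))
  structure(list(loadings = load, scores = scores, eigenvalues = ev,
                 explained = ev / total_var, total_var = total_var),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("<shape_pca> %d components; PC1 explains %.1f%% of variance\n",
              length(x$eigenvalues), 100 * x$explained[1]))
  invisible(x)
}

#' Heritability of principal-component scores
#'
#' Applies the single-GRM REML estimator to every component score column
#' (residualized on the covariate model, standardized), mirroring the
#' vertex-wise map but over components. Reports the maximal component
#' heritability.
#'
#' @param pca a [pca_components()] result; score rows must align with the
#'   GRM subjects.
#' @param k a [compute_grm()] result.
#' @param model a [covariate_model()] or `NULL`.
#' @param q FDR level.
#' @param eig optional cached [grm_eigen()].
#' @return A `heritability_map` tibble over components (`vertex` column
#'   holds component labels `PC1`, `PC2`, ...).
#' @export
component_h2 <- function(pca, k, model = NULL, q = 0.05, eig = NULL) {
  stopifnot(inherits(pca, "shape_pca"))
  scores <- pca$scores
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  hm <- h2_map(scores, k, model = model, q = q, eig = eig)
  attr(hm, "measure") <- "pca_component"
  hm
}

#' Rank agreement between eigenvalue order and heritability order
#'
#' Spearman rank correlation (tie-corrected) between the component order by
#' explained variance and the order by estimated heritability. Near-zero
#' values mean the high-variance shape components are not the heritable
#' ones.
#'
#' @param pca a [pca_components()] result.
#' @param h2 a [component_h2()] map over the same components.
#' @return Spearman rho (scalar).
#' @export
eigen_vs_h2_rank <- function(pca, h2) {
  stopifnot(inherits(pca, "shape_pca"))
  if (length(pca$eigenvalues) != nrow(h2)) {
    stop("component count mismatch between PCA and heritability map")
  }
  if (length(pca$eigenvalues) < 3) stop("need at least 3 components")
  stats::cor(rank(-pca$eigenvalues), rank(-h2$h2), method = "spearman")
}
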
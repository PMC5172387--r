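#' Covariate model design matrix
#'
#' The three adjustment models used for heritability mapping: a basic model
#' with age and sex, and the basic model additionally adjusted for either
#' intracranial volume (`icv`) or the gross volume of the structure under
#' study (`volume`). Always includes an intercept.
#'
#' @param covariates tibble/data frame with columns `age`, `sex`, and
#'   (depending on model) `icv` or `volume`.
#' @param model `"basic"`, `"icv"` or `"volume"`.
#' @return A `covariate_model`: list with the design `matrix` (full column
#'   rank enforced) and the model name.
#' @export
covariate_model <- function(covariates, model = c("basic", "icv", "volume")) {
  model <- match.arg(model)
  covariates <- as.data.frame(covariates)
  cols <- switch(model,
                 basic = c("age", "sex"),
                 icv = c("age", "sex", "icv"),
                 volume = c("age", "sex", "volume"))
  missing_cols <- setdiff(cols, names(covariates))
  if (length(missing_cols)) {
    stop("covariates missing columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- cbind(`(Intercept)` = 1, as.matrix(covariates[, cols, drop = FALSE]))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(matrix = x, model = model, qr = qrx),
            class = "covariate_model")
}

#' Residualize phenotype columns on a covariate model
#'
#' Replaces each phenotype column by its least-squares residual on the
#' design, removing fixed covariate effects before variance-component
#' estimation. Residual columns are orthogonal to every covariate.
#'
#' @param y subjects x phenotypes matrix (or `shape_measures`).
#' @param model a [covariate_model()], or a bare design matrix.
#' @return Matrix of residuals, same shape and dimnames as `y`.
#' @export
residualize <- function(y, model) {
  y <- as.matrix(y)
  qrx <- if (inherits(model, "covariate_model")) model$qr else qr(as.matrix(model))
  if (nrow(y) != nrow(qrx$qr)) stop("subject rows must match design rows")
  r <- qr.resid(qrx, y)
  dimnames(r) <- dimnames(y)
  r
}

scale_columns <- function(y) {
  s <- apply(y, 2, stats::sd)
  if (any(s == 0)) stop("zero-variance phenotype column")
  sweep(y, 2, s, "/")
}

#' Cached eigendecomposition of a GRM
#'
#' `K = U diag(lambda) U'`, computed once per cohort and reused by every
#' per-vertex REML fit. Refuses clearly non-PSD matrices.
#'
#' @param k a [compute_grm()] result (or symmetric matrix).
#' @return List with `u` (eigenvectors), `lambda` (eigenvalues, descending),
#'   `subject_ids`.
#' @export
grm_eigen <- function(k) {
  km <- unclass(as.matrix(k))
  e <- eigen(km, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values))) {
    stop(paste0("GRM is not positive semi-definite; prune related subjects ",
                "or regularize before REML"))
  }
  list(u = e$vectors, lambda = pmax(e$values, 0), subject_ids = rownames(km))
}

# profile restricted log-likelihood of h2 for rotated data:
# y~ ~ N(0, sigma_p^2 * diag(h2*lambda + 1 - h2)); sigma_p^2 profiled out.
reml_profile_ll <- function(h2, ytilde2, lambda) {
  d <- h2 * lambda + (1 - h2)
  if (min(d) <= 0) return(-Inf)   # h2 = 1 with a rank-deficient GRM
  n <- length(lambda)
  sp2 <- sum(ytilde2 / d) / n
  -0.5 * (n * log(sp2) + sum(log(d)) + n)
}

#' Single-GRM REML heritability for one phenotype
#'
#' Fits `y ~ N(0, sigma_g^2 K + sigma_e^2 I)` by restricted maximum
#' likelihood after fixed effects have been projected out
#' ([residualize()]) and the column standardized, so the heritability
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` is profiled directly on
#' `[0, 1]` using the cached eigendecomposition. The p-value tests
#' `h2 = 0` by likelihood ratio against the boundary mixture
#' `0.5 chi2_0 + 0.5 chi2_1`; the standard error comes from the numerical
#' second derivative of the profile likelihood at the optimum.
#'
#' @param y_col numeric phenotype vector (residualized, standardized).
#' @param k a [compute_grm()] result or a cached [grm_eigen()].
#' @param tol optimizer tolerance on h2.
#' @return A `reml_fit` list: `h2`, `se`, `p`, `lrt`, `loglik`, `boundary`.
#' @export
reml_h2 <- function(y_col, k, tol = 1e-6) {
  eig <- if (is.list(k) && !is.null(k$lambda)) k else grm_eigen(k)
  y_col <- as.numeric(y_col)
  if (length(y_col) != length(eig$lambda)) {
    stop("phenotype length must match GRM dimension")
  }
  if (stats::sd(y_col) == 0) stop("zero-variance phenotype")
  lambda <- eig$lambda
  if (max(lambda) - min(lambda) < 1e-10) {
    warning("GRM eigenvalues are constant (identity relatedness); h2 unidentified")
    return(new_reml_fit(h2 = 0, se = NA_real_, p = 1, lrt = 0,
                        loglik = reml_profile_ll(0, drop(crossprod(eig$u, y_col))^2, lambda),
                        boundary = TRUE))
  }
  ytilde2 <- drop(crossprod(eig$u, y_col))^2
  obj <- function(h2) reml_profile_ll(h2, ytilde2, lambda)
  opt <- stats::optimize(obj, interval = c(0, 1), maximum = TRUE, tol = tol)
  h2 <- opt$maximum
  ll1 <- opt$objective
  ll0 <- obj(0)
  # the optimizer never probes the exact boundary; accept 0/1 if better
  if (obj(0) >= ll1) { h2 <- 0; ll1 <- obj(0) }
  if (obj(1) > ll1) { h2 <- 1; ll1 <- obj(1) }
  lrt <- max(0, 2 * (ll1 - ll0))
  p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  se <- reml_numeric_se(obj, h2)
  new_reml_fit(h2 = h2, se = se, p = p, lrt = lrt, loglik = ll1,
               boundary = h2 %in% c(0, 1))
}

new_reml_fit <- function(h2, se, p, lrt, loglik, boundary) {
  structure(list(h2 = h2, se = se, p = p, lrt = lrt, loglik = loglik,
                 boundary = boundary),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> h2 = %.3f (se %.3f), LRT = %.2f, p = %.3g\n",
              x$h2, x$se, x$lrt, x$p))
  invisible(x)
}

# curvature-based s.e.: central difference away from the boundary,
# one-sided second difference at it
reml_numeric_se <- function(obj, h2, h = 1e-3) {
  lo <- max(0, h2 - h); hi <- min(1, h2 + h)
  if (hi - lo < h) return(NA_real_)
  mid <- (lo + hi) / 2
  d2 <- (obj(lo) - 2 * obj(mid) + obj(hi)) / ((hi - lo) / 2)^2
  if (!is.finite(d2) || d2 >= 0) return(NA_real_)
  sqrt(-1 / d2)
}

#' Haseman-Elston regression heritability
#'
#' Moment-based fast path: regresses the phenotype cross-products
#' `y_i y_j` on the relatedness `K_ij` over all `i < j` pairs. For a
#' residualized, variance-standardized phenotype the slope estimates `h2`.
#'
#' @param y_col numeric phenotype vector (residualized, standardized).
#' @param k a [compute_grm()] result.
#' @return List with `h2` (slope clamped to `[0, 1]`), `h2_raw`, `se`.
#' @export
he_regression <- function(y_col, k) {
  y_col <- as.numeric(y_col)
  km <- unclass(as.matrix(k))
  if (length(y_col) != nrow(km)) stop("phenotype length must match GRM")
  if (stats::sd(y_col) == 0) stop("zero-variance phenotype")
  ut <- upper.tri(km)
  kij <- km[ut]
  qij <- tcrossprod(y_col)[ut]
  kc <- kij - mean(kij)
  slope <- sum(kc * qij) / sum(kc^2)
  res <- qij - mean(qij) - slope * kc
  se <- sqrt(sum(res^2) / (length(kij) - 2) / sum(kc^2))
  list(h2 = min(1, max(0, slope)), h2_raw = slope, se = se)
}

#' Permutation p-value for the REML likelihood-ratio test
#'
#' Nonparametric check on the mixture chi-squared reference: permutes the
#' phenotype against the GRM and recomputes the REML LRT statistic.
#' Add-one rule, so p never returns exactly 0.
#'
#' @param y_col phenotype vector.
#' @param k GRM or cached [grm_eigen()].
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `p`, `observed` LRT, `n_perm`.
#' @export
permutation_p <- function(y_col, k, n_perm = 500, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  eig <- if (is.list(k) && !is.null(k$lambda)) k else grm_eigen(k)
  obs <- reml_h2(y_col, eig)$lrt
  withr_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      yp <- sample(y_col)
      if (reml_h2(yp, eig)$lrt >= obs) exceed <- exceed + 1L
    }
    list(p = (1 + exceed) / (1 + n_perm), observed = obs, n_perm = n_perm)
  })
}

#' Vertex-wise heritability map (population, GRM-based)
#'
#' Residualizes every vertex column on the covariate model, standardizes,
#' and fits single-GRM REML per vertex reusing one cached GRM
#' eigendecomposition. Estimates are FDR-flagged at level `q` by
#' Benjamini-Hochberg over all vertices in the map.
#'
#' @param y subjects x vertices matrix ([shape_measures()] or plain).
#' @param k a [compute_grm()] result (subjects must match rows of `y`).
#' @param model a [covariate_model()] or `NULL` (centering only).
#' @param q FDR level.
#' @param eig optional precomputed [grm_eigen()].
#' @return A `heritability_map` tibble: `vertex`, `h2`, `se`, `p`,
#'   `fdr_sig`, plus attributes `model`, `measure`, `max_h2`, `max_vertex`.
#' @export
h2_map <- function(y, k, model = NULL, q = 0.05, eig = NULL) {
  y <- as.matrix(y)
  km <- as.matrix(k)
  if (nrow(y) != nrow(km)) {
    ry <- rownames(y); rk <- rownames(km)
    stop("subject mismatch between phenotypes and GRM; disjoint IDs: ",
         paste(utils::head(c(setdiff(ry, rk), setdiff(rk, ry)), 5),
               collapse = ", "))
  }
  if (!is.null(rownames(y)) && !is.null(rownames(km)) &&
      !identical(rownames(y), rownames(km))) {
    stop("subject order differs between phenotypes and GRM")
  }
  r <- if (is.null(model)) scale(y, scale = FALSE) else residualize(y, model)
  r <- scale_columns(r)
  if (is.null(eig)) eig <- grm_eigen(k)
  fits <- lapply(seq_len(ncol(r)), function(j) reml_h2(r[, j], eig))
  out <- tibble::tibble(
    vertex = if (!is.null(colnames(y))) colnames(y) else paste0("v", seq_len(ncol(y))),
    h2 = vapply(fits, `[[`, numeric(1), "h2"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    p = vapply(fits, `[[`, numeric(1), "p")
  )
  out$fdr_sig <- bh_fdr(out$p, q = q)$significant
  heritability_map(out,
                   model = if (is.null(model)) "center" else model$model,
                   measure = attr(y, "measure") %||% "phenotype")
}

heritability_map <- function(tbl, model, measure) {
  imax <- which.max(tbl$h2)
  structure(tbl,
            class = c("heritability_map", class(tibble::tibble()))) -> hm
  attr(hm, "model") <- model
  attr(hm, "measure") <- measure
  attr(hm, "max_h2") <- tbl$h2[imax]
  attr(hm, "max_vertex") <- tbl$vertex[imax]
  hm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.heritability_map <- function(x, ...) {
  cat(sprintf(
    "<heritability_map> %d vertices, model %s, measure %s; max h2 = %.3f at %s\n",
    nrow(x), attr(x, "model"), attr(x, "measure"),
    attr(x, "max_h2"), attr(x, "max_vertex")))
  NextMethod()
}
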
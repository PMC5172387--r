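#' Falconer point estimates from twin-pair correlations
#'
#' Closed-form initializer and sanity check for the ACE likelihood:
#' `h2 = 2 (r_MZ - r_DZ)` and `c2 = 2 r_DZ - r_MZ`, with pair correlations
#' computed on double-entered pairs after residualizing covariates.
#' Opposite-sex pairs are pooled with DZ. Estimates may fall outside
#' `[0, 1]` and are reported unclamped.
#'
#' @param cohort a [twin_cohort()].
#' @param column phenotype column index.
#' @param residualize_covariates adjust for age and sex before correlating.
#' @return List with `h2`, `c2`, `r_mz`, `r_dz`.
#' @export
falconer <- function(cohort, column = 1L, residualize_covariates = TRUE) {
  stopifnot(inherits(cohort, "twin_cohort"))
  z <- cohort$pairs$zygosity
  if (sum(z == "MZ") < 2 || sum(z != "MZ") < 2) {
    stop("need at least 2 MZ and 2 DZ/OS pairs")
  }
  yy <- twin_residualized(cohort, column, residualize_covariates)
  r_mz <- double_entry_cor(yy$y1[z == "MZ"], yy$y2[z == "MZ"])
  r_dz <- double_entry_cor(yy$y1[z != "MZ"], yy$y2[z != "MZ"])
  list(h2 = 2 * (r_mz - r_dz), c2 = 2 * r_dz - r_mz,
       r_mz = r_mz, r_dz = r_dz)
}

double_entry_cor <- function(a, b) {
  stats::cor(c(a, b), c(b, a))
}

# residualize each member's phenotype on age + own sex, then standardize
# jointly so the pair covariance scale is preserved
twin_residualized <- function(cohort, column, residualize_covariates) {
  y1 <- cohort$y1[, column]
  y2 <- cohort$y2[, column]
  if (residualize_covariates) {
    p <- cohort$pairs
    long <- data.frame(y = c(y1, y2),
                       age = c(p$age, p$age),
                       sex = c(p$sex1, p$sex2))
    r <- stats::resid(stats::lm(y ~ age + sex, data = long))
    y1 <- r[seq_along(y1)]
    y2 <- r[-seq_along(y1)]
  }
  s <- stats::sd(c(y1, y2))
  if (s == 0) stop("zero-variance twin phenotype")
  mu <- mean(c(y1, y2))
  list(y1 = (y1 - mu) / s, y2 = (y2 - mu) / s)
}

# ACE log-likelihood on the standardized scale: each pair bivariate normal
# with unit variances and correlation a2+c2 (MZ) or a2/2+c2 (DZ/OS).
ace_loglik <- function(a2, c2, y1, y2, is_mz, free_var = FALSE, s2 = 1) {
  rho <- ifelse(is_mz, a2 + c2, a2 / 2 + c2)
  if (any(rho >= 1 - 1e-10) || any(rho <= -1 + 1e-10)) return(-Inf)
  q <- (y1^2 - 2 * rho * y1 * y2 + y2^2) / (s2 * (1 - rho^2))
  sum(-log(2 * pi) - log(s2) - 0.5 * log(1 - rho^2) - 0.5 * q)
}

#' Twin ACE heritability by maximum likelihood
#'
#' Decomposes standardized phenotypic variance into additive genetic (A),
#' common environment (C) and unique environment (E) fractions by
#' maximizing the sum of bivariate-normal pair log-densities with pair
#' correlation `a2 + c2` for MZ and `a2/2 + c2` for DZ and opposite-sex
#' pairs. The null hypothesis of no genetic variance (`a2 = 0`, the CE
#' model) is tested by likelihood ratio with the boundary mixture
#' `0.5 chi2_0 + 0.5 chi2_1`. Optimization starts from the Falconer
#' estimates clamped into the simplex plus seeded restarts.
#'
#' @param cohort a [twin_cohort()].
#' @param column phenotype column index.
#' @param residualize_covariates adjust for age and sex first.
#' @param n_restarts extra random restarts.
#' @param seed seed for the restarts.
#' @return An `ace_fit` list: `a2`, `c2`, `e2`, `loglik`, `loglik_null`,
#'   `lrt`, `p`, `n_pairs`.
#' @export
ace_ml <- function(cohort, column = 1L, residualize_covariates = TRUE,
                   n_restarts = 3L, seed = 1L) {
  stopifnot(inherits(cohort, "twin_cohort"))
  yy <- twin_residualized(cohort, column, residualize_covariates)
  is_mz <- cohort$pairs$zygosity == "MZ"
  nll <- function(par) {
    # par = (s, t): a2 = s*t, c2 = s*(1-t), a2 + c2 = s
    s <- par[1]; t <- par[2]
    -ace_loglik(s * t, s * (1 - t), yy$y1, yy$y2, is_mz)
  }
  init <- falconer_init(cohort, column, residualize_covariates)
  starts <- list(init)
  withr_seed(seed, {
    for (r in seq_len(n_restarts)) {
      starts[[r + 1L]] <- c(stats::runif(1, 0.05, 0.9), stats::runif(1))
    }
  })
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(1 - 1e-8, 1)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("ACE optimizer failed to converge after restarts")
  s <- best$par[1]; t <- best$par[2]
  a2 <- s * t; c2 <- s * (1 - t)
  ll1 <- -best$value
  # null (CE) model: a2 = 0, optimize over c2 only
  nll0 <- function(c2) -ace_loglik(0, c2, yy$y1, yy$y2, is_mz)
  opt0 <- stats::optimize(nll0, interval = c(0, 1 - 1e-8))
  ll0 <- -opt0$objective
  lrt <- max(0, 2 * (ll1 - ll0))
  p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(a2 = a2, c2 = c2, e2 = 1 - a2 - c2,
                 loglik = ll1, loglik_null = ll0, lrt = lrt, p = p,
                 n_pairs = length(yy$y1)),
            class = "ace_fit")
}

falconer_init <- function(cohort, column, residualize_covariates) {
  f <- tryCatch(falconer(cohort, column, residualize_covariates),
                error = function(e) list(h2 = 0.3, c2 = 0.1))
  a2 <- min(0.95, max(0, f$h2))
  c2 <- min(0.95, max(0, f$c2))
  s <- min(1 - 1e-6, a2 + c2)
  t <- if (s > 0) a2 / (a2 + c2 + 1e-12) else 0.5
  c(max(s, 1e-4), min(1, max(0, t)))
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf(
    "<ace_fit> a2 = %.3f, c2 = %.3f, e2 = %.3f; LRT = %.2f, p = %.3g (%d pairs)\n",
    x$a2, x$c2, x$e2, x$lrt, x$p, x$n_pairs))
  invisible(x)
}

#' Vertex-wise twin heritability map
#'
#' Fits the ACE model at every vertex and assembles a map with the same
#' fields as the population map, including per-structure maxima and
#' Benjamini-Hochberg FDR flags.
#'
#' @param cohort a [twin_cohort()] whose `y1`/`y2` have one column per
#'   vertex.
#' @param q FDR level.
#' @param ... passed to [ace_ml()].
#' @return A `heritability_map` tibble with `h2` (= `a2`), `c2`, `p`,
#'   `fdr_sig`.
#' @export
twin_h2_map <- function(cohort, q = 0.05, ...) {
  stopifnot(inherits(cohort, "twin_cohort"))
  nv <- ncol(cohort$y1)
  fits <- lapply(seq_len(nv), function(j) ace_ml(cohort, column = j, ...))
  out <- tibble::tibble(
    vertex = colnames(cohort$y1) %||% paste0("v", seq_len(nv)),
    h2 = vapply(fits, `[[`, numeric(1), "a2"),
    c2 = vapply(fits, `[[`, numeric(1), "c2"),
    se = NA_real_,
    p = vapply(fits, `[[`, numeric(1), "p")
  )
  out$fdr_sig <- bh_fdr(out$p, q = q)$significant
  heritability_map(out, model = "twin_ace", measure = "twin")
}
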
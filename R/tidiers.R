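#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML heritability fit
#'
#' @param x a [reml_h2()] fit.
#' @param ... unused.
#' @return One-row tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(term = "h2", estimate = x$h2, std.error = x$se,
                 statistic = x$lrt, p.value = x$p)
}

#' @rdname tidy.reml_fit
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, LRT = x$lrt, p.value = x$p,
                 boundary = x$boundary)
}

#' Tidy a twin ACE fit
#'
#' @param x an [ace_ml()] fit.
#' @param ... unused.
#' @return Tibble with one row per variance fraction (`a2`, `c2`, `e2`).
#' @method tidy ace_fit
#' @export
tidy.ace_fit <- function(x, ...) {
  tibble::tibble(term = c("a2", "c2", "e2"),
                 estimate = c(x$a2, x$c2, x$e2))
}

#' @rdname tidy.ace_fit
#' @method glance ace_fit
#' @export
glance.ace_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, logLik.null = x$loglik_null,
                 LRT = x$lrt, p.value = x$p, n.pairs = x$n_pairs)
}

#' Tidy a shape PCA
#'
#' @param x a [pca_components()] result.
#' @param ... unused.
#' @return Tibble with `component`, `eigenvalue`, `explained`,
#'   `cumulative`.
#' @method tidy shape_pca
#' @export
tidy.shape_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 explained = x$explained,
                 cumulative = cumsum(x$explained))
}

#' @rdname tidy.shape_pca
#' @method glance shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  tibble::tibble(n.components = length(x$eigenvalues),
                 total.variance = x$total_var,
                 pc1.explained = x$explained[1])
}
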
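#' Vertex-wise test-retest ICC map
#'
#' Two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation — ICC(2,1) — per vertex from the standard
#' mean-squares decomposition over subjects x 2 sessions. Negative
#' estimates are retained. A one-way ICC(1,1) is available via `type`.
#'
#' @param scan1,scan2 subjects x vertices matrices for the two sessions
#'   (same subjects, same vertex order).
#' @param type `"icc2_1"` (two-way random, absolute agreement, default) or
#'   `"icc1_1"` (one-way random).
#' @return An `icc_map` tibble: `vertex`, `icc`, `n`; vertices with zero
#'   between-subject variance get `NA` with a logged count.
#' @export
icc_map <- function(scan1, scan2, type = c("icc2_1", "icc1_1")) {
  type <- match.arg(type)
  s1 <- as.matrix(scan1); s2 <- as.matrix(scan2)
  if (!identical(dim(s1), dim(s2))) stop("scan matrices must match in shape")
  n <- nrow(s1)
  if (n < 3) stop("ICC needs at least 3 rescanned subjects")
  k <- 2
  subj_mean <- (s1 + s2) / 2
  grand <- colMeans(subj_mean)
  sess_mean1 <- colMeans(s1); sess_mean2 <- colMeans(s2)
  # mean squares, per vertex (columns)
  msr <- k * colSums(sweep(subj_mean, 2, grand)^2) / (n - 1)           # rows (subjects)
  msc <- n * ((sess_mean1 - grand)^2 + (sess_mean2 - grand)^2) / (k - 1)  # columns (sessions)
  sstot <- colSums(sweep(s1, 2, grand)^2 + sweep(s2, 2, grand)^2)
  ssr <- (n - 1) * msr
  ssc <- (k - 1) * msc
  mse <- (sstot - ssr - ssc) / ((n - 1) * (k - 1))
  icc <- if (type == "icc2_1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    msw <- (sstot - ssr) / (n * (k - 1))
    (msr - msw) / (msr + (k - 1) * msw)
  }
  degenerate <- msr <= .Machine$double.eps
  if (any(degenerate)) {
    message(sprintf("icc_map: %d vertex(es) with zero between-subject variance set to NA",
                    sum(degenerate)))
    icc[degenerate] <- NA_real_
  }
  structure(tibble::tibble(
    vertex = colnames(s1) %||% paste0("v", seq_len(ncol(s1))),
    icc = icc, n = n),
    class = c("icc_map", class(tibble::tibble())),
    type = type)
}

#' Heritability-reproducibility concordance
#'
#' Pearson and Spearman correlations between a heritability map and an ICC
#' map over matched vertices, plus the paired per-vertex table for
#' scatter plots. Vertices with undefined ICC are excluded with a logged
#' count.
#'
#' @param h2map a `heritability_map`.
#' @param iccmap an `icc_map`.
#' @return List with `pearson`, `spearman`, `n_vertices`, and `pairs`
#'   (tibble `vertex`, `h2`, `icc`).
#' @export
concordance <- function(h2map, iccmap) {
  if (nrow(h2map) != nrow(iccmap)) {
    stop("h2 and ICC maps must cover the same vertices")
  }
  ok <- !is.na(iccmap$icc) & !is.na(h2map$h2)
  if (sum(!ok)) {
    message(sprintf("concordance: excluding %d vertex(es) with undefined values",
                    sum(!ok)))
  }
  h2 <- h2map$h2[ok]; icc <- iccmap$icc[ok]
  list(pearson = stats::cor(h2, icc),
       spearman = stats::cor(h2, icc, method = "spearman"),
       n_vertices = sum(ok),
       pairs = tibble::tibble(vertex = h2map$vertex[ok], h2 = h2, icc = icc))
}

#' Correlation between two heritability maps
#'
#' Pearson correlation with a two-sided p-value, used for model-vs-model
#' (e.g. basic vs ICV-adjusted) and population-vs-twin comparisons.
#'
#' @param map_a,map_b `heritability_map`s over matched vertices.
#' @return List with `r`, `p`, `n_vertices`.
#' @export
map_correlation <- function(map_a, map_b) {
  if (nrow(map_a) != nrow(map_b)) stop("maps must cover the same vertices")
  a <- map_a$h2; b <- map_b$h2
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant map")
  }
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n_vertices = length(a))
}
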
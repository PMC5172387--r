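#' Genotype dosages with per-variant QC metadata
#'
#' @param dosage numeric matrix, subjects x variants, entries in `[0, 2]`
#'   (imputed allele dosages; `NA` allowed for missing hard calls).
#' @param variants tibble of per-variant metadata with columns `id`, `maf`,
#'   `rsq` (imputation quality), `hwe_p`, `call_rate`.
#' @param subject_ids character vector of subject identifiers.
#' @return A `genotype_data` object.
#' @export
genotype_data <- function(dosage, variants, subject_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(dosage)))
  variants <- tibble::as_tibble(variants)
  need <- c("id", "maf", "rsq", "hwe_p", "call_rate")
  if (!all(need %in% names(variants))) {
    stop("variant metadata must contain: ", paste(need, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosage)) {
    stop("variant metadata rows must match dosage columns")
  }
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  rownames(dosage) <- subject_ids
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants,
                 subject_ids = subject_ids),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("<genotype_data> %d subjects x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Filter variants on QC metadata
#'
#' Retains variants with MAF, imputation quality (Rsq), Hardy-Weinberg
#' equilibrium p-value and call rate at or above the given thresholds. The
#' defaults drop poorly imputed (Rsq < 0.5) and rare (MAF < 0.01) variants,
#' with array-QC style HWE (p < 1e-6) and call-rate cutoffs.
#'
#' @param g a [genotype_data()].
#' @param maf_min,rsq_min,hwe_p_min,callrate_min thresholds in `[0, 1]`.
#' @param verbose log removal counts.
#' @return Filtered `genotype_data`.
#' @export
filter_variants <- function(g, maf_min = 0.01, rsq_min = 0.5,
                            hwe_p_min = 1e-6, callrate_min = 0.95,
                            verbose = FALSE) {
  stopifnot(inherits(g, "genotype_data"))
  th <- c(maf_min, rsq_min, hwe_p_min, callrate_min)
  if (any(th < 0 | th > 1)) stop("thresholds must lie in [0, 1]")
  v <- g$variants
  keep <- v$maf >= maf_min & v$rsq >= rsq_min &
    v$hwe_p >= hwe_p_min & v$call_rate >= callrate_min
  if (!any(keep)) stop("all variants removed by QC filters")
  if (verbose) {
    message(sprintf("filter_variants: kept %d / %d variants", sum(keep),
                    length(keep)))
  }
  genotype_data(g$dosage[, keep, drop = FALSE], v[keep, , drop = FALSE],
                g$subject_ids)
}

#' Genomic relationship matrix
#'
#' `K = W W' / M` over the `M` retained variants, where
#' `w_ij = (x_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))` and the allele frequency
#' `p_j` is estimated from the analysis sample. Missing dosages are
#' mean-imputed per variant before standardization.
#'
#' @param g a QC-filtered [genotype_data()].
#' @return A `grm` object: symmetric `n x n` matrix `K`, with attributes
#'   `n_variants`, `subject_ids` and `pruned_ids` (empty until
#'   [prune_related()]).
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_data"))
  x <- g$dosage
  mu <- colMeans(x, na.rm = TRUE)
  if (anyNA(x)) {
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- mu[na_idx[, 2]]
  }
  p <- mu / 2
  if (any(p <= 0 | p >= 1)) {
    stop(sprintf("monomorphic variant at GRM stage: %s",
                 g$variants$id[which(p <= 0 | p >= 1)[1]]))
  }
  w <- sweep(sweep(x, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  k <- tcrossprod(w) / ncol(w)
  dimnames(k) <- list(g$subject_ids, g$subject_ids)
  new_grm(k, n_variants = ncol(w), pruned_ids = character(0))
}

new_grm <- function(k, n_variants, pruned_ids) {
  structure(k, class = c("grm", "matrix"),
            n_variants = n_variants, pruned_ids = pruned_ids)
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d subjects, %d variants, %d pruned\n",
              nrow(x), attr(x, "n_variants"), length(attr(x, "pruned_ids"))))
  invisible(x)
}

#' Prune related subjects from a GRM
#'
#' Greedy removal: while any off-diagonal relatedness exceeds `threshold`,
#' drop the subject appearing in the most offending pairs (ties broken by
#' lowest subject index). The default threshold 0.025 removes one member of
#' each pair of cryptically related individuals so downstream models can
#' treat subjects as unrelated.
#'
#' @param k a [compute_grm()] result.
#' @param threshold maximum allowed off-diagonal genotype similarity.
#' @return Pruned `grm`; removed subject IDs in attribute `pruned_ids`.
#' @export
prune_related <- function(k, threshold = 0.025) {
  stopifnot(inherits(k, "grm"), threshold > 0)
  ids <- rownames(k)
  keep <- rep(TRUE, nrow(k))
  km <- unclass(k)
  diag(km) <- 0
  repeat {
    off <- km[keep, keep, drop = FALSE] > threshold
    if (!any(off)) break
    deg <- rowSums(off)
    worst_local <- which.max(deg)  # which.max takes the first (lowest index) tie
    worst <- which(keep)[worst_local]
    keep[worst] <- FALSE
    if (sum(keep) < 2) stop("relatedness pruning left fewer than 2 subjects")
  }
  out <- unclass(k)[keep, keep, drop = FALSE]
  new_grm(out, n_variants = attr(k, "n_variants"),
          pruned_ids = c(attr(k, "pruned_ids"), ids[!keep]))
}

#' Write / read a GRM in the GCTA binary dialect
#'
#' `prefix.grm.bin` holds the lower triangle (including diagonal) as
#' little-endian float32 in row order; `prefix.grm.N.bin` the per-pair
#' variant counts; `prefix.grm.id` two tab-separated ID columns.
#'
#' @param k a [compute_grm()] result.
#' @param prefix path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm_gcta <- function(k, prefix) {
  n <- nrow(k)
  lt <- unclass(k)[upper.tri(unclass(k), diag = TRUE)]
  # GCTA stores rows of the lower triangle: pairs (i, j <= i); column-major
  # upper triangle of a symmetric matrix enumerates the same values in the
  # same (i, j<=i) order.
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(attr(k, "n_variants")), length(lt)), con,
           size = 4, endian = "little")
  close(con)
  ids <- rownames(k)
  utils::write.table(data.frame(fid = ids, iid = ids),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_gcta
#' @export
read_grm_gcta <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), sep = "\t",
                           stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  m <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  lt <- readBin(con, "numeric", n = m, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "rb")
  nv <- readBin(con, "numeric", n = 1, size = 4, endian = "little")
  close(con)
  k <- matrix(0, n, n)
  k[upper.tri(k, diag = TRUE)] <- lt
  k <- k + t(k) - diag(diag(k))
  dimnames(k) <- list(ids, ids)
  new_grm(k, n_variants = as.integer(round(nv)), pruned_ids = character(0))
}

#' Write / read dosages as TSV
#'
#' Subjects x variants table with a header row of variant IDs and a leading
#' `subject_id` column; variant metadata goes to a side-car
#' `<path>.variants.tsv`.
#'
#' @param g a [genotype_data()].
#' @param path output TSV path.
#' @export
write_dosage_tsv <- function(g, path) {
  df <- data.frame(subject_id = g$subject_ids, g$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$variants, paste0(path, ".variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  variants <- tibble::as_tibble(
    utils::read.table(paste0(path, ".variants.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE))
  dosage <- as.matrix(df[, -1, drop = FALSE])
  genotype_data(dosage, variants, subject_ids = df[[1]])
}
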
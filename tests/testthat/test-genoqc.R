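toy_genotypes <- function(n = 6, m = 10, seed = 42, fail = 0) {
  set.seed(seed)
  x <- matrix(rbinom(n * m, 2, 0.4), n, m)
  variants <- tibble::tibble(
    id = paste0("v", seq_len(m)),
    maf = rep(0.3, m), rsq = rep(0.9, m),
    hwe_p = rep(0.5, m), call_rate = rep(1, m))
  if (fail > 0) {
    variants$rsq[seq_len(fail)] <- 0.2
    if (fail > 1) variants$maf[2] <- 0.005
    if (fail > 2) variants$hwe_p[3] <- 1e-8
  }
  genotype_data(x, variants)
}

test_that("variant QC drops exactly the failing variants", {
  g <- toy_genotypes(fail = 3)
  out <- filter_variants(g)
  expect_equal(ncol(out$dosage), 7L)
  expect_identical(out$variants$id, paste0("v", 4:10))
  # no-op when all pass
  g_ok <- toy_genotypes()
  expect_identical(filter_variants(g_ok)$dosage, g_ok$dosage)
  # thresholds outside [0,1] rejected; removing everything errors
  expect_error(filter_variants(g, maf_min = 2), "thresholds")
  expect_error(filter_variants(g, rsq_min = 0.99, maf_min = 0.49,
                               callrate_min = 1, hwe_p_min = 0.99999),
               "all variants removed")
})

test_that("GRM equals the brute-force pairwise computation", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:10, 1); m <- sample(5:20, 1)
    x <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(1:m, each = n)]), n, m)
    # avoid monomorphic columns: flip one entry by +-1
    mono <- which(apply(x, 2, function(col) length(unique(col)) == 1))
    x[1, mono] <- ifelse(x[1, mono] > 0, x[1, mono] - 1, x[1, mono] + 1)
    g <- genotype_data(x, tibble::tibble(
      id = paste0("v", 1:m), maf = 0.3, rsq = 0.9, hwe_p = 0.5, call_rate = 1))
    k <- compute_grm(g)
    expect_equal(unclass(as.matrix(k)), brute_grm(x), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("duplicate dosage rows give K12 = K11 = K22", {
  set.seed(9)
  x <- matrix(rbinom(4 * 12, 2, 0.4), 4, 12)
  x[2, ] <- x[1, ]
  mono <- which(apply(x, 2, function(c) length(unique(c)) == 1))
  x[3, mono] <- ifelse(x[3, mono] > 0, x[3, mono] - 1, x[3, mono] + 1)
  g <- genotype_data(x, tibble::tibble(
    id = paste0("v", 1:12), maf = 0.3, rsq = 0.9, hwe_p = 0.5, call_rate = 1))
  k <- compute_grm(g)
  expect_equal(k[1, 2], k[1, 1], tolerance = 1e-12)
  expect_equal(k[1, 2], k[2, 2], tolerance = 1e-12)
})

test_that("monomorphic variants are refused at the GRM stage", {
  x <- cbind(c(2, 2, 2, 2), c(0, 1, 2, 1))
  g <- genotype_data(x, tibble::tibble(
    id = c("mono", "ok"), maf = c(0.3, 0.3), rsq = 0.9, hwe_p = 0.5,
    call_rate = 1))
  expect_error(compute_grm(g), "monomorphic")
})

test_that("missing dosages are mean-imputed before standardization", {
  set.seed(12)
  x <- matrix(rbinom(8 * 10, 2, 0.4), 8, 10)
  x[x == 2][1] <- 2  # keep polymorphic
  xm <- x
  xm[1, 3] <- NA
  xfill <- xm
  xfill[1, 3] <- mean(xm[-1, 3])
  meta <- tibble::tibble(id = paste0("v", 1:10), maf = 0.3, rsq = 0.9,
                         hwe_p = 0.5, call_rate = 1)
  k1 <- compute_grm(genotype_data(xm, meta))
  k2 <- compute_grm(genotype_data(xfill, meta))
  expect_equal(unclass(as.matrix(k1)), unclass(as.matrix(k2)),
               tolerance = 1e-12)
})

test_that("relatedness pruning removes the expected subjects", {
  base <- diag(6) * 1.0
  k <- shapeherit:::new_grm(base, n_variants = 100, pruned_ids = character(0))
  rownames(k) <- colnames(k) <- paste0("S", 1:6)
  # no pair above threshold: no-op
  out <- prune_related(k, 0.025)
  expect_equal(nrow(out), 6L)
  expect_length(attr(out, "pruned_ids"), 0)
  # one related pair: exactly one of subjects 1, 2 removed
  k2 <- base; k2[1, 2] <- k2[2, 1] <- 0.5
  k2 <- shapeherit:::new_grm(k2, 100, character(0))
  rownames(k2) <- colnames(k2) <- paste0("S", 1:6)
  out2 <- prune_related(k2, 0.025)
  expect_equal(nrow(out2), 5L)
  expect_identical(attr(out2, "pruned_ids"), "S1")  # lowest-index tie-break
  expect_true(max(out2[upper.tri(out2)]) <= 0.025)
  # hub subject related to two others: hub goes first (max degree)
  k3 <- base
  k3[1, 2] <- k3[2, 1] <- 0.3
  k3[2, 3] <- k3[3, 2] <- 0.3
  k3 <- shapeherit:::new_grm(k3, 100, character(0))
  rownames(k3) <- colnames(k3) <- paste0("S", 1:6)
  out3 <- prune_related(k3, 0.025)
  expect_identical(attr(out3, "pruned_ids"), "S2")
  expect_equal(nrow(out3), 5L)
})

test_that("GCTA binary GRM and dosage TSV round-trip", {
  g <- toy_genotypes(n = 7, m = 15, seed = 3)
  k <- compute_grm(g)
  prefix <- file.path(withr::local_tempdir(), "test")
  write_grm_gcta(k, prefix)
  back <- read_grm_gcta(prefix)
  expect_equal(unclass(as.matrix(back)), unclass(as.matrix(k)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(k))
  expect_equal(attr(back, "n_variants"), attr(k, "n_variants"))

  path <- file.path(withr::local_tempdir(), "dose.tsv")
  write_dosage_tsv(g, path)
  g2 <- read_dosage_tsv(path)
  expect_equal(g2$dosage, g$dosage, ignore_attr = TRUE)
  expect_equal(g2$variants$maf, g$variants$maf)
})
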
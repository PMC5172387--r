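test_that("residualize centers, removes exact fits and enforces orthogonality", {
  fx <- fix_small_cohort()
  y <- unclass(fx$sim$phenotypes)
  covs <- fx$sim$covariates
  # intercept-only design centers columns
  r0 <- residualize(y, matrix(1, nrow(y), 1))
  expect_equal(colMeans(r0), rep(0, ncol(y)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # column exactly linear in age vanishes
  cm <- covariate_model(covs, "basic")
  ylin <- cbind(2 + 0.5 * covs$age, y[, 1])
  rlin <- residualize(ylin, cm)
  expect_lt(max(abs(rlin[, 1])), 1e-8)
  # residuals orthogonal to every covariate column
  r <- residualize(y, cm)
  ip <- crossprod(cm$matrix, r) / nrow(y)
  expect_lt(max(abs(ip)), 1e-8)
  # simulated age effect removed
  expect_lt(max(abs(cor(r, covs$age))), 0.05)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  covs <- tibble::tibble(age = 1:10, sex = rep(1, 10))  # sex constant
  expect_error(covariate_model(covs, "basic"), "collinear")
  covs2 <- tibble::tibble(age = 1:10, sex = rep(0:1, 5))
  covs2$icv <- covs2$age * 2
  expect_error(covariate_model(covs2, "icv"), "icv")
})

test_that("HE regression finds no heritability in a permuted phenotype", {
  fx <- fix_small_cohort()
  r <- std_cols(residualize(fx$sim$phenotypes,
                            covariate_model(fx$sim$covariates, "basic")))
  set.seed(1)
  yp <- sample(r[, 1])
  he <- he_regression(yp, fx$k)
  expect_lt(abs(he$h2_raw), 3 * he$se)
})

test_that("REML reaches the upper bound for a noiseless genetic phenotype", {
  cfg <- sim_config(n_subjects = 500, n_variants = 1000, n_vertices = 1,
                    h2_field = 0, seed = 55)
  g <- simulate_genotypes(cfg, qc_fail_frac = 0)
  w <- shapeherit:::standardize_dosage(g$dosage)
  set.seed(56)
  y <- drop(w %*% rnorm(ncol(w))) # pure genetic value, no residual
  fit <- reml_h2(y / sd(y), compute_grm(g))
  expect_gte(fit$h2, 0.95)
  expect_lt(fit$p, 1e-6)
})

test_that("identity relatedness leaves h2 unidentified: returns 0 with p 1", {
  k <- shapeherit:::new_grm(diag(50), 100, character(0))
  rownames(k) <- colnames(k) <- paste0("S", 1:50)
  set.seed(2)
  expect_warning(fit <- reml_h2(rnorm(50), k), "unidentified")
  expect_equal(fit$h2, 0)
  expect_equal(fit$p, 1)
})

test_that("REML results are identical with and without the cached eigendecomposition", {
  fx <- fix_small_cohort()
  r <- std_cols(residualize(fx$sim$phenotypes,
                            covariate_model(fx$sim$covariates, "basic")))
  f1 <- lapply(1:4, function(j) reml_h2(r[, j], fx$k))
  f2 <- lapply(1:4, function(j) reml_h2(r[, j], fx$eig))
  expect_identical(f1, f2)
})

test_that("HE and REML agree within joint uncertainty on simulated vertices", {
  fx <- fix_small_cohort()
  r <- std_cols(residualize(fx$sim$phenotypes,
                            covariate_model(fx$sim$covariates, "basic")))
  for (j in seq_len(ncol(r))) {
    he <- he_regression(r[, j], fx$k)
    ml <- reml_h2(r[, j], fx$eig)
    joint <- sqrt(he$se^2 + ifelse(is.finite(ml$se), ml$se^2, 0))
    expect_lt(abs(he$h2_raw - ml$h2), 3 * joint + 0.05)
  }
})

test_that("permutation p respects the add-one bound and nullity", {
  fx <- fix_small_cohort()
  expect_error(permutation_p(rnorm(200), fx$eig, n_perm = 50), "at least 100")
  set.seed(7)
  y <- rnorm(nrow(fx$k))  # unrelated to the GRM
  pp <- permutation_p(y, fx$eig, n_perm = 100, seed = 8)
  expect_gt(pp$p, 1 / 101 - 1e-12)
  expect_lte(pp$p, 1)
  if (pp$observed == 0) expect_gt(pp$p, 0.5)
  # reproducible under the same seed
  pp2 <- permutation_p(y, fx$eig, n_perm = 100, seed = 8)
  expect_identical(pp$p, pp2$p)
})

test_that("h2_map assembles estimates, FDR flags and the map maximum", {
  fx <- fix_small_cohort()
  cm <- covariate_model(fx$sim$covariates, "basic")
  hm <- h2_map(fx$sim$phenotypes, fx$k, cm, eig = fx$eig)
  expect_s3_class(hm, "heritability_map")
  expect_equal(nrow(hm), ncol(fx$sim$phenotypes))
  expect_true(all(hm$h2 >= 0 & hm$h2 <= 1))
  expect_true(all(hm$p > 0 & hm$p <= 1))
  expect_equal(attr(hm, "max_h2"), max(hm$h2))
  expect_identical(attr(hm, "max_vertex"), hm$vertex[which.max(hm$h2)])
  expect_identical(attr(hm, "model"), "basic")
  # mismatched subjects error
  expect_error(h2_map(fx$sim$phenotypes[1:100, ], fx$k, cm), "mismatch")
})

test_that("broom-style tidiers summarize fits", {
  fx <- fix_small_cohort()
  r <- std_cols(residualize(fx$sim$phenotypes,
                            covariate_model(fx$sim$covariates, "basic")))
  fit <- reml_h2(r[, 1], fx$eig)
  td <- tidy(fit)
  expect_identical(td$term, "h2")
  expect_equal(td$estimate, fit$h2)
  gl <- glance(fit)
  expect_equal(gl$LRT, fit$lrt)
})
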
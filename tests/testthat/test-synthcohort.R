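test_that("generators are deterministic given seed and config", {
  cfg <- sim_config(n_subjects = 30, n_variants = 40, n_vertices = 8,
                    h2_field = 0.3, seed = 1)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$variants, g2$variants)
  s1 <- simulate_vertex_phenotypes(g1, cfg)
  s2 <- simulate_vertex_phenotypes(g2, cfg)
  expect_identical(unclass(s1$phenotypes), unclass(s2$phenotypes))
  t1 <- simulate_twin_cohort(cfg)
  t2 <- simulate_twin_cohort(cfg)
  expect_identical(t1$cohort$y1, t2$cohort$y1)
  # different seed changes output
  cfg2 <- sim_config(n_subjects = 30, n_variants = 40, n_vertices = 8,
                     h2_field = 0.3, seed = 2)
  expect_false(identical(simulate_genotypes(cfg2)$dosage, g1$dosage))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(h2_field = 1.1), "h2")
  expect_error(sim_config(h2_field = 0.7, c2 = 0.4), "below 1")
  expect_error(sim_config(c2 = -0.1), "c2")
  expect_error(sim_config(noise_sd = -1), "noise")
  expect_error(sim_config(n_subjects = 0))
})

test_that("dosage moments match the drawn allele frequencies", {
  cfg <- sim_config(n_subjects = 10000, n_variants = 30, n_vertices = 1,
                    h2_field = 0, seed = 77)
  g <- simulate_genotypes(cfg, qc_fail_frac = 0)
  p <- g$variants$true_freq
  emp <- colMeans(g$dosage) / 2
  se <- sqrt(p * (1 - p) / (2 * nrow(g$dosage)))
  expect_true(all(abs(emp - p) < 3.5 * se))
  expect_true(all(g$dosage %in% 0:2))
})

test_that("a flagged fraction of variants fails the QC filters", {
  cfg <- sim_config(n_subjects = 50, n_variants = 400, n_vertices = 1,
                    h2_field = 0, seed = 5)
  g <- simulate_genotypes(cfg, qc_fail_frac = 0.2)
  kept <- filter_variants(g)
  n_fail <- sum(g$variants$rsq < 0.5 | g$variants$maf < 0.01)
  expect_gt(n_fail, 0)
  expect_equal(ncol(kept$dosage), 400L - n_fail)
})

test_that("null heritability field gives phenotypes independent of genotypes", {
  cfg <- sim_config(n_subjects = 300, n_variants = 300, n_vertices = 4,
                    h2_field = 0, covariate_effects = c(age = 0), seed = 8)
  g <- simulate_genotypes(cfg, qc_fail_frac = 0)
  sim <- simulate_vertex_phenotypes(g, cfg)
  k <- compute_grm(g)
  fits <- apply(std_cols(sim$phenotypes), 2, function(y) reml_h2(y, k)$h2)
  expect_lt(mean(fits), 0.25)
  expect_equal(sim$truth$h2, rep(0, 4))
})

test_that("phenotype variance is near 1 and truth dimensions line up", {
  cfg <- sim_config(n_subjects = 4000, n_variants = 200, n_vertices = 6,
                    h2_field = c(0, 0.2, 0.4, 0.6, 0.3, 0.1),
                    covariate_effects = c(age = 0), seed = 13)
  g <- simulate_genotypes(cfg, qc_fail_frac = 0)
  sim <- simulate_vertex_phenotypes(g, cfg)
  v <- apply(sim$phenotypes, 2, var)
  expect_true(all(abs(v - 1) < 3 * sqrt(2 / nrow(sim$phenotypes)) + 0.08))
  expect_length(sim$truth$h2, 6)
  expect_equal(dim(sim$truth$genetic_values), c(4000L, 6L))
  # per-vertex realized genetic variance tracks the target field
  gv <- apply(sim$truth$genetic_values, 2, var)
  expect_equal(gv, cfg$h2, tolerance = 0.15, ignore_attr = TRUE)
})

test_that("h2 field bumps evaluate to peaks at their centers", {
  cfg <- sim_config(n_vertices = 100,
                    h2_field = list(list(center = 20, scale = 5, peak = 0.6),
                                    list(center = 70, scale = 8, peak = 0.4)))
  expect_equal(cfg$h2[20], 0.6, tolerance = 1e-12)
  expect_equal(cfg$h2[70], 0.4, tolerance = 1e-12)
  expect_lt(cfg$h2[45], 0.05)
})

test_that("twin pair correlations match the ACE closed forms", {
  cfg <- sim_config(h2_field = 0.6, c2 = 0.2,
                    twin_pairs = c(MZ = 10000, DZ = 10000, OS = 0), seed = 31)
  tw <- simulate_twin_cohort(cfg)
  z <- tw$cohort$pairs$zygosity
  r_mz <- cor(tw$cohort$y1[z == "MZ", 1], tw$cohort$y2[z == "MZ", 1])
  r_dz <- cor(tw$cohort$y1[z == "DZ", 1], tw$cohort$y2[z == "DZ", 1])
  se <- 1 / sqrt(10000)
  expect_lt(abs(r_mz - 0.8), 3 * se * (1 - 0.8^2))
  expect_lt(abs(r_dz - 0.5), 3 * se * (1 - 0.5^2))
})

test_that("no genetic or shared variance gives uncorrelated twins", {
  cfg <- sim_config(h2_field = 0, c2 = 0,
                    twin_pairs = c(MZ = 4000, DZ = 4000, OS = 0), seed = 32)
  tw <- simulate_twin_cohort(cfg)
  z <- tw$cohort$pairs$zygosity
  expect_lt(abs(cor(tw$cohort$y1[z == "MZ", 1], tw$cohort$y2[z == "MZ", 1])),
            3 / sqrt(4000))
  expect_lt(abs(cor(tw$cohort$y1[z == "DZ", 1], tw$cohort$y2[z == "DZ", 1])),
            3 / sqrt(4000))
})

test_that("default twin design matches the replication pair mix", {
  cfg <- sim_config(h2_field = 0.5, c2 = 0.1, seed = 33)
  tw <- simulate_twin_cohort(cfg)
  tb <- table(tw$cohort$pairs$zygosity)
  expect_equal(unname(tb[c("MZ", "DZ", "OS")]), c(148L, 120L, 82L),
               ignore_attr = TRUE)
  expect_equal(nrow(tw$cohort$pairs), 350L)
  # opposite-sex pairs are sex-discordant
  os <- tw$cohort$pairs[tw$cohort$pairs$zygosity == "OS", ]
  expect_true(all(os$sex1 != os$sex2))
})

test_that("shape cohort: zero field is identity, unit bump moves 1 mm", {
  tube <- mesh_tube(n_rings = 6, n_seg = 8)
  nv <- nrow(tube$vertices)
  y0 <- matrix(0, 3, nv)
  sc <- simulate_shape_cohort(y0, template = tube, amplitude_mm = 1)
  for (m in sc$meshes) expect_equal(m$vertices, tube$vertices, tolerance = 1e-12)

  y1 <- matrix(0, 1, nv); y1[1, 10] <- 1
  sc1 <- simulate_shape_cohort(y1, template = tube, amplitude_mm = 1)
  rd0 <- radial_distance(tube, sc1$curve)
  rd1 <- radial_distance(sc1$meshes[[1]], sc1$curve)
  expect_equal(rd1[10] - rd0[10], 1.0, tolerance = 0.02)
})

test_that("measured radial distances recover the injected field (round trip)", {
  tube <- mesh_tube(n_rings = 8, n_seg = 10)
  nv <- nrow(tube$vertices)
  set.seed(44)
  y <- matrix(rnorm(20 * nv, sd = 0.5), 20, nv)
  sc <- simulate_shape_cohort(y, template = tube, amplitude_mm = 0.5)
  meas <- shape_measures(sc$meshes, tube, "radial_distance", curve = sc$curve)
  expect_equal(nrow(meas), 20L)
  lat <- which(sc$displaceable)
  cors <- vapply(lat, function(v) cor(y[, v], meas[, v]), numeric(1))
  expect_gt(min(cors), 0.99)
})

test_that("excessive inward displacement is clamped with a warning", {
  tube <- mesh_tube(n_rings = 4, n_seg = 6, radius = 2)
  nv <- nrow(tube$vertices)
  y <- matrix(-5, 1, nv)
  expect_warning(sc <- simulate_shape_cohort(y, template = tube,
                                             amplitude_mm = 1),
                 "clamp")
  rd <- radial_distance(sc$meshes[[1]], sc$curve)
  expect_true(all(rd[sc$displaceable] > 0))
})

test_that("rescan noise model: noiseless is exact, variance ratio sets ICC", {
  cfg0 <- sim_config(n_subjects = 40, n_vertices = 5, h2_field = 0,
                     noise_sd = 0, seed = 3)
  y <- matrix(rnorm(40 * 5), 40, 5)
  rs <- simulate_rescan(y, cfg0)
  expect_identical(rs$scan1, rs$scan2)
  expect_equal(rs$true_icc, rep(1, 5))

  cfg1 <- sim_config(n_subjects = 40, n_vertices = 5, h2_field = 0,
                     noise_sd = 1, seed = 3)
  y3 <- apply(y, 2, function(col) col / sd(col) * sqrt(3))  # var exactly 3
  rs1 <- simulate_rescan(y3, cfg1)
  expect_equal(rs1$true_icc, rep(0.75, 5), tolerance = 1e-12)
})
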
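#' Simulation configuration
#'
#' Defines one synthetic cohort: genotypes, a per-vertex heritability field,
#' covariate effects and a per-vertex measurement-noise profile. The seed
#' fully determines every generated object.
#'
#' Default cohort sizes mirror the study designs the pipeline targets: a
#' population cohort of unrelated adults (thousands of subjects, age and sex
#' covariates) and a twin cohort of 148 MZ, 120 DZ and 82 opposite-sex
#' complete pairs.
#'
#' @param n_subjects number of subjects.
#' @param n_variants number of independent variants.
#' @param n_vertices number of mesh vertices / phenotype columns.
#' @param h2_field heritability field: either a single value recycled to all
#'   vertices, a length-`n_vertices` vector, or a list of bumps
#'   `list(center=, scale=, peak=)` combined over a 1-D vertex lattice
#'   (peaks in `[0, 1)`).
#' @param c2 shared-environment fraction (twin mode), in `[0, 1)`.
#' @param covariate_effects named numeric vector of slopes on the phenotype
#'   for covariates among `age`, `sex`, `icv`.
#' @param noise_sd per-vertex measurement (scan-rescan) noise s.d.; scalar
#'   or length-`n_vertices`.
#' @param twin_pairs named counts `c(MZ=, DZ=, OS=)` used by
#'   [simulate_twin_cohort()].
#' @param seed integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 500, n_variants = 1000, n_vertices = 50,
                       h2_field = 0.4, c2 = 0.2,
                       covariate_effects = c(age = 0.02, sex = 0.3),
                       noise_sd = 0.3,
                       twin_pairs = c(MZ = 148, DZ = 120, OS = 82),
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_variants >= 1, n_vertices >= 1)
  if (c2 < 0 || c2 >= 1) stop("c2 must lie in [0, 1)")
  h2 <- eval_h2_field(h2_field, n_vertices)
  if (any(h2 < 0 | h2 >= 1)) stop("per-vertex h2 must lie in [0, 1)")
  if (any(h2 + c2 >= 1)) stop("peak h2 + c2 must stay below 1 at every vertex")
  noise_sd <- rep_len(noise_sd, n_vertices)
  if (any(noise_sd < 0)) stop("noise s.d. must be nonnegative")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_variants = as.integer(n_variants),
                 n_vertices = as.integer(n_vertices),
                 h2 = h2, c2 = c2,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd,
                 twin_pairs = twin_pairs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# h2 field over a 1-D vertex lattice: scalar, vector, or Gaussian bumps
eval_h2_field <- function(spec, n_vertices) {
  if (is.numeric(spec)) {
    if (length(spec) == 1L) return(rep(spec, n_vertices))
    if (length(spec) == n_vertices) return(spec)
    stop("h2_field vector must have length 1 or n_vertices")
  }
  if (is.list(spec)) {
    v <- seq_len(n_vertices)
    h2 <- rep(0, n_vertices)
    for (bump in spec) {
      h2 <- pmax(h2, bump$peak * exp(-(v - bump$center)^2 / (2 * bump$scale^2)))
    }
    return(h2)
  }
  stop("unrecognized h2_field specification")
}

#' Simulate genotype dosages with QC metadata
#'
#' Independent biallelic variants (no linkage disequilibrium): allele
#' frequencies drawn uniformly on `[0.05, 0.5]`, hard-call dosages
#' `Binomial(2, p)`. A random `qc_fail_frac` of variants is marked with low
#' imputation quality (Rsq < 0.5) and low frequency (MAF < 0.01) so that
#' downstream QC filters are exercisable; those variants' metadata, not
#' their dosages, carry the failure.
#'
#' @param config a [sim_config()].
#' @param qc_fail_frac fraction of variants flagged to fail QC.
#' @return A [genotype_data()].
#' @export
simulate_genotypes <- function(config, qc_fail_frac = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_variants < 2) stop("need at least 2 variants")
  withr_seed(config$seed, {
    n <- config$n_subjects; m <- config$n_variants
    p <- stats::runif(m, 0.05, 0.5)
    x <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    maf <- pmin(colMeans(x) / 2, 1 - colMeans(x) / 2)
    fail <- stats::runif(m) < qc_fail_frac
    rsq <- ifelse(fail, stats::runif(m, 0.05, 0.45), stats::runif(m, 0.6, 1))
    maf_meta <- ifelse(fail, stats::runif(m, 0.0005, 0.009), pmax(maf, 0.01))
    variants <- tibble::tibble(
      id = sprintf("rs%06d", seq_len(m)),
      maf = maf_meta,
      rsq = rsq,
      hwe_p = stats::runif(m, 1e-4, 1),
      call_rate = stats::runif(m, 0.97, 1),
      true_freq = p
    )
    genotype_data(x, variants, subject_ids = sprintf("S%05d", seq_len(n)))
  })
}

# deterministic seeded evaluation without clobbering the caller's RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

standardize_dosage <- function(x) {
  p <- colMeans(x) / 2
  sweep(sweep(x, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
}

#' Simulate vertex-wise phenotypes from genotypes
#'
#' Forward model of the heritability estimand. For vertex `v` with target
#' heritability `h2_v`, the phenotype is
#' `y_v = C beta + g_v + e_v`, where the genetic value
#' `g_v = W u_v` sums standardized dosages with i.i.d. weights of variance
#' `h2_v / M` (infinitesimal architecture), and the residual has variance
#' `1 - h2_v`, so the genetic+residual part has unit variance and
#' `h2_v` is the genetic variance fraction.
#'
#' @param genotypes a QC-passing [genotype_data()].
#' @param config a [sim_config()].
#' @param covariates optional subjects-level tibble (`age`, `sex`, `icv`);
#'   simulated when `NULL`.
#' @return List with `phenotypes` (subjects x vertices `shape_measures`-like
#'   matrix), `covariates` (tibble), and `truth` (a `ground_truth` list:
#'   per-vertex true `h2`, true `icc`, covariate slopes, per-subject genetic
#'   values).
#' @export
simulate_vertex_phenotypes <- function(genotypes, config, covariates = NULL) {
  stopifnot(inherits(genotypes, "genotype_data"), inherits(config, "sim_config"))
  n <- nrow(genotypes$dosage)
  m <- ncol(genotypes$dosage)
  h2 <- config$h2
  withr_seed(config$seed + 1L, {
    w <- standardize_dosage(genotypes$dosage)
    if (is.null(covariates)) {
      covariates <- tibble::tibble(
        subject_id = genotypes$subject_ids,
        age = stats::rnorm(n, 65, 10),
        sex = stats::rbinom(n, 1, 0.5),
        icv = stats::rnorm(n, 1500, 120)
      )
    }
    # weights per vertex: u_v ~ N(0, h2_v / M)
    u <- matrix(stats::rnorm(m * config$n_vertices), m, config$n_vertices)
    u <- sweep(u, 2, sqrt(h2 / m), "*")
    gval <- w %*% u                       # n x vertices, var ~= h2_v
    resid <- matrix(stats::rnorm(n * config$n_vertices), n, config$n_vertices)
    resid <- sweep(resid, 2, sqrt(1 - h2), "*")
    fixed <- matrix(0, n, config$n_vertices)
    for (nm in names(config$covariate_effects)) {
      if (!nm %in% names(covariates)) next
      z <- scale(covariates[[nm]])[, 1]
      fixed <- fixed + outer(z, rep(config$covariate_effects[[nm]],
                                    config$n_vertices))
    }
    y <- fixed + gval + resid
    rownames(y) <- genotypes$subject_ids
    colnames(y) <- paste0("v", seq_len(ncol(y)))
    sigma_between <- rep(1, config$n_vertices)
    truth <- ground_truth(
      h2 = h2,
      icc = sigma_between / (sigma_between + config$noise_sd^2),
      covariate_slopes = config$covariate_effects,
      genetic_values = gval
    )
    list(phenotypes = structure(y, class = c("shape_measures", "matrix"),
                                measure = "simulated", structure = "synthetic"),
         covariates = covariates,
         truth = truth)
  })
}

#' Ground truth container for synthetic cohorts
#'
#' @param h2 per-vertex true heritability in `[0, 1)`.
#' @param icc per-vertex true test-retest ICC in `(0, 1]`.
#' @param covariate_slopes named true slopes.
#' @param genetic_values subjects x vertices true genetic values.
#' @export
ground_truth <- function(h2, icc, covariate_slopes = NULL,
                         genetic_values = NULL) {
  structure(list(h2 = h2, icc = icc, covariate_slopes = covariate_slopes,
                 genetic_values = genetic_values),
            class = "ground_truth")
}

#' Simulate a twin cohort
#'
#' Pairs drawn from the ACE model: both members share a common-environment
#' deviate (variance `c2`) and additive-genetic deviates correlated 1 for MZ
#' and 1/2 for DZ and opposite-sex pairs, so the expected pair correlation
#' is `a2 + c2` (MZ) and `a2/2 + c2` (DZ/OS). Opposite-sex pairs are
#' modelled as DZ with discordant sex. Phenotypes have unit variance, so
#' fractions are on the standardized scale.
#'
#' @param config a [sim_config()]; `h2_field` must be scalar here (it plays
#'   the role of `a2`), `c2` the shared-environment fraction, `twin_pairs`
#'   the per-zygosity pair counts.
#' @param n_vertices number of phenotype columns to simulate (default 1).
#' @return List with `cohort` (a `twin_cohort`: tibble of pairs with
#'   `pair_id`, `zygosity`, member phenotype matrices `y1`, `y2`, member
#'   sexes) and `truth`.
#' @export
simulate_twin_cohort <- function(config, n_vertices = 1L) {
  stopifnot(inherits(config, "sim_config"))
  a2 <- config$h2[1]
  c2 <- config$c2
  if (a2 + c2 >= 1) stop("a2 + c2 must stay below 1")
  counts <- config$twin_pairs
  counts <- counts[counts > 0]
  if (!length(counts)) stop("at least one twin pair required")
  withr_seed(config$seed + 2L, {
    zyg <- rep(names(counts), counts)
    np <- length(zyg)
    rg <- ifelse(zyg == "MZ", 1, 0.5)
    e2 <- 1 - a2 - c2
    sim_col <- function() {
      a_shared <- stats::rnorm(np)
      a1 <- a_shared
      a2m <- rg * a_shared + sqrt(1 - rg^2) * stats::rnorm(np)
      cdev <- stats::rnorm(np)
      y1 <- sqrt(a2) * a1 + sqrt(c2) * cdev + sqrt(e2) * stats::rnorm(np)
      y2 <- sqrt(a2) * a2m + sqrt(c2) * cdev + sqrt(e2) * stats::rnorm(np)
      cbind(y1, y2)
    }
    cols <- lapply(seq_len(n_vertices), function(i) sim_col())
    y1 <- do.call(cbind, lapply(cols, function(cc) cc[, 1]))
    y2 <- do.call(cbind, lapply(cols, function(cc) cc[, 2]))
    colnames(y1) <- colnames(y2) <- paste0("v", seq_len(n_vertices))
    sex1 <- ifelse(zyg == "OS", 0L, stats::rbinom(np, 1, 0.5))
    sex2 <- ifelse(zyg == "OS", 1L, sex1)
    cohort <- twin_cohort(
      pairs = tibble::tibble(pair_id = sprintf("P%04d", seq_len(np)),
                             zygosity = zyg, sex1 = sex1, sex2 = sex2,
                             age = stats::rnorm(np, 23, 3)),
      y1 = y1, y2 = y2
    )
    truth <- ground_truth(h2 = rep(a2, n_vertices),
                          icc = rep(1, n_vertices),
                          covariate_slopes = c(a2 = a2, c2 = c2, e2 = e2))
    list(cohort = cohort, truth = truth)
  })
}

#' Twin cohort container
#'
#' @param pairs tibble with `pair_id`, `zygosity` (`MZ`, `DZ`, `OS`) and
#'   per-member covariates (`sex1`, `sex2`, `age`).
#' @param y1,y2 phenotype matrices (pairs x vertices) for members 1 and 2.
#' @export
twin_cohort <- function(pairs, y1, y2) {
  y1 <- as.matrix(y1); y2 <- as.matrix(y2)
  stopifnot(nrow(pairs) == nrow(y1), identical(dim(y1), dim(y2)))
  if (!all(pairs$zygosity %in% c("MZ", "DZ", "OS"))) {
    stop("zygosity must be MZ, DZ or OS")
  }
  structure(list(pairs = tibble::as_tibble(pairs), y1 = y1, y2 = y2),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  tb <- table(x$pairs$zygosity)
  cat(sprintf("<twin_cohort> %d pairs (%s), %d phenotype column(s)\n",
              nrow(x$pairs),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
              ncol(x$y1)))
  invisible(x)
}

#' Simulate a cohort of shape meshes carrying vertex phenotypes
#'
#' Each subject's mesh is the template with vertex `v` displaced along the
#' template's outward radial direction (away from the template's medial
#' curve) by `amplitude_mm * y[s, v]` mm. Vertices lying on the medial
#' curve itself (cap apexes) have no defined radial direction and are left
#' in place. Displacements large enough to invert the local radius are
#' clamped with a warning.
#'
#' @param phenotypes subjects x vertices matrix (e.g. from
#'   [simulate_vertex_phenotypes()]); column count must equal the template
#'   vertex count.
#' @param template a [surface_mesh()] (default a capped tube).
#' @param amplitude_mm mm of radial displacement per phenotype unit.
#' @return List with `meshes` (list of `surface_mesh`), `template`, `curve`
#'   (template medial curve) and `displaceable` (logical per-vertex mask).
#' @export
simulate_shape_cohort <- function(phenotypes, template = NULL,
                                  amplitude_mm = 0.5) {
  y <- as.matrix(phenotypes)
  if (is.null(template)) {
    nv <- ncol(y)
    n_seg <- 8L
    n_rings <- max(2L, as.integer(ceiling((nv - 2L) / n_seg)))
    template <- mesh_tube(n_rings = n_rings, n_seg = n_seg)
    if (n_vertices(template) != nv) {
      stop(sprintf(paste0("no default tube with exactly %d vertices; pass a ",
                          "template with matching vertex count"), nv))
    }
  }
  if (ncol(y) != n_vertices(template)) {
    stop("phenotype columns must match template vertex count")
  }
  curve <- fit_medial_curve(template)
  base_r <- radial_distance(template, curve)
  dir <- radial_direction(template, curve)
  displaceable <- base_r > 1e-8
  clamp_lo <- -0.9 * base_r   # keep radius positive: no self-intersection
  meshes <- lapply(seq_len(nrow(y)), function(s) {
    d <- amplitude_mm * y[s, ]
    d[!displaceable] <- 0
    if (any(d < clamp_lo)) {
      warning("displacement amplitude clamped to avoid self-intersection")
      d <- pmax(d, clamp_lo)
    }
    v <- template$vertices + dir * d
    surface_mesh(v, template$faces, template$structure, template$hemisphere)
  })
  names(meshes) <- rownames(y)
  list(meshes = meshes, template = template, curve = curve,
       displaceable = displaceable)
}

# unit vector from nearest medial-curve point to each vertex (0 when on-curve)
radial_direction <- function(mesh, curve) {
  p <- mesh$vertices
  best_d <- rep(Inf, nrow(p))
  best_proj <- matrix(0, nrow(p), 3)
  for (s in seq_len(nrow(curve$points) - 1L)) {
    a <- curve$points[s, ]; b <- curve$points[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(p)) else {
      pmin(1, pmax(0, drop(sweep(p, 2, a) %*% ab) / len2))
    }
    proj <- outer(t, ab) + rep(a, each = nrow(p))
    d <- sqrt(rowSums((p - proj)^2))
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_proj[upd, ] <- proj[upd, , drop = FALSE]
  }
  dirv <- p - best_proj
  nrm <- sqrt(rowSums(dirv^2))
  ok <- nrm > 1e-8
  dirv[ok, ] <- dirv[ok, , drop = FALSE] / nrm[ok]
  dirv[!ok, ] <- 0
  dirv
}

#' Simulate rescans with per-vertex measurement noise
#'
#' Returns a second phenotype matrix per subject with independent
#' `N(0, noise_sd_v^2)` measurement noise added at every vertex of both
#' sessions, emulating a scan-rescan reliability subsample. The implied
#' true ICC per vertex, `var_between / (var_between + noise_sd^2)`, is
#' recorded.
#'
#' @param phenotypes error-free subjects x vertices matrix.
#' @param config a [sim_config()] supplying `noise_sd` and `seed`.
#' @return List with `scan1`, `scan2` (noisy matrices) and `true_icc`.
#' @export
simulate_rescan <- function(phenotypes, config) {
  y <- as.matrix(phenotypes)
  sd_v <- rep_len(config$noise_sd, ncol(y))
  if (any(sd_v < 0)) stop("noise s.d. must be nonnegative")
  withr_seed(config$seed + 3L, {
    noise <- function() {
      sweep(matrix(stats::rnorm(length(y)), nrow(y), ncol(y)), 2, sd_v, "*")
    }
    s1 <- y + noise()
    s2 <- y + noise()
    vb <- apply(y, 2, stats::var)
    list(scan1 = s1, scan2 = s2,
         true_icc = vb / (vb + sd_v^2))
  })
}
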
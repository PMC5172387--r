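# Shared simulation fixtures, built lazily once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small unrelated cohort for fast unit tests
fix_small_cohort <- function() {
  fixture("small", function() {
    cfg <- sim_config(n_subjects = 200, n_variants = 400, n_vertices = 12,
                      h2_field = 0.5, seed = 101)
    g <- filter_variants(simulate_genotypes(cfg))
    k <- compute_grm(g)
    sim <- simulate_vertex_phenotypes(g, cfg)
    list(cfg = cfg, g = g, k = k, eig = grm_eigen(k), sim = sim)
  })
}

# mid-size cohort shared by the designed-property checks
fix_mid_cohort <- function() {
  fixture("mid", function() {
    cfg <- sim_config(n_subjects = 800, n_variants = 2000, n_vertices = 2,
                      h2_field = 0, seed = 202)
    g <- filter_variants(simulate_genotypes(cfg))
    k <- compute_grm(g)
    idx_b <- 401:800  # held-out half for out-of-sample component scoring
    kb <- compute_grm(genotype_data(g$dosage[idx_b, ], g$variants))
    list(cfg = cfg, g = g, k = k, eig = grm_eigen(k),
         w = shapeherit:::standardize_dosage(g$dosage),
         idx_a = 1:400, idx_b = idx_b, kb = kb, eig_b = grm_eigen(kb))
  })
}

# recovery-scale cohort (built once; reused by several acceptance checks)
fix_big_cohort <- function() {
  fixture("big", function() {
    cfg <- sim_config(n_subjects = 2000, n_variants = 5000, n_vertices = 2,
                      h2_field = 0, seed = 303)
    g <- filter_variants(simulate_genotypes(cfg))
    k <- compute_grm(g)
    list(cfg = cfg, g = g, k = k, eig = grm_eigen(k),
         w = shapeherit:::standardize_dosage(g$dosage))
  })
}

# phenotypes with target h2 from a standardized dosage matrix
make_phenos <- function(w, h2, n_cols, seed) {
  set.seed(seed)
  m <- ncol(w)
  u <- matrix(rnorm(m * n_cols, sd = sqrt(h2 / m)), m, n_cols)
  g <- w %*% u
  e <- matrix(rnorm(nrow(w) * n_cols, sd = sqrt(1 - h2)), nrow(w), n_cols)
  g + e
}

std_cols <- function(y) shapeherit:::scale_columns(scale(y, scale = FALSE))

# brute-force GRM: explicit double loop over subject pairs
brute_grm <- function(x) {
  p <- colMeans(x) / 2
  w <- sweep(sweep(x, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  n <- nrow(x); m <- ncol(x)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (v in seq_len(m)) s <- s + w[i, v] * w[j, v]
      k[i, j] <- s / m
    }
  }
  k
}

# brute-force BH: largest i with sorted p_(i) <= i q / m, by full search
brute_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  pass <- which(ps <= seq_len(m) * q / m)
  sig <- rep(FALSE, m)
  if (length(pass)) sig[ord[seq_len(max(pass))]] <- TRUE
  sig
}
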
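#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure at level `q`: flags every p-value at or below the
#' largest `p_(i)` with `p_(i) <= i q / m`. Used to localize vertices with
#' significant heritability while controlling the expected false-discovery
#' proportion. Flags are computed through `stats::p.adjust(method = "BH")`.
#'
#' @param p_values p-values in `(0, 1]`.
#' @param q FDR level in `(0, 1)`.
#' @return List with `significant` (logical flags), `threshold` (largest
#'   passing p, 0 when none pass), `q`, `n_significant`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value list")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  sig <- stats::p.adjust(p_values, method = "BH") <= q
  thr <- if (any(sig)) max(p_values[sig]) else 0
  list(significant = sig, threshold = thr, q = q,
       n_significant = sum(sig))
}

#' Analysis configuration
#'
#' Parameters of one end-to-end synthetic run: cohort sizes, heritability
#' field, covariate model(s), FDR level, seed.
#'
#' @param n_subjects,n_variants,n_vertices cohort dimensions.
#' @param h2_field as in [sim_config()].
#' @param models covariate models to fit (subset of basic/icv/volume).
#' @param q FDR level in `(0, 1)`.
#' @param noise_sd per-vertex measurement noise s.d. (scalar or
#'   length-`n_vertices`); the default ramps from 0.2 to 1.2 across the
#'   vertex index, so the map has both well- and poorly-reproducible
#'   regions.
#' @param n_rescan number of subjects in the scan-rescan subsample.
#' @param prune_threshold relatedness pruning threshold; `NULL` (default)
#'   uses `max(0.025, 5 / sqrt(M))`, i.e. the conventional 0.025 cutoff
#'   once the GRM's sampling noise (s.d. `1/sqrt(M)`) is small enough for
#'   it to be meaningful, and a noise-aware cutoff otherwise.
#' @param seed integer seed.
#' @export
analysis_config <- function(n_subjects = 300, n_variants = 1000,
                            n_vertices = 98,
                            h2_field = list(list(center = 25, scale = 6, peak = 0.6),
                                            list(center = 70, scale = 8, peak = 0.45)),
                            models = c("basic", "icv"),
                            q = 0.05,
                            noise_sd = NULL, n_rescan = 85,
                            prune_threshold = NULL,
                            seed = 1L) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (is.null(noise_sd)) noise_sd <- seq(0.2, 1.2, length.out = n_vertices)
  structure(list(n_subjects = n_subjects, n_variants = n_variants,
                 n_vertices = n_vertices, h2_field = h2_field,
                 models = match.arg(models, c("basic", "icv", "volume"),
                                    several.ok = TRUE),
                 q = q, noise_sd = noise_sd, n_rescan = n_rescan,
                 prune_threshold = prune_threshold,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full synthetic pipeline
#'
#' Simulate genotypes and vertex phenotypes -> QC + GRM (+ relatedness
#' pruning) -> shape cohort meshes -> measured radial distances -> per-model
#' heritability maps with FDR -> scan-rescan ICC map and concordance ->
#' PCA + component heritability + rank agreement -> report. Deterministic
#' for a fixed config.
#'
#' @param config an [analysis_config()].
#' @param verbose log stage progress.
#' @return A `shapeherit_report` list: `h2_maps` (one per covariate model),
#'   `icc`, `concordance`, `pca`, `component_h2`, `rank_rho`, `volumes`,
#'   `volume_h2`, `truth`, `report` (summary tibble), `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  cfg <- sim_config(n_subjects = config$n_subjects,
                    n_variants = config$n_variants,
                    n_vertices = config$n_vertices,
                    h2_field = config$h2_field,
                    noise_sd = config$noise_sd,
                    seed = config$seed)
  say("simulate: %d subjects x %d variants x %d vertices (seed %d)",
      cfg$n_subjects, cfg$n_variants, cfg$n_vertices, cfg$seed)
  g <- simulate_genotypes(cfg)
  g_qc <- filter_variants(g)
  say("qc: %d / %d variants retained", ncol(g_qc$dosage), ncol(g$dosage))
  sim <- simulate_vertex_phenotypes(g_qc, cfg)
  k0 <- compute_grm(g_qc)
  thr <- config$prune_threshold %||%
    max(0.025, 5 / sqrt(attr(k0, "n_variants")))
  k <- prune_related(k0, threshold = thr)
  keep <- rownames(k)
  say("grm: %d subjects after pruning (%d removed)", nrow(k),
      length(attr(k, "pruned_ids")))
  y <- sim$phenotypes[keep, , drop = FALSE]
  covs <- sim$covariates[match(keep, sim$covariates$subject_id), ]

  shapes <- simulate_shape_cohort(y)
  meas_true <- shape_measures(shapes$meshes, shapes$template,
                              measure = "radial_distance",
                              curve = shapes$curve)
  vols <- vapply(shapes$meshes, gross_volume, numeric(1), units = "cm3")
  covs$volume <- vols
  say("measures: radial distance for %d meshes", length(shapes$meshes))

  # every analyzed scan carries per-vertex measurement noise; the rescan
  # subsample gets an independent second scan
  rescan <- simulate_rescan(meas_true, cfg)
  meas <- rescan$scan1
  attr(meas, "measure") <- "radial_distance"

  eig <- grm_eigen(k)
  drop_flat <- apply(meas, 2, stats::sd) > 0
  h2_maps <- lapply(config$models, function(mn) {
    cm <- covariate_model(covs, mn)
    h2_map(meas[, drop_flat, drop = FALSE], k, cm, q = config$q, eig = eig)
  })
  names(h2_maps) <- config$models
  say("h2 maps: %s", paste(config$models, collapse = ", "))

  vol_fit <- reml_h2(
    scale_columns(residualize(matrix(vols, ncol = 1),
                              covariate_model(covs, "basic")))[, 1], eig)

  n_rescan <- min(config$n_rescan, nrow(y))
  iccm <- icc_map(rescan$scan1[seq_len(n_rescan), drop_flat, drop = FALSE],
                  rescan$scan2[seq_len(n_rescan), drop_flat, drop = FALSE])
  conc <- concordance(h2_maps[[1]], iccm)
  say("icc: %d rescanned subjects; concordance r = %.2f", n_rescan,
      conc$pearson)

  pca <- pca_components(meas[, drop_flat, drop = FALSE])
  ch2 <- component_h2(pca, k, covariate_model(covs, "basic"),
                      q = config$q, eig = eig)
  rho <- if (nrow(ch2) >= 3) eigen_vs_h2_rank(pca, ch2) else NA_real_

  report <- assemble_report(
    structure_name = shapes$template$structure,
    h2_maps = h2_maps, volume_h2 = vol_fit, component_maps = list(ch2))

  structure(list(h2_maps = h2_maps, icc = iccm, concordance = conc,
                 pca = pca, component_h2 = ch2, rank_rho = rho,
                 volumes = vols, volume_h2 = vol_fit,
                 truth = sim$truth, displaceable = drop_flat,
                 report = report, config = config),
            class = "shapeherit_report")
}

#' Summary report table
#'
#' One row per structure and covariate model with the gross-volume
#' heritability and the maximal vertex-wise and component-wise
#' heritability estimates with their p-values — the per-structure summary
#' a shape-heritability study tabulates.
#'
#' @param structure_name structure label.
#' @param h2_maps named list of vertex-wise `heritability_map`s.
#' @param volume_h2 a [reml_h2()] fit for the gross volume (or `NULL`).
#' @param component_maps list of component `heritability_map`s (or `NULL`).
#' @return Tibble with columns `structure`, `model`, `volume_h2`,
#'   `volume_p`, `max_vertex_h2`, `max_vertex_p`, `max_component_h2`,
#'   `max_component_p`, `n_fdr_sig`.
#' @export
assemble_report <- function(structure_name, h2_maps, volume_h2 = NULL,
                            component_maps = NULL) {
  vol_est <- if (is.null(volume_h2)) NA_real_ else volume_h2$h2
  vol_p <- if (is.null(volume_h2)) NA_real_ else volume_h2$p
  rows <- purrr::imap(h2_maps, function(hm, mn) {
    imax <- which.max(hm$h2)
    cmap <- if (!is.null(component_maps) && length(component_maps) >= 1) {
      component_maps[[min(length(component_maps), match(mn, names(h2_maps)))]]
    } else NULL
    cimax <- if (!is.null(cmap)) which.max(cmap$h2) else NA_integer_
    tibble::tibble(
      structure = structure_name,
      model = mn,
      volume_h2 = vol_est,
      volume_p = vol_p,
      max_vertex_h2 = hm$h2[imax],
      max_vertex_p = hm$p[imax],
      max_component_h2 = if (is.null(cmap)) NA_real_ else cmap$h2[cimax],
      max_component_p = if (is.null(cmap)) NA_real_ else cmap$p[cimax],
      n_fdr_sig = sum(hm$fdr_sig)
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.shapeherit_report <- function(x, ...) {
  cat("<shapeherit_report>\n")
  print(x$report)
  invisible(x)
}

#' Write a result table as TSV with a commented provenance header
#'
#' @param tbl data frame / tibble.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @param extra named character vector of extra header fields.
#' @export
write_result_tsv <- function(tbl, path, seed = NA_integer_, extra = NULL) {
  hdr <- c(sprintf("# shapeherit %s", as.character(utils::packageVersion("shapeherit"))),
           sprintf("# seed: %s", seed),
           sprintf("# written: %s", format(Sys.time(), "%Y-%m-%d")),
           if (!is.null(extra)) sprintf("# %s: %s", names(extra), extra))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(as.data.frame(tbl), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a TSV written by [write_result_tsv()]
#' @param path input path.
#' @export
read_result_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      comment.char = "#",
                                      stringsAsFactors = FALSE))
}
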
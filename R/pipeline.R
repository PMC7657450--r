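#' Configuration for a full analysis run
#'
#' Nested model ladder: m1 = ratings only; m2 = ratings + ROI activity;
#' m3 = ratings + ROI activity + pattern expression. The smoothing sweep
#' kernels must be sorted ascending and start at 0.
#'
#' @param params a [generator_params()] (ignored when `study` supplied).
#' @param study optional pre-built `study_dataset`; default simulates one.
#' @param z_thresh voxelwise cluster-forming threshold (default 2.56).
#' @param alpha target family-wise error rate.
#' @param connectivity cluster connectivity (6/18/26).
#' @param n_null_iter Monte-Carlo iterations for the extent threshold.
#' @param sweep_kernels_mm smoothing-sweep kernels (FWHM, mm).
#' @param chains,iter,warmup MCMC settings for every model fit.
#' @param seed master seed for the analysis stages.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(params = generator_params(), study = NULL,
                            z_thresh = 2.56, alpha = 0.05,
                            connectivity = 26L, n_null_iter = 500L,
                            sweep_kernels_mm = seq(0, 40, by = 4),
                            chains = 4L, iter = 1000L, warmup = 500L,
                            seed = 1L) {
  if (is.unsorted(sweep_kernels_mm) || sweep_kernels_mm[1] != 0) {
    stop("sweep kernels must be ascending and start at 0")
  }
  structure(list(params = params, study = study, z_thresh = z_thresh,
                 alpha = alpha, connectivity = as.integer(connectivity),
                 n_null_iter = as.integer(n_null_iter),
                 sweep_kernels_mm = sweep_kernels_mm,
                 chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "analysis_config")
}

model_ladder_specs <- function(config, hierarchical, seed_offset = 0L) {
  preds <- list(m1 = "rating",
                m2 = c("rating", "roi_mean"),
                m3 = c("rating", "roi_mean", "expression_r"))
  lapply(preds, function(p) {
    model_spec(p, hierarchical = hierarchical, chains = config$chains,
               iter = config$iter, warmup = config$warmup,
               seed = config$seed + seed_offset)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a study, builds the feature table, fits the
#' nested model ladder m1-m3 within person and at the article level,
#' compares m3 against m1 and m2 by PSIS-LOO, runs the overlap-masking
#' sensitivity analysis (Monte-Carlo extent threshold, signed pattern
#' thresholding, cluster removal, refit) and the pattern smoothing sweep.
#'
#' @param config an [analysis_config()].
#' @return A `results_bundle`: list with `features`, `fits_within`,
#'   `fits_article`, `r2_within`, `r2_article`, `loo_comparisons`,
#'   `extent`, `clusters`, `masked_pattern`, `masked_fit_within`,
#'   `masked_fit_article`, `sweep` (per-kernel coefficient table),
#'   `provenance`.
#' @export
run_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  study <- stage("simulate", {
    if (is.null(config$study)) {
      simulate_default_study(config$params)
    } else config$study
  })
  features <- stage("features", {
    standardize(build_feature_table(study))
  })
  specs_w <- model_ladder_specs(config, hierarchical = TRUE)
  specs_a <- model_ladder_specs(config, hierarchical = FALSE,
                                seed_offset = 100L)
  fits_w <- stage("fit_within", lapply(specs_w, fit_hierarchical,
                                       table = features))
  fits_a <- stage("fit_article", lapply(specs_a, fit_article_level,
                                        table = features))
  r2_w <- lapply(fits_w, bayes_r2)
  r2_a <- lapply(fits_a, bayes_r2)
  loo_cmp <- stage("loo", list(
    within_m3_m1 = compare_loo(fits_w$m3, fits_w$m1),
    within_m3_m2 = compare_loo(fits_w$m3, fits_w$m2),
    article_m3_m1 = compare_loo(fits_a$m3, fits_a$m1),
    article_m3_m2 = compare_loo(fits_a$m3, fits_a$m2)))

  ## sensitivity: extent threshold -> signed clusters -> overlap masking
  null_dist <- stage("null_sim", simulate_max_cluster_null(
    study$grid, fwhm_mm = 8, z_thresh = config$z_thresh,
    n_iter = config$n_null_iter, connectivity = config$connectivity,
    seed = config$seed + 7L))
  extent <- stage("extent", extent_threshold(null_dist, config$alpha))
  clusters <- stage("threshold", threshold_pattern(
    study$pattern, config$z_thresh, extent$k_extent, config$connectivity))
  masked <- stage("mask", mask_out_overlap(study$pattern, clusters,
                                           study$rois))
  feat_masked <- stage("masked_features", {
    standardize(build_feature_table(study, pattern = masked))
  })
  spec_masked_w <- model_spec("expression_r", hierarchical = TRUE,
                              chains = config$chains, iter = config$iter,
                              warmup = config$warmup,
                              seed = config$seed + 200L)
  spec_masked_a <- model_spec("expression_r", hierarchical = FALSE,
                              chains = config$chains, iter = config$iter,
                              warmup = config$warmup,
                              seed = config$seed + 201L)
  masked_fit_w <- stage("masked_fit", fit_hierarchical(feat_masked,
                                                       spec_masked_w))
  masked_fit_a <- stage("masked_fit", fit_article_level(feat_masked,
                                                        spec_masked_a))

  ## smoothing sweep: expression-only within-person refit per kernel
  sweep_tables <- stage("sweep_features", smoothing_sweep(
    study$pattern, config$sweep_kernels_mm, study))
  sweep <- stage("sweep_fits", {
    rows <- lapply(seq_along(sweep_tables), function(i) {
      ft <- standardize(sweep_tables[[i]])
      sp <- model_spec("expression_r", hierarchical = TRUE,
                       chains = config$chains, iter = config$iter,
                       warmup = config$warmup,
                       seed = config$seed + 300L + i)
      f <- fit_hierarchical(ft, sp)
      s <- f$summary[f$summary$term == "expression_r", ]
      data.frame(fwhm_mm = config$sweep_kernels_mm[i], beta = s$mean,
                 lower = s$lower, upper = s$upper)
    })
    do.call(rbind, rows)
  })

  structure(list(
    features = features, fits_within = fits_w, fits_article = fits_a,
    r2_within = r2_w, r2_article = r2_a, loo_comparisons = loo_cmp,
    null_dist = null_dist, extent = extent, clusters = clusters,
    masked_pattern = masked, masked_fit_within = masked_fit_w,
    masked_fit_article = masked_fit_a, sweep = sweep,
    provenance = list(seed = config$seed,
                      params = unclass(config$params),
                      z_thresh = config$z_thresh, alpha = config$alpha,
                      n_null_iter = config$n_null_iter,
                      kernels = config$sweep_kernels_mm,
                      version = as.character(utils::packageVersion("neuroshare")))),
    class = "results_bundle")
}

results_tables <- function(results) {
  coef_tab <- do.call(rbind, lapply(c("within", "article"), function(lv) {
    fits <- results[[paste0("fits_", lv)]]
    do.call(rbind, lapply(names(fits), function(mn) {
      s <- fits[[mn]]$summary
      s <- s[s$term != "sigma", , drop = FALSE]
      cbind(level = lv, model = mn, s)
    }))
  }))
  r2_tab <- do.call(rbind, lapply(c("within", "article"), function(lv) {
    r2 <- results[[paste0("r2_", lv)]]
    do.call(rbind, lapply(names(r2), function(mn) {
      data.frame(level = lv, model = mn, r2_median = r2[[mn]]$median,
                 lower = r2[[mn]]$lower, upper = r2[[mn]]$upper)
    }))
  }))
  loo_tab <- do.call(rbind, lapply(names(results$loo_comparisons),
                                   function(cn) {
    cc <- results$loo_comparisons[[cn]]
    data.frame(comparison = cn, delta_looic = cc$delta_looic, se = cc$se)
  }))
  list(coefficients = coef_tab, r2 = r2_tab, loo = loo_tab,
       sweep = results$sweep)
}

#' Write report tables for a results bundle
#'
#' Emits `coefficients.csv` (term-level posterior summaries per model),
#' `r2.csv`, `loo_comparisons.csv`, `sweep.csv`, a machine-readable
#' `summary.json` and a plain-text `run.log` under `outdir`. The tables are
#' derived from the serialized fits alone, so regenerating the report from
#' a saved bundle reproduces it exactly.
#'
#' @param results a `results_bundle`.
#' @param outdir output directory (created if missing).
#' @return Invisibly, the list of written paths.
#' @export
write_report <- function(results, outdir) {
  stopifnot(inherits(results, "results_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tabs <- results_tables(results)
  paths <- character()
  for (nm in names(tabs)) {
    p <- file.path(outdir, paste0(
      c(coefficients = "coefficients", r2 = "r2", loo = "loo_comparisons",
        sweep = "sweep")[nm], ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  summ <- list(
    provenance = results$provenance,
    extent = unclass(results$extent),
    n_clusters = length(results$clusters$sizes),
    masked_voxels = results$masked_pattern$masked_voxels,
    r2 = tabs$r2, loo = tabs$loo)
  jp <- file.path(outdir, "summary.json")
  jsonlite::write_json(summ, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  lp <- file.path(outdir, "run.log")
  writeLines(c(
    sprintf("neuroshare run, seed %d", results$provenance$seed),
    sprintf("extent threshold: k = %d at z = %.2f (achieved FWER %.4f)",
            results$extent$k_extent, results$extent$z_thresh,
            results$extent$achieved_fwer),
    sprintf("clusters surviving: %d", length(results$clusters$sizes)),
    sprintf("models fit: %d within-person, %d article-level, 2 masked, %d sweep",
            length(results$fits_within), length(results$fits_article),
            nrow(results$sweep))), lp)
  invisible(c(paths, jp, lp))
}
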
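#' Pipeline configuration
#'
#' Bundles the analysis parameters of the full asymmetry pipeline with the
#' simulation settings of the synthetic cohort it runs on. Analysis defaults
#' follow the method's standard settings: cluster-forming threshold z = 2.3,
#' 10,000 randomizations, covariate-screen alpha 0.001.
#'
#' @param simulation a [simulation_config()] describing the cohort.
#' @param threshold_z cluster-forming threshold for both cluster tests.
#' @param n_perm randomizations per cluster test.
#' @param alpha significance level for cluster-corrected p-values.
#' @param screen_alpha covariate-screen significance threshold.
#' @param rng_seed seed for the analysis-stage randomness (the cohort has its
#'   own seed inside `simulation`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            threshold_z = 2.3, n_perm = 10000L,
                            alpha = 0.05, screen_alpha = 0.001,
                            rng_seed = 1L) {
  stopifnot(inherits(simulation, "simulation_config"))
  if (threshold_z <= 0) stop("config error: threshold_z must be positive")
  if (n_perm < 100L) stop("config error: n_perm must be >= 100")
  structure(list(simulation = simulation, threshold_z = threshold_z,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 screen_alpha = screen_alpha, rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

significant_cluster_union <- function(test, alpha) {
  keep <- Filter(function(cl) cl$p_corr <= alpha, test$clusters)
  sort(unique(unlist(lapply(keep, `[[`, "vertices"))))
}

#' Run the full asymmetry pipeline on a synthetic cohort
#'
#' Stages: simulate the cohort; per-subject signed/unsigned activity
#' asymmetry (RRA) maps and their Fisher-randomization cluster test;
#' per-subject connectivity asymmetry (FCA) maps and their cluster test;
#' conjunction of the significant clusters (FA cluster) with per-subject
#' coefficient extraction and the RRA-FCA cross-index correlation; optional
#' behavioural covariate screen; seed-by-network profile ANOVA with post hoc
#' contrasts; and the hemispheric temporal-SNR control. When a cluster test
#' yields no significant cluster the conjunction falls back to the single
#' most massive cluster of each test (reported in the log).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, maps (TSV), coefficient
#'   tables (TSV), results (JSON) and a provenance log are written there.
#' @param covariates optional data frame of behavioural covariates (one row
#'   per subject) for the screen stage.
#' @return A list with elements `cohort`, `rra_maps`, `rra_test`, `fca_test`,
#'   `fa_cluster`, `coefficients`, `cross_correlation`, `screen`, `profile`,
#'   `anova`, `posthoc`, `snr`.
#' @export
run_pipeline <- function(config, out_dir = NULL, covariates = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- c(paste0("asymmap pipeline, seed = ", config$rng_seed,
                        ", cohort seed = ", config$simulation$rng_seed),
                 paste0("config hash = ",
                        sum(utils::head(utf8ToInt(paste(
                          deparse(unclass(config$simulation)), collapse = "")), 10000))))

  cohort <- simulate_cohort(config$simulation)
  mask <- cohort$masks$ompfc

  rra_maps <- lapply(cohort$contrast, function(pair) {
    rra_map(pair$left, pair$right, cohort$corr, mask)
  })
  rra_test <- fisher_randomization_test(rra_maps, mask, cohort$adjacency,
                                        threshold_z = config$threshold_z,
                                        n_perm = config$n_perm,
                                        rng_seed = config$rng_seed)
  fca_subject_maps <- lapply(cohort$rest, function(ts) {
    fca_from_series(ts$left, ts$right, mask, cohort$corr)
  })
  fca_test <- fisher_randomization_test(fca_subject_maps, mask, cohort$adjacency,
                                        threshold_z = config$threshold_z,
                                        n_perm = config$n_perm,
                                        rng_seed = config$rng_seed + 1L)

  pick <- function(test) {
    sig <- significant_cluster_union(test, config$alpha)
    if (length(sig) > 0) return(sig)
    if (length(test$clusters) > 0) return(test$clusters[[1]]$vertices)
    integer(0)
  }
  rra_cluster <- pick(rra_test)
  fca_cluster <- pick(fca_test)
  fa_cluster <- if (length(rra_cluster) && length(fca_cluster)) {
    suppressWarnings(conjunction_mask(rra_cluster, fca_cluster))
  } else integer(0)
  log_lines <- c(log_lines,
                 paste0("RRA cluster: ", length(rra_cluster), " vertices; ",
                        "FCA cluster: ", length(fca_cluster), " vertices; ",
                        "FA cluster: ", length(fa_cluster), " vertices"))

  coef_region <- if (length(fa_cluster) > 0) fa_cluster else cohort$masks$planted
  rra_coeff <- vapply(rra_maps, extract_region_coefficient, numeric(1),
                      region = coef_region, which = "signed")
  fca_coeff <- vapply(fca_subject_maps, function(v) mean(v[coef_region]), numeric(1))
  coefficients <- fa_coefficients(rra_coeff, fca_coeff)
  cross <- cross_index_correlation(rra_coeff, fca_coeff)

  screen <- if (!is.null(covariates)) {
    covariate_screen(coefficients$fa, covariates, alpha = config$screen_alpha)
  } else NULL

  networks <- list(dmn_left = cohort$masks$dmn, dmn_right = cohort$masks$dmn,
                   exn_left = cohort$masks$exn, exn_right = cohort$masks$exn)
  profile <- build_profile_table(cohort$rest, coef_region, coef_region, networks)
  anova <- three_way_anova(profile)
  posthoc <- posthoc_contrasts(profile)

  snr <- snr_check(lapply(cohort$rest, `[[`, "left"),
                   lapply(cohort$rest, `[[`, "right"),
                   coef_region, cohort$corr)

  results <- list(cohort = cohort, rra_maps = rra_maps, rra_test = rra_test,
                  fca_test = fca_test, fa_cluster = fa_cluster,
                  coefficients = coefficients, cross_correlation = cross,
                  screen = screen, profile = profile, anova = anova,
                  posthoc = posthoc, snr = snr)

  if (!is.null(out_dir)) {
    write_vertex_map(replace(rra_test$t_map, is.na(rra_test$t_map), 0),
                     file.path(out_dir, "rra_group_t.tsv"))
    write_vertex_map(replace(fca_test$t_map, is.na(fca_test$t_map), 0),
                     file.path(out_dir, "fca_group_t.tsv"))
    if (length(fa_cluster) > 0) write_mask(fa_cluster, file.path(out_dir, "fa_cluster.txt"))
    utils::write.table(coefficients, file.path(out_dir, "coefficients.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(profile, file.path(out_dir, "profile_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary_json <- list(
      rra_clusters = lapply(rra_test$clusters, function(cl)
        list(n_vertices = length(cl$vertices), mass = cl$mass, p_corr = cl$p_corr)),
      fca_clusters = lapply(fca_test$clusters, function(cl)
        list(n_vertices = length(cl$vertices), mass = cl$mass, p_corr = cl$p_corr)),
      fa_cluster_size = length(fa_cluster),
      cross_correlation = as.list(cross),
      anova = as.data.frame(anova$effects),
      posthoc = as.data.frame(posthoc),
      snr_p = snr$p
    )
    jsonlite::write_json(summary_json, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  invisible(results)
}
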
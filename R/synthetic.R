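#' Configuration of a synthetic bilateral cohort
#'
#' Defines the study conditions for the simulator: cohort size, mesh
#' resolution, mask sizes, planted effect sizes for activity (RRA) and
#' connectivity (FCA) lateralization, noise levels, and the target correlation
#' between the two per-subject asymmetry magnitudes.
#'
#' Defaults describe a desk-scale cohort with a clearly lateralized hot spot:
#' a 642-vertex icosphere per hemisphere, a 150-vertex analysis mask, a
#' 20-vertex planted region carrying a 1.5 z-unit right-dominant activity
#' increment over unit-SD smoothed noise, a 0.4 increment of the planted
#' seed's default-mode coupling, and a 0.6 correlation between the two
#' latent asymmetry magnitudes.
#'
#' @param n_subjects number of subjects.
#' @param V_brain vertices per hemisphere; must be an icosphere count
#'   (10 * 4^s + 2).
#' @param V_mask vertices in the OMPFC-like analysis mask.
#' @param T_len timepoints per resting run.
#' @param planted_size vertices in the planted asymmetric region (within mask).
#' @param rra_effect mean activity increment (z-units) in the dominant
#'   hemisphere's planted region.
#' @param fca_effect mean increment of the planted seed's DMN-latent coupling
#'   in the connectivity-dominant hemisphere.
#' @param dominance `"all-right"` or `"mixed"` (per-subject sign drawn with
#'   probability `p_right` of right dominance).
#' @param p_right probability of right dominance under `"mixed"`.
#' @param latent_sd between-subject SD of the asymmetry magnitudes, as a
#'   fraction of their mean.
#' @param noise_sd SD of vertex-wise contrast-map noise before smoothing.
#' @param smooth_rounds rounds of neighbour averaging applied to map noise
#'   (0 = spatially exchangeable noise).
#' @param target_rra_fca_corr correlation between the activity and
#'   connectivity asymmetry magnitudes across subjects.
#' @param seed_coupling baseline loading of mask vertices on the DMN and ExN
#'   latents.
#' @param network_size vertices per network patch per hemisphere.
#' @param ts_noise_sd SD of white noise added to each vertex time series.
#' @param baseline_mean constant added to every series (raw signal level, so
#'   temporal SNR is defined); correlations are unaffected.
#' @param rng_seed integer seed; all randomness flows from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 20L, V_brain = 642L, V_mask = 150L,
                              T_len = 300L, planted_size = 20L,
                              rra_effect = 1.5, fca_effect = 0.4,
                              dominance = c("all-right", "mixed"),
                              p_right = 1, latent_sd = 0.5, noise_sd = 1,
                              smooth_rounds = 2L, target_rra_fca_corr = 0.6,
                              seed_coupling = 0.3, network_size = 60L,
                              ts_noise_sd = 1, baseline_mean = 100,
                              rng_seed = 1L) {
  dominance <- match.arg(dominance)
  cfg <- list(n_subjects = as.integer(n_subjects), V_brain = as.integer(V_brain),
              V_mask = as.integer(V_mask), T_len = as.integer(T_len),
              planted_size = as.integer(planted_size), rra_effect = rra_effect,
              fca_effect = fca_effect, dominance = dominance, p_right = p_right,
              latent_sd = latent_sd, noise_sd = noise_sd,
              smooth_rounds = as.integer(smooth_rounds),
              target_rra_fca_corr = target_rra_fca_corr,
              seed_coupling = seed_coupling, network_size = as.integer(network_size),
              ts_noise_sd = ts_noise_sd, baseline_mean = baseline_mean,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    if (n_subjects < 1L) stop("config error: n_subjects must be positive")
    if (V_brain < 12L) stop("config error: V_brain too small to triangulate (need >= 12)")
    if (is.na(icosphere_level(V_brain))) {
      stop("config error: V_brain must be an icosphere count (12, 42, 162, 642, 2562, ...)")
    }
    if (planted_size > V_mask) stop("config error: planted region must lie within the mask")
    if (V_mask > V_brain) stop("config error: V_mask exceeds V_brain")
    if (T_len < 20L) stop("config error: T_len must be >= 20")
    if (abs(target_rra_fca_corr) > 1) stop("config error: |target_rra_fca_corr| must be <= 1")
    if (p_right < 0 || p_right > 1) stop("config error: p_right must be in [0, 1]")
  })
  structure(cfg, class = "simulation_config")
}

icosphere_level <- function(V) {
  s <- log((V - 2) / 10, base = 4)
  if (V >= 12 && isTRUE(all.equal(s, round(s)))) round(s) else NA_integer_
}

#' Identical left/right meshes with identity correspondence
#'
#' Builds one icosphere triangulation, labels two copies left and right, and
#' pairs vertices by index. The synthetic cohorts are geometrically symmetric
#' by construction, so homotopic correspondence is the identity.
#'
#' @param V_brain vertices per hemisphere (icosphere count).
#' @return List with `left`, `right` ([surface_mesh()]) and `corr`
#'   ([correspondence_map()]).
#' @export
make_symmetric_cohort_mesh <- function(V_brain) {
  lvl <- icosphere_level(V_brain)
  if (V_brain < 12L || is.na(lvl)) {
    stop("config error: V_brain must be an icosphere count >= 12 (12, 42, 162, 642, ...)")
  }
  base <- icosphere(lvl, hemisphere = "right")
  left <- surface_mesh(base$vertex_coords, base$triangles, "left")
  list(left = left, right = base, corr = correspondence_map(seq_len(V_brain)))
}

# k rounds of neighbour averaging (self + edge neighbours); the simulator's
# stand-in for geodesic Gaussian smoothing of map noise.
smooth_on_mesh <- function(values, adjacency, rounds) {
  for (r in seq_len(rounds)) {
    values <- vapply(seq_along(values), function(i) {
      nb <- adjacency[[i]]
      (values[i] + sum(values[nb])) / (1 + length(nb))
    }, numeric(1))
  }
  values
}

# The target correlation is a property of the realized cohort ("across
# subjects"), so the construction fixes the SAMPLE correlation of the two
# standardized latent vectors at exactly rho via in-sample orthogonalization
# (for n >= 3; tiny cohorts fall back to shared-component mixing). This keeps
# recovery tests about the estimators, not about cohort-level sampling noise.
draw_ground_truth <- function(cfg) {
  n <- cfg$n_subjects
  rho <- cfg$target_rra_fca_corr
  z0 <- stats::rnorm(n); z1 <- stats::rnorm(n)
  if (n >= 3L && stats::sd(z0) > 0) {
    x <- as.numeric(scale(z0))
    e <- stats::residuals(stats::lm(z1 ~ x))
    if (stats::sd(e) > 0) {
      e <- e / stats::sd(e)
      con_std <- rho * x + sqrt(1 - rho^2) * e
    } else {
      con_std <- rho * x
    }
    act_std <- x
  } else {
    act_std <- sqrt(abs(rho)) * z0 + sqrt(1 - abs(rho)) * z1
    con_std <- sign(rho) * act_std
  }
  dominance <- switch(cfg$dominance,
    "all-right" = rep(1, n),
    "mixed" = ifelse(stats::runif(n) < cfg$p_right, 1, -1)
  )
  list(
    activity_magnitude = cfg$rra_effect * (1 + cfg$latent_sd * act_std),
    connectivity_magnitude = cfg$fca_effect * (1 + cfg$latent_sd * con_std),
    dominance = dominance
  )
}

#' Simulate a bilateral cohort with planted, known lateralization
#'
#' Generates, under one RNG seed: symmetric left/right meshes; an OMPFC-like
#' analysis mask, a contiguous planted region inside it, and DMN/ExN network
#' patches outside it; per-subject left/right contrast maps (bilateral
#' baseline + lateralized increment in the planted region + smoothed noise);
#' and per-subject left/right resting time series from a linear latent-factor
#' model in which planted-seed vertices of the dominant hemisphere carry an
#' increased DMN-latent loading. The per-subject activity and connectivity
#' asymmetry magnitudes share a latent component so their correlation targets
#' `target_rra_fca_corr`.
#'
#' @param cfg a [simulation_config()].
#' @param with_timeseries generate resting time series (set `FALSE` to build
#'   contrast maps only, which is much faster).
#' @return An `asym_cohort` list: `config`, `meshes`, `corr`, `adjacency`,
#'   `masks` (`ompfc`, `planted`, `dmn`, `exn`; network masks apply at the
#'   same indices on both hemispheres), `truth`, `contrast` (per subject,
#'   `left`/`right` [vertex_map()]s) and `rest` (per subject, `left`/`right`
#'   T x V matrices; raw, mean `baseline_mean`).
#' @export
simulate_cohort <- function(cfg, with_timeseries = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$rng_seed)
  meshes <- make_symmetric_cohort_mesh(cfg$V_brain)
  adjacency <- build_adjacency(meshes$right)
  V <- cfg$V_brain

  ompfc <- mesh_patch(adjacency, 1L, cfg$V_mask)
  planted <- mesh_patch(adjacency, 1L, cfg$planted_size)
  coords <- meshes$right$vertex_coords
  d_pole <- sqrt(rowSums(sweep(coords, 2, coords[1L, ])^2))
  dmn_center <- which.max(replace(d_pole, ompfc, -Inf))
  dmn <- mesh_patch(adjacency, dmn_center, cfg$network_size, avoid = ompfc)
  d_dmn <- sqrt(rowSums(sweep(coords, 2, coords[dmn_center, ])^2))
  score <- d_pole + d_dmn
  score[c(ompfc, dmn)] <- -Inf
  exn_center <- which.max(score)
  exn <- mesh_patch(adjacency, exn_center, cfg$network_size,
                    avoid = c(ompfc, dmn))
  masks <- list(ompfc = ompfc, planted = planted, dmn = dmn, exn = exn)

  truth <- draw_ground_truth(cfg)
  contrast <- simulate_contrast_maps(cfg, truth, adjacency, masks)
  rest <- if (with_timeseries) simulate_rest_timeseries(cfg, truth, masks) else NULL

  structure(list(config = cfg, meshes = meshes, corr = meshes$corr,
                 adjacency = adjacency, masks = masks, truth = truth,
                 contrast = contrast, rest = rest),
            class = "asym_cohort")
}

#' Per-subject left/right contrast maps
#'
#' Dominant-hemisphere map = baseline + the subject's activity magnitude
#' inside the planted region + smoothed Gaussian noise; the other hemisphere
#' gets baseline + noise only. Exposed separately so map-only cohorts can be
#' built cheaply; normally called via [simulate_cohort()].
#'
#' @param cfg a [simulation_config()].
#' @param truth ground-truth list (per-subject magnitudes and dominance).
#' @param adjacency mesh adjacency (for noise smoothing).
#' @param masks mask list containing `planted`.
#' @return List of per-subject lists with `left` and `right` [vertex_map()]s.
#' @export
simulate_contrast_maps <- function(cfg, truth, adjacency, masks) {
  V <- cfg$V_brain
  baseline <- rep(1, V)
  lapply(seq_len(cfg$n_subjects), function(s) {
    one_hemi <- function() {
      noise <- stats::rnorm(V, sd = cfg$noise_sd)
      if (cfg$noise_sd > 0 && cfg$smooth_rounds > 0) {
        noise <- smooth_on_mesh(noise, adjacency, cfg$smooth_rounds)
      }
      baseline + noise
    }
    left <- one_hemi()
    right <- one_hemi()
    mag <- truth$activity_magnitude[s]
    if (truth$dominance[s] > 0) {
      right[masks$planted] <- right[masks$planted] + mag
    } else {
      left[masks$planted] <- left[masks$planted] + mag
    }
    list(left = vertex_map(left, "left", s), right = vertex_map(right, "right", s))
  })
}

# Base latent loadings for one hemisphere: columns (DMN, ExN).
base_loadings <- function(cfg, masks) {
  L <- matrix(0, cfg$V_brain, 2L, dimnames = list(NULL, c("dmn", "exn")))
  L[masks$dmn, "dmn"] <- 1
  L[masks$exn, "exn"] <- 1
  L[masks$ompfc, ] <- cfg$seed_coupling
  L
}

# One subject's full generative model: loading matrices and per-vertex noise
# SDs for both hemispheres. The planted DMN-coupling increment is variance
# compensated: noise variance at the affected vertices is reduced so total
# series variance is unchanged, which keeps ExN correlations and temporal SNR
# identical across hemispheres (the manipulation changes the DMN coupling and
# nothing else). The compensation is floored at 10% of the nominal noise
# variance for extreme subjects.
subject_model <- function(cfg, truth, masks, s) {
  base <- base_loadings(cfg, masks)
  load_l <- load_r <- base
  nsd_l <- nsd_r <- rep(cfg$ts_noise_sd, cfg$V_brain)
  inc <- truth$connectivity_magnitude[s]
  c0 <- cfg$seed_coupling
  extra_var <- (c0 + inc)^2 - c0^2
  comp_var <- pmax(cfg$ts_noise_sd^2 - extra_var, (0.1 * cfg$ts_noise_sd)^2)
  if (truth$dominance[s] > 0) {
    load_r[masks$planted, "dmn"] <- load_r[masks$planted, "dmn"] + inc
    nsd_r[masks$planted] <- sqrt(comp_var)
  } else {
    load_l[masks$planted, "dmn"] <- load_l[masks$planted, "dmn"] + inc
    nsd_l[masks$planted] <- sqrt(comp_var)
  }
  list(load_l = load_l, load_r = load_r, nsd_l = nsd_l, nsd_r = nsd_r)
}

#' Per-subject loading matrices of the latent time-series model
#'
#' Returns the V x 2 loading matrices (columns: DMN latent, ExN latent) of one
#' subject's left and right hemispheres, including the planted coupling
#' increment, together with the per-vertex noise SDs. The population
#' correlation between any two vertices is then available in closed form:
#' `cov = a_u . a_v`, `var = |a|^2 + noise_sd^2` (vertex-wise).
#'
#' @param cohort an `asym_cohort`.
#' @param s subject index.
#' @return List with `left` and `right` V x 2 loading matrices and
#'   `noise_sd_left` / `noise_sd_right` per-vertex noise SDs.
#' @export
subject_loadings <- function(cohort, s) {
  m <- subject_model(cohort$config, cohort$truth, cohort$masks, s)
  list(left = m$load_l, right = m$load_r,
       noise_sd_left = m$nsd_l, noise_sd_right = m$nsd_r)
}

#' Per-subject left/right resting time series
#'
#' Each vertex's series is a loading-weighted sum of two shared network
#' latents (DMN-like and ExN-like, i.i.d. standard normal over time) plus
#' white noise and a constant raw baseline. Planted-seed vertices of the
#' connectivity-dominant hemisphere carry a DMN loading increased by the
#' subject's connectivity magnitude; ExN loadings are identical across
#' hemispheres, and the DMN increment is variance-compensated through the
#' vertex noise so total series variance (hence ExN correlation and temporal
#' SNR) stays matched across hemispheres. Normally called via
#' [simulate_cohort()].
#'
#' @inheritParams simulate_contrast_maps
#' @param masks mask list with `ompfc`, `planted`, `dmn`, `exn`.
#' @return List of per-subject lists with `left` and `right` T x V matrices.
#' @export
simulate_rest_timeseries <- function(cfg, truth, masks) {
  V <- cfg$V_brain
  Tn <- cfg$T_len
  lapply(seq_len(cfg$n_subjects), function(s) {
    latents <- matrix(stats::rnorm(Tn * 2L), Tn, 2L)
    mdl <- subject_model(cfg, truth, masks, s)
    one_hemi <- function(load, nsd) {
      noise <- matrix(stats::rnorm(Tn * V), Tn, V) * rep(nsd, each = Tn)
      latents %*% t(load) + noise + cfg$baseline_mean
    }
    list(left = one_hemi(mdl$load_l, mdl$nsd_l),
         right = one_hemi(mdl$load_r, mdl$nsd_r))
  })
}

#' Relabel the hemispheres of a synthetic cohort
#'
#' Swaps every left/right pair (contrast maps, time series) and flips the
#' ground-truth dominance signs. Used to check that signed quantities negate
#' and unsigned quantities are invariant under hemisphere relabeling.
#'
#' @param cohort an `asym_cohort`.
#' @return The relabeled cohort.
#' @export
swap_hemispheres <- function(cohort) {
  swap_vm <- function(pair) {
    list(left = vertex_map(as.numeric(pair$right), "left",
                           attr(pair$right, "subject_id")),
         right = vertex_map(as.numeric(pair$left), "right",
                            attr(pair$left, "subject_id")))
  }
  cohort$contrast <- lapply(cohort$contrast, swap_vm)
  if (!is.null(cohort$rest)) {
    cohort$rest <- lapply(cohort$rest, function(p) list(left = p$right, right = p$left))
  }
  cohort$truth$dominance <- -cohort$truth$dominance
  cohort
}

#' Write a synthetic cohort to disk
#'
#' Per-subject contrast maps (GIFTI metric or TSV), the mask files (0-based
#' index lists), the identity correspondence, and the ground truth as JSON.
#' Time series are not written (regenerate from the config seed instead).
#'
#' @param cohort an `asym_cohort`.
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"gifti"` for the maps.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "gifti")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "gifti") ".func.gii" else ".tsv"
  for (s in seq_along(cohort$contrast)) {
    write_vertex_map(cohort$contrast[[s]]$left,
                     file.path(dir, sprintf("sub%03d_left%s", s, ext)), format)
    write_vertex_map(cohort$contrast[[s]]$right,
                     file.path(dir, sprintf("sub%03d_right%s", s, ext)), format)
  }
  for (nm in names(cohort$masks)) {
    write_mask(cohort$masks[[nm]], file.path(dir, paste0("mask_", nm, ".txt")))
  }
  utils::write.table(
    data.frame(left = seq_along(cohort$corr) - 1L, right = cohort$corr - 1L),
    file.path(dir, "correspondence.tsv"),
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(activity_magnitude = cohort$truth$activity_magnitude,
         connectivity_magnitude = cohort$truth$connectivity_magnitude,
         dominance = cohort$truth$dominance,
         planted_region_0based = cohort$masks$planted - 1L,
         config = unclass(cohort$config)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.asym_cohort <- function(x, ...) {
  cfg <- x$config
  cat("asym_cohort: ", cfg$n_subjects, " subjects, V = ", cfg$V_brain,
      " per hemisphere, mask ", length(x$masks$ompfc), " vertices, planted ",
      length(x$masks$planted), " vertices",
      if (is.null(x$rest)) " (contrast maps only)" else
        paste0(", T = ", cfg$T_len), "\n", sep = "")
  invisible(x)
}
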
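test_that("symmetric cohort meshes are identical with identity pairing", {
  m <- make_symmetric_cohort_mesh(12L)
  expect_equal(m$left$n_vertices, 12L)
  expect_equal(nrow(m$left$triangles), 20L)
  expect_identical(m$left$triangles, m$right$triangles)
  expect_identical(m$left$vertex_coords, m$right$vertex_coords)
  expect_identical(as.integer(m$corr), 1:12)
  expect_error(make_symmetric_cohort_mesh(11L), "config error")
  expect_error(make_symmetric_cohort_mesh(100L), "config error")
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- tiny_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a$contrast, lapply, as.numeric),
                   lapply(b$contrast, lapply, as.numeric))
  expect_identical(a$rest, b$rest)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(tiny_config(rng_seed = 43L))
  expect_false(identical(a$truth$activity_magnitude,
                         c2$truth$activity_magnitude))
})

test_that("planted region and networks are contiguous, nested and disjoint", {
  co <- simulate_cohort(tiny_config(), with_timeseries = FALSE)
  expect_true(all(co$masks$planted %in% co$masks$ompfc))
  expect_length(intersect(co$masks$dmn, co$masks$ompfc), 0)
  expect_length(intersect(co$masks$exn, co$masks$ompfc), 0)
  expect_length(intersect(co$masks$dmn, co$masks$exn), 0)
  # contiguity: the planted region is one connected component of itself
  comps <- oracle_components(replace(rep(1, co$config$V_brain), -co$masks$planted, NA),
                             co$masks$planted, co$adjacency, 0)
  expect_length(comps, 1)
})

test_that("noise-free construction plants the exact signed difference", {
  cfg <- tiny_config(rra_effect = 0, noise_sd = 0, latent_sd = 0)
  co <- simulate_cohort(cfg, with_timeseries = FALSE)
  for (p in co$contrast) {
    expect_identical(as.numeric(p$left), as.numeric(p$right))
  }

  cfg2 <- tiny_config(rra_effect = 1.5, noise_sd = 0, latent_sd = 0)
  co2 <- simulate_cohort(cfg2, with_timeseries = FALSE)
  am <- rra_map(co2$contrast[[1]]$left, co2$contrast[[1]]$right,
                co2$corr, co2$masks$ompfc)
  expect_equal(unique(am$signed[co2$masks$planted]), 1.5)
  outside <- setdiff(co2$masks$ompfc, co2$masks$planted)
  expect_true(all(am$signed[outside] == 0))
})

test_that("mean signed asymmetry matches the configured effect under noise", {
  cfg <- tiny_config(n_subjects = 200L, V_brain = 42L, V_mask = 20L,
                     planted_size = 5L, network_size = 5L,
                     rra_effect = 1.5, noise_sd = 1, smooth_rounds = 0L,
                     rng_seed = 7L)
  co <- simulate_cohort(cfg, with_timeseries = FALSE)
  coeffs <- vapply(co$contrast, function(p) {
    am <- rra_map(p$left, p$right, co$corr, co$masks$ompfc)
    extract_region_coefficient(am, co$masks$planted, "signed")
  }, numeric(1))
  sem <- sd(coeffs) / sqrt(length(coeffs))
  expect_lt(abs(mean(coeffs) - 1.5), 3 * sem)
})

test_that("ground-truth magnitudes correlate at the configured target", {
  cfg <- tiny_config(n_subjects = 4000L, target_rra_fca_corr = 0.6,
                     rng_seed = 5L)
  set.seed(cfg$rng_seed)
  tr <- asymmap:::draw_ground_truth(cfg)
  r <- cor(tr$activity_magnitude, tr$connectivity_magnitude)
  expect_lt(abs(r - 0.6), 0.05)
})

test_that("sample connectivity matches the closed-form latent-model value", {
  cfg <- tiny_config(n_subjects = 1L, V_brain = 42L, V_mask = 10L,
                     planted_size = 3L, network_size = 8L, T_len = 5000L,
                     fca_effect = 0.4, latent_sd = 0, rng_seed = 3L)
  co <- simulate_cohort(cfg)
  ld <- subject_loadings(co, 1)
  seed_v <- co$masks$planted[1]   # right-hemisphere planted seed (dominant)
  dmn_v <- co$masks$dmn[1]
  a <- ld$right[seed_v, ]; b <- ld$right[dmn_v, ]
  pop_r <- sum(a * b) / sqrt((sum(a^2) + ld$noise_sd_right[seed_v]^2) *
                             (sum(b^2) + ld$noise_sd_right[dmn_v]^2))
  samp_r <- pearson_corr(co$rest[[1]]$right[, seed_v], co$rest[[1]]$right[, dmn_v])
  expect_lt(abs(samp_r - pop_r), 0.02)
  # the left (non-dominant) homologue has the weaker coupling
  a_l <- ld$left[seed_v, ]
  expect_lt(sum(a_l * b), sum(a * b))
})

test_that("sample FCA converges to the closed-form population FCA", {
  # even with identical loadings the population FCA is not exactly zero:
  # the whole-brain target set includes the seed pair itself, and a seed
  # correlates 1 with its own series but < 1 with its homologue, leaving a
  # 'self-column' floor of about 2 * (1 - rho_homotopic) / m per seed
  cfg <- tiny_config(n_subjects = 1L, V_brain = 42L, V_mask = 10L,
                     planted_size = 3L, network_size = 8L, T_len = 5000L,
                     fca_effect = 0, latent_sd = 0, rng_seed = 4L)
  co <- simulate_cohort(cfg)
  ld <- subject_loadings(co, 1)
  V <- cfg$V_brain
  load_wb <- rbind(ld$left, ld$right)
  nsd_wb <- c(ld$noise_sd_left, ld$noise_sd_right)
  pop_cor <- function(u, v) {
    num <- sum(load_wb[u, ] * load_wb[v, ]) + (u == v) * nsd_wb[u]^2
    num / sqrt((sum(load_wb[u, ]^2) + nsd_wb[u]^2) *
               (sum(load_wb[v, ]^2) + nsd_wb[v]^2))
  }
  pop_fca <- vapply(co$masks$ompfc, function(s) {
    mean(vapply(seq_len(2 * V), function(j)
      abs(pop_cor(s, j) - pop_cor(V + s, j)), numeric(1)))
  }, numeric(1))
  fca <- fca_from_series(co$rest[[1]]$left, co$rest[[1]]$right,
                         co$masks$ompfc, co$corr)
  # sampling noise adds a small positive bias to |.|; allow it above the floor
  expect_lt(abs(mean(fca[co$masks$ompfc]) - mean(pop_fca)), 0.03)
  expect_gt(mean(fca[co$masks$ompfc]), mean(pop_fca) / 2)
})

test_that("hemisphere relabeling flips signed and preserves unsigned maps", {
  co <- simulate_cohort(tiny_config(), with_timeseries = FALSE)
  sw <- swap_hemispheres(co)
  mask <- co$masks$ompfc
  for (s in seq_along(co$contrast)) {
    a <- rra_map(co$contrast[[s]]$left, co$contrast[[s]]$right, co$corr, mask)
    b <- rra_map(sw$contrast[[s]]$left, sw$contrast[[s]]$right, sw$corr, mask)
    expect_identical(b$signed[mask], -a$signed[mask])
    expect_identical(b$unsigned[mask], a$unsigned[mask])
  }
  expect_identical(sw$truth$dominance, -co$truth$dominance)
})

test_that("cohorts round-trip through the on-disk export", {
  co <- simulate_cohort(tiny_config(n_subjects = 2L), with_timeseries = FALSE)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_vertex_map(file.path(dir, "sub001_left.tsv"), "tsv", "left")
  expect_identical(as.numeric(back), as.numeric(co$contrast[[1]]$left))
  expect_identical(read_mask(file.path(dir, "mask_planted.txt")),
                   co$masks$planted)
  corr <- read_correspondence(file.path(dir, "correspondence.tsv"),
                              co$config$V_brain)
  expect_identical(as.integer(corr), as.integer(co$corr))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$activity_magnitude, co$truth$activity_magnitude)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_subjects = 0), "config error")
  expect_error(simulation_config(V_brain = 8), "config error")
  expect_error(simulation_config(V_brain = 100), "icosphere")
  expect_error(simulation_config(planted_size = 200, V_mask = 150), "within the mask")
  expect_error(simulation_config(target_rra_fca_corr = 1.2), "config error")
  expect_error(simulation_config(T_len = 10), "config error")
})
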
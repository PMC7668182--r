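make_rest <- function(n_subj, T_len, V, f) {
  lapply(seq_len(n_subj), function(s) f(s))
}

test_that("profile cells are mean seed-network pair correlations", {
  set.seed(17)
  V <- 10; T_len <- 40
  rest <- lapply(1:3, function(s)
    list(left = matrix(rnorm(T_len * V), T_len, V),
         right = matrix(rnorm(T_len * V), T_len, V)))
  networks <- list(dmn_left = 3L, dmn_right = 4L, exn_left = 5L, exn_right = 6L)
  tab <- build_profile_table(rest, fa_left = 1L, fa_right = 2L, networks)
  expect_equal(nrow(tab), 3 * 8)
  # single-vertex masks: the cell is the single pair's correlation
  row <- tab[tab$subject == 2 & tab$seed_hemisphere == "L" &
               tab$network == "DMN" & tab$network_hemisphere == "R", ]
  expect_equal(row$mean_connectivity,
               pearson_corr(rest[[2]]$left[, 1], rest[[2]]$right[, 4]))
  row2 <- tab[tab$subject == 3 & tab$seed_hemisphere == "R" &
                tab$network == "ExN" & tab$network_hemisphere == "L", ]
  expect_equal(row2$mean_connectivity,
               pearson_corr(rest[[3]]$right[, 2], rest[[3]]$left[, 5]))
  expect_error(build_profile_table(rest, 1L, 2L,
                                   list(dmn_left = 1L, dmn_right = 4L,
                                        exn_left = 5L, exn_right = 6L)),
               "disjoint")
})

test_that("seeds coupled only to the DMN latent show DMN cells far above ExN", {
  cfg <- tiny_config(n_subjects = 6L, T_len = 200L, fca_effect = 0,
                     rng_seed = 18L)
  co <- simulate_cohort(cfg)
  # seed on pure-DMN vertices; keep networks disjoint from the seed
  seed <- co$masks$dmn[1:4]
  networks <- list(dmn_left = setdiff(co$masks$dmn, seed),
                   dmn_right = setdiff(co$masks$dmn, seed),
                   exn_left = co$masks$exn, exn_right = co$masks$exn)
  tab <- build_profile_table(co$rest, seed, seed, networks)
  agg <- tapply(tab$mean_connectivity, tab$network, mean)
  expect_gt(agg[["DMN"]], 0.3)
  expect_lt(abs(agg[["ExN"]]), 0.1)
  # symmetric cohort: L and R seed rows agree within sampling error
  lr <- tapply(tab$mean_connectivity, tab$seed_hemisphere, mean)
  expect_lt(abs(lr[["L"]] - lr[["R"]]), 0.06)
})

test_that("an all-constant table yields zero F and p = 1 everywhere", {
  tab <- expand.grid(subject = 1:4, seed_hemisphere = c("L", "R"),
                     network = c("DMN", "ExN"), network_hemisphere = c("L", "R"),
                     stringsAsFactors = FALSE)
  tab$mean_connectivity <- 0.2
  res <- three_way_anova(tab)
  expect_true(all(res$effects$F == 0))
  expect_true(all(res$effects$p == 1))
})

test_that("a pure seed-by-network pattern loads only that interaction", {
  tab <- expand.grid(subject = 1:5, seed_hemisphere = c("L", "R"),
                     network = c("DMN", "ExN"), network_hemisphere = c("L", "R"),
                     stringsAsFactors = FALSE)
  d <- 0.3
  tab$mean_connectivity <- d * ifelse(tab$seed_hemisphere == "R", 1, -1) *
    ifelse(tab$network == "ExN", 1, -1)
  res <- three_way_anova(tab)
  ss <- res$effects$sum_sq
  names(ss) <- res$effects$effect
  expect_gt(ss[["seed_hemisphere:network"]], 0)
  others <- ss[setdiff(names(ss), "seed_hemisphere:network")]
  expect_true(all(others < 1e-20))
  expect_equal(res$residual_ss, 0)
})

test_that("sums of squares match the orthogonal-projection oracle", {
  set.seed(19)
  for (rep in 1:5) {
    n_subj <- sample(3:8, 1)
    tab <- expand.grid(subject = seq_len(n_subj), seed_hemisphere = c("L", "R"),
                       network = c("DMN", "ExN"),
                       network_hemisphere = c("L", "R"),
                       stringsAsFactors = FALSE)
    tab$mean_connectivity <- rnorm(nrow(tab))
    res <- three_way_anova(tab)
    want <- oracle_anova_ss(tab)
    got <- res$effects$sum_sq
    names(got) <- res$effects$effect
    expect_equal(got[["seed_hemisphere"]], want[["seed"]], tolerance = 1e-10)
    expect_equal(got[["seed_hemisphere:network"]], want[["seed_network"]],
                 tolerance = 1e-10)
    expect_equal(res$residual_ss, want[["residual"]], tolerance = 1e-10)
    total <- sum((tab$mean_connectivity - mean(tab$mean_connectivity))^2)
    expect_equal(sum(got) + res$residual_ss, total, tolerance = 1e-8)
  }
})

test_that("the design degrees of freedom follow the observation count", {
  set.seed(20)
  tab <- expand.grid(subject = 1:57, seed_hemisphere = c("L", "R"),
                     network = c("DMN", "ExN"), network_hemisphere = c("L", "R"),
                     stringsAsFactors = FALSE)
  tab$mean_connectivity <- rnorm(nrow(tab))
  res <- three_way_anova(tab)
  expect_equal(res$n_obs, 456L)
  inter <- res$effects[res$effects$effect == "seed_hemisphere:network", ]
  expect_equal(inter$df_num, 1L)
  expect_equal(inter$df_den, 456L - 8L)
})

test_that("incomplete designs are rejected with the missing cells listed", {
  tab <- expand.grid(subject = 1:3, seed_hemisphere = c("L", "R"),
                     network = c("DMN", "ExN"), network_hemisphere = c("L", "R"),
                     stringsAsFactors = FALSE)
  tab$mean_connectivity <- rnorm(nrow(tab))
  tab <- tab[!(tab$seed_hemisphere == "L" & tab$network == "DMN" &
                 tab$network_hemisphere == "R"), ]
  expect_error(three_way_anova(tab), "missing cell")
})

test_that("post hoc contrasts are paired, adjusted, and null on identical cells", {
  tab <- expand.grid(subject = 1:6, seed_hemisphere = c("L", "R"),
                     network = c("DMN", "ExN"), network_hemisphere = c("L", "R"),
                     stringsAsFactors = FALSE)
  tab$mean_connectivity <- 0.1
  res <- posthoc_contrasts(tab)
  expect_equal(res$estimate, c(0, 0))
  expect_equal(res$p_adj, c(1, 1))

  set.seed(21)
  tab$mean_connectivity <- rnorm(nrow(tab))
  res2 <- posthoc_contrasts(tab)
  expect_true(all(res2$p_adj >= res2$p))
  # oracle: paired t on per-subject R-L means within DMN
  sub <- tab[tab$network == "DMN", ]
  d <- tapply(sub$mean_connectivity[sub$seed_hemisphere == "R"],
              sub$subject[sub$seed_hemisphere == "R"], mean) -
    tapply(sub$mean_connectivity[sub$seed_hemisphere == "L"],
           sub$subject[sub$seed_hemisphere == "L"], mean)
  expect_equal(res2$t[res2$contrast == "R_vs_L_seed_DMN"], oracle_t(d),
               tolerance = 1e-10)
})
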
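test_that("pearson_corr has the defining identities and closed-form value", {
  set.seed(1)
  x <- rnorm(20)
  expect_equal(pearson_corr(x, x), 1)
  expect_equal(pearson_corr(x, -x), -1)
  r <- pearson_corr(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_equal(r, 0.9820, tolerance = 1e-4)
  y <- rnorm(20)
  expect_equal(pearson_corr(3 * x + 2, y), pearson_corr(x, y))
  expect_equal(pearson_corr(-3 * x + 2, y), -pearson_corr(x, y))
  expect_error(pearson_corr(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_corr(1:3, 1:4), "equal length")
})

test_that("seed profiles follow seed order and match looped correlations", {
  set.seed(2)
  ts <- matrix(rnorm(200), 20, 10)
  prof <- seed_profile(ts, seeds = c(7L, 3L))
  expect_equal(dim(prof$matrix), c(2L, 10L))
  expect_equal(prof$matrix[1, 7], 1)     # self-correlation
  expect_equal(prof$matrix[2, 3], 1)
  for (j in 1:10) {
    expect_equal(prof$matrix[1, j], pearson_corr(ts[, 7], ts[, j]))
    expect_equal(prof$matrix[2, j], pearson_corr(ts[, 3], ts[, j]))
  }
  one <- seed_profile(ts[, 4, drop = FALSE], seeds = 1L)
  expect_equal(one$matrix, matrix(1, 1, 1), ignore_attr = TRUE)
})

test_that("constant target series are flagged undefined and excluded pairwise", {
  set.seed(3)
  ts <- matrix(rnorm(100), 20, 5)
  ts[, 4] <- 7
  prof <- seed_profile(ts, seeds = 1:2)
  expect_equal(prof$undefined, 4L)
  expect_true(all(is.na(prof$matrix[, 4])))
  fca <- fca_map(prof, seed_profile(ts[, c(2, 1, 3, 4, 5)], seeds = 1:2))
  expect_true(all(is.finite(fca$values)))  # denominator adjusted, not NA
  expect_error(seed_profile(ts, seeds = 4L), "constant seed")
})

test_that("FCA is the mean absolute profile difference with its symmetries", {
  p <- function(m) structure(list(matrix = m, seeds = seq_len(nrow(m)),
                                  m = ncol(m), undefined = integer(0)),
                             class = "connectivity_profile")
  L <- matrix(0.5, 1, 4); R <- matrix(0.1, 1, 4)
  expect_equal(fca_map(p(L), p(R))$values, 0.4)
  expect_equal(fca_map(p(L), p(L))$values, 0)

  set.seed(4)
  A <- matrix(runif(50 * 30, -1, 1), 50); B <- matrix(runif(50 * 30, -1, 1), 50)
  M <- matrix(runif(50 * 30, -1, 1), 50)
  f_ab <- fca_map(p(A), p(B))$values
  expect_equal(f_ab, oracle_fca(A, B))
  expect_identical(f_ab, fca_map(p(B), p(A))$values)            # symmetry
  expect_true(all(f_ab >= 0))
  perm <- sample(30)
  expect_equal(fca_map(p(A[, perm]), p(B[, perm]))$values, f_ab) # target perm
  f_am <- fca_map(p(A), p(M))$values; f_mb <- fca_map(p(M), p(B))$values
  expect_true(all(f_ab <= f_am + f_mb + 1e-12))                  # triangle bound
  expect_error(fca_map(p(A), p(B[, 1:10])), "dimension error")
})

test_that("mean connectivity strength is the per-seed row mean", {
  p <- structure(list(matrix = rbind(rep(0.3, 4), c(1, -1, 1, -1)),
                      seeds = 1:2, m = 4, undefined = integer(0)),
                 class = "connectivity_profile")
  expect_equal(mean_connectivity_strength(p), c(0.3, 0))
  set.seed(5)
  m <- matrix(rnorm(40), 5)
  p2 <- structure(list(matrix = m, seeds = 1:5, m = 8, undefined = integer(0)),
                  class = "connectivity_profile")
  expect_equal(mean_connectivity_strength(p2), apply(m, 1, function(r) sum(r) / 8))
})

test_that("single-subject MIGP spans the top principal subspace", {
  set.seed(6)
  X <- matrix(rnorm(40 * 100), 40, 100) %*% diag(runif(100, 0.5, 2))
  g <- migp(list(X), out_dim = 5, internal_dim = 40)
  Xc <- sweep(X, 2, colMeans(X))
  top5 <- t(svd(Xc)$v[, 1:5])
  expect_lt(max(principal_angles(g$matrix, top5)), 1e-6)
})

test_that("lossless MIGP reproduces the full-concatenation subspace", {
  set.seed(7)
  B <- qr.Q(qr(matrix(rnorm(200 * 10), 200, 10)))
  series <- lapply(1:4, function(s) {
    matrix(rnorm(30 * 10), 30, 10) %*% diag(sqrt(10:1)) %*% t(B) +
      matrix(rnorm(30 * 200, sd = 0.1), 30, 200)
  })
  g <- migp(series, out_dim = 8, internal_dim = 120)  # m_int >= sum T_i
  conc <- do.call(rbind, lapply(series, function(X) sweep(X, 2, colMeans(X))))
  top8 <- t(svd(conc)$v[, 1:8])
  expect_lt(max(principal_angles(g$matrix, top8)), 1e-6)
  expect_error(migp(list(series[[1]], series[[2]][, 1:100]), out_dim = 4),
               "dimension error")
  expect_error(migp(series, out_dim = 10, internal_dim = 5), "internal_dim")
})

test_that("seed-threshold network definition recovers planted networks", {
  cfg <- tiny_config(n_subjects = 4L, T_len = 200L, rng_seed = 11L)
  co <- simulate_cohort(cfg)
  wb <- lapply(co$rest, function(p) cbind(p$left, p$right))
  g <- migp(wb, out_dim = 100, internal_dim = 200)
  V <- cfg$V_brain
  seed <- co$masks$dmn[1:4]  # left-hemisphere DMN seed vertices
  net <- network_from_seed(g, seed, threshold_r = 0.3)
  dmn_both <- c(co$masks$dmn, V + co$masks$dmn)
  expect_gt(length(intersect(net, dmn_both)) / length(setdiff(dmn_both, seed)), 0.9)
  pure_noise <- setdiff(seq_len(2 * V),
                        c(dmn_both, co$masks$exn, V + co$masks$exn,
                          co$masks$ompfc, V + co$masks$ompfc))
  expect_length(intersect(net, pure_noise), 0)
  expect_length(intersect(net, seed), 0)  # seed excluded
  expect_error(network_from_seed(g, seed, threshold_r = 1.2), "threshold_r")
})
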
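test_that("empirical semivariogram matches hand evaluation and an O(n^2) oracle", {
  # two points 0.03 km apart, values 0 and 1: one pair in bin 1, gamma 0.5
  emp <- empirical_semivariogram(cbind(c(0, 0.03), c(0, 0)), c(0, 1),
                                 lag_size = 0.04, n_lags = 12)
  expect_equal(emp$npairs[1], 1)
  expect_equal(emp$gamma[1], 0.5)
  expect_true(all(emp$npairs[-1] == 0))

  # constant values: zero semivariance in every occupied lag
  set.seed(4)
  coords <- cbind(runif(25, 0, 0.4), runif(25, 0, 0.4))
  flat <- empirical_semivariogram(coords, rep(3.3, 25), 0.04, 12)
  expect_true(all(flat$gamma[flat$npairs > 0] == 0))

  # 40-point fixture vs brute-force double loop
  set.seed(8)
  coords <- cbind(runif(40, 0, 0.5), runif(40, 0, 0.5))
  z <- rnorm(40)
  ours <- empirical_semivariogram(coords, z, 0.04, 12)
  brute <- brute_semivariogram(coords, z, lag_size = 0.04, n_lags = 12)
  expect_equal(ours$npairs, brute$npairs)
  expect_equal(ours$gamma, brute$gamma, tolerance = 1e-12)
  expect_equal(ours$dist, brute$dist, tolerance = 1e-12)

  expect_error(empirical_semivariogram(cbind(0, 0), 1, 0.04, 12),
               "at least 2")
})

test_that("cross-semivariogram is bilinear and matches the oracle", {
  set.seed(12)
  coords <- cbind(runif(30, 0, 0.5), runif(30, 0, 0.5))
  a <- rnorm(30)
  b <- rnorm(30)
  direct <- empirical_semivariogram(coords, a, 0.04, 12)
  same <- empirical_cross_semivariogram(coords, a, a, 0.04, 12)
  expect_equal(same$gamma, direct$gamma, tolerance = 1e-12)
  neg <- empirical_cross_semivariogram(coords, a, -a, 0.04, 12)
  expect_equal(neg$gamma, -direct$gamma, tolerance = 1e-12)

  ours <- empirical_cross_semivariogram(coords, a, b, 0.04, 12)
  brute <- brute_semivariogram(coords, a, b, lag_size = 0.04, n_lags = 12)
  expect_equal(ours$gamma, brute$gamma, tolerance = 1e-12)
})

test_that("anisotropic binning stretches the minor axis before binning", {
  # two pairs at the same Euclidean distance, along and across the major
  # axis: the across pair lands in a farther bin under factor 2
  coords <- cbind(c(0, 0.1, 0, 0), c(0, 0, 0.1, 0.5))
  z <- c(0, 1, 1, 5)
  emp <- empirical_semivariogram(coords[1:3, ], z[1:3], lag_size = 0.05,
                                 n_lags = 12, aniso_factor = 2,
                                 aniso_angle = 0)
  # pair (1,2): along x, h_eff = 0.1 -> bin 3; pair (1,3): along y,
  # h_eff = 0.2 -> bin 5; pair (2,3): sqrt(0.1^2 + 0.04) -> bin 5
  expect_equal(emp$npairs[3], 1)
  expect_equal(emp$npairs[5], 2)
})

test_that("variogram fitting recovers exact parameters and degenerate cases", {
  truth <- variogram_model("spherical", nugget = 0.1, psill = 0.4,
                           range = 0.3)
  h <- (1:12 - 0.5) * 0.04
  emp <- structure(
    data.frame(lag = 1:12, dist = h, gamma = vgm_gamma(truth, h),
               npairs = rep(50L, 12)),
    lag_size = 0.04, n_lags = 12, kind = "direct",
    class = c("empirical_variogram", "data.frame")
  )
  fit <- fit_variogram_model(emp, "spherical")
  expect_equal(fit$nugget, 0.1, tolerance = 1e-6)
  expect_equal(fit$psill, 0.4, tolerance = 1e-6)
  expect_equal(fit$range, 0.3, tolerance = 1e-6)

  emp0 <- structure(
    data.frame(lag = 1:12, dist = h, gamma = rep(0, 12),
               npairs = rep(10L, 12)),
    lag_size = 0.04, n_lags = 12, kind = "direct",
    class = c("empirical_variogram", "data.frame")
  )
  fit0 <- fit_variogram_model(emp0, "spherical")
  expect_equal(fit0$nugget, 0)
  expect_equal(fit0$psill, 0)

  emp2 <- emp[1:2, ]
  attr(emp2, "lag_size") <- 0.04
  expect_error(fit_variogram_model(emp2), "3 occupied lags")
})

test_that("LMC fitting zeroes absent cross-structure and always yields PSD matrices", {
  h <- (1:12 - 0.5) * 0.04
  mkemp <- function(gamma, np = 40L) {
    structure(
      data.frame(lag = 1:12, dist = h, gamma = gamma,
                 npairs = rep(np, 12)),
      lag_size = 0.04, n_lags = 12, kind = "direct",
      class = c("empirical_variogram", "data.frame")
    )
  }
  m <- variogram_model("spherical", 0.05, 0.3, 0.25)
  emps <- list(
    a = mkemp(vgm_gamma(m, h)),
    b = mkemp(vgm_gamma(m, h)),
    `a:b` = mkemp(rep(0, 12))
  )
  lmc <- fit_lmc(emps, c("a", "b"), "spherical")
  expect_equal(lmc$B0["a", "b"], 0, tolerance = 1e-8)
  expect_equal(lmc$B1["a", "b"], 0, tolerance = 1e-8)

  # random empirical variograms: coefficient matrices always PSD
  for (s in 1:100) {
    set.seed(s)
    emps_r <- list(
      a = mkemp(cumsum(abs(rnorm(12, 0.05, 0.02)))),
      b = mkemp(cumsum(abs(rnorm(12, 0.05, 0.02)))),
      `a:b` = mkemp(rnorm(12, 0, 0.2))
    )
    lmc_r <- fit_lmc(emps_r, c("a", "b"))
    expect_gte(min(eigen(lmc_r$B0, symmetric = TRUE)$values), -1e-12)
    expect_gte(min(eigen(lmc_r$B1, symmetric = TRUE)$values), -1e-12)
  }

  expect_error(fit_lmc(list(), character(0)), "no variograms")
})

test_that("co-kriging interpolates exactly at data under zero nugget and honors constraints", {
  B0 <- matrix(0, 2, 2, dimnames = list(c("p", "s"), c("p", "s")))
  B1 <- matrix(c(0.4, 0.15, 0.15, 0.3), 2, 2,
               dimnames = dimnames(B0))
  model <- make_lmc(c("p", "s"), B0, B1, range = 2)
  set.seed(3)
  coords <- cbind(runif(12, 0, 3), runif(12, 0, 3))
  data <- list(
    p = list(coords = coords, values = rbinom(12, 1, 0.4)),
    s = list(coords = coords, values = rnorm(12))
  )
  for (i in c(1, 5, 9)) {
    out <- cokrige_point(model, data, coords[i, ])
    expect_equal(out$prediction, data$p$values[i], tolerance = 1e-8)
  }
  # weight constraints at an off-data target
  out <- cokrige_point(model, data, c(1.234, 2.345))
  expect_equal(sum(out$weights[out$var_of == 1]), 1, tolerance = 1e-12)
  expect_equal(sum(out$weights[out$var_of == 2]), 0, tolerance = 1e-12)
  expect_gte(out$variance, 0)
})

test_that("co-kriging equals a dense hand-assembled solve on small systems", {
  B0 <- matrix(c(0.05, 0.01, 0.01, 0.04), 2, 2,
               dimnames = list(c("p", "s"), c("p", "s")))
  B1 <- matrix(c(0.5, 0.2, 0.2, 0.45), 2, 2, dimnames = dimnames(B0))
  model <- make_lmc(c("p", "s"), B0, B1, range = 1.5)
  set.seed(21)
  cp <- cbind(runif(4), runif(4))
  cs <- cbind(runif(5), runif(5))
  data <- list(p = list(coords = cp, values = rnorm(4)),
               s = list(coords = cs, values = rnorm(5)))
  target <- c(0.4, 0.6)
  ours <- cokrige_point(model, data, target)
  brute <- brute_cokrige(model, data, target)
  expect_equal(ours$prediction, brute$prediction, tolerance = 1e-10)
  expect_equal(unname(ours$weights), brute$weights, tolerance = 1e-10)
  expect_equal(sum(brute$weights[brute$var_of == 1]), 1,
               tolerance = 1e-12)
  expect_equal(sum(brute$weights[brute$var_of == 2]), 0,
               tolerance = 1e-12)
})

test_that("a secondary with zero cross-structure reduces to ordinary kriging", {
  B0 <- matrix(0, 2, 2, dimnames = list(c("p", "s"), c("p", "s")))
  B1 <- matrix(c(0.4, 0, 0, 0.3), 2, 2, dimnames = dimnames(B0))
  co <- make_lmc(c("p", "s"), B0, B1, range = 2)
  B0p <- matrix(0, 1, 1, dimnames = list("p", "p"))
  B1p <- matrix(0.4, 1, 1, dimnames = list("p", "p"))
  ok <- make_lmc("p", B0p, B1p, range = 2)
  set.seed(5)
  coords <- cbind(runif(10, 0, 3), runif(10, 0, 3))
  pvals <- rnorm(10)
  data2 <- list(p = list(coords = coords, values = pvals),
                s = list(coords = coords, values = rnorm(10)))
  data1 <- list(p = list(coords = coords, values = pvals))
  tg <- c(1.1, 0.7)
  expect_equal(cokrige_point(co, data2, tg)$prediction,
               cokrige_point(ok, data1, tg)$prediction, tolerance = 1e-9)

  # degenerate case: a single primary datum predicts itself everywhere
  d1 <- list(p = list(coords = cbind(0.5, 0.5), values = 0.8))
  expect_equal(cokrige_point(ok, d1, c(2, 2))$prediction, 0.8)
})

test_that("predictions are invariant to translation and rotation when isotropic", {
  B0 <- matrix(c(0.02, 0, 0, 0.02), 2, 2,
               dimnames = list(c("p", "s"), c("p", "s")))
  B1 <- matrix(c(0.5, 0.2, 0.2, 0.45), 2, 2, dimnames = dimnames(B0))
  model <- make_lmc(c("p", "s"), B0, B1, range = 1.5)
  set.seed(9)
  coords <- cbind(runif(15, 0, 2), runif(15, 0, 2))
  data <- function(xy) list(p = list(coords = xy, values = rnorm(15)),
                            s = list(coords = xy, values = rnorm(15)))
  set.seed(10)
  d0 <- data(coords)
  tg <- c(0.9, 1.1)
  base <- cokrige_point(model, d0, tg)$prediction
  # translate
  shift <- function(xy) cbind(xy[, 1] + 5, xy[, 2] - 3)
  d_t <- d0
  d_t$p$coords <- shift(d0$p$coords)
  d_t$s$coords <- shift(d0$s$coords)
  expect_equal(cokrige_point(model, d_t, c(tg[1] + 5, tg[2] - 3))$prediction,
               base, tolerance = 1e-10)
  # rotate by 37 degrees
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- function(xy) xy %*% R
  d_r <- d0
  d_r$p$coords <- rot(d0$p$coords)
  d_r$s$coords <- rot(d0$s$coords)
  expect_equal(cokrige_point(model, d_r, drop(tg %*% R))$prediction,
               base, tolerance = 1e-10)
})

test_that("surfaces honor the water mask, clamping, and cell extraction", {
  B0p <- matrix(0, 1, 1, dimnames = list("p", "p"))
  B1p <- matrix(0.4, 1, 1, dimnames = list("p", "p"))
  model <- make_lmc("p", B0p, B1p, range = 3)
  grid <- grid_spec(c(0, 2, 0, 2), cell = 0.5)

  # all-water mask with all-one data: surface identically 1
  set.seed(2)
  coords <- cbind(runif(8, 0, 2), runif(8, 0, 2))
  d1 <- list(p = list(coords = coords, values = rep(1, 8)))
  s1 <- predict_surface(model, d1, grid)
  expect_equal(as.numeric(s1$prob), rep(1, length(s1$prob)),
               tolerance = 1e-9)

  # masked cells are exactly 0 regardless of neighbors
  wb <- data.frame(id = c("A", "B"), x = c(0.25, 0.25), y = c(0.3, 0.4),
                   stringsAsFactors = FALSE)
  mask <- water_mask(grid, wb)
  expect_equal(sum(mask), 1)
  s2 <- predict_surface(model, d1, grid, mask)
  expect_equal(s2$prob[1, 1], 1, tolerance = 1e-9)
  expect_true(all(s2$prob[-1] == 0))

  # raw negative prediction is clamped to 0: a datum of -0.03 at a cell
  # centre predicts itself there under zero nugget, then clamps
  d_neg <- list(p = list(coords = rbind(c(0.25, 0.25), c(1.9, 1.9)),
                         values = c(-0.03, 1)))
  s3 <- predict_surface(model, d_neg, grid)
  expect_equal(s3$prob[1, 1], 0)

  # extraction returns the containing cell's value; co-resident
  # waterbodies share it
  probs <- extract_at_waterbodies(s2, wb)
  expect_equal(unname(probs), c(1, 1))
  outside <- data.frame(id = "Z", x = 5, y = 5, stringsAsFactors = FALSE)
  expect_error(extract_at_waterbodies(s2, outside), "outside")

  # indicator coding
  expect_equal(indicator(c(0, 1, 1, 0)), c(0, 1, 1, 0))
  expect_equal(sum(indicator(c(0, 2, 0.5))), 2)
})

test_that("variogram parameters are recovered from simulated Gaussian fields", {
  # exponential field, range 0.2 km, unit sill, n = 400; median recovered
  # range over 10 seeds within 25 % of truth
  ranges <- numeric(10)
  sills <- numeric(10)
  for (s in 1:10) {
    set.seed(300 + s)
    coords <- cbind(runif(400), runif(400))
    z <- simulate_gaussian_field(coords, "exponential", range = 0.2,
                                 sill = 1)
    emp <- empirical_semivariogram(coords, z, lag_size = 0.05,
                                   n_lags = 12)
    fit <- fit_variogram_model(emp, "exponential")
    ranges[s] <- fit$range
    sills[s] <- fit$nugget + fit$psill
  }
  expect_lt(abs(median(ranges) - 0.2) / 0.2, 0.25)
  expect_lt(abs(median(sills) - 1), 0.5)
})

test_that("LMC coefficients are recovered from a known coregionalization", {
  # two co-regionalized fields built from independent unit fields with a
  # known mixing matrix; n = 500, 5 seeds, 15 % tolerance on the median
  B1_true <- matrix(c(1, 0.6, 0.6, 0.8), 2, 2)
  A <- t(chol(B1_true))
  est <- array(NA_real_, c(5, 2, 2))
  for (s in 1:5) {
    set.seed(400 + s)
    coords <- cbind(runif(500), runif(500))
    u1 <- simulate_gaussian_field(coords, "spherical", range = 0.3,
                                  sill = 1)
    u2 <- simulate_gaussian_field(coords, "spherical", range = 0.3,
                                  sill = 1)
    za <- A[1, 1] * u1
    zb <- A[2, 1] * u1 + A[2, 2] * u2
    emps <- list(
      a = empirical_semivariogram(coords, za, 0.05, 12),
      b = empirical_semivariogram(coords, zb, 0.05, 12),
      `a:b` = empirical_cross_semivariogram(coords, za, zb, 0.05, 12)
    )
    lmc <- fit_lmc(emps, c("a", "b"), "spherical", range = 0.3)
    est[s, , ] <- lmc$B0 + lmc$B1
  }
  med <- apply(est, c(2, 3), median)
  expect_equal(med, B1_true, tolerance = 0.15)
})
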
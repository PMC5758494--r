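# Probability (indicator) co-kriging engine ------------------------------
#
# Empirical direct and cross semivariograms (Matheron estimator), weighted
# least-squares variogram fitting, a linear model of coregionalization
# (shared ranges, PSD-projected coefficient matrices), and ordinary
# co-kriging with one unbiasedness constraint per variable.  Predictions of
# a 0/1 presence indicator, clamped to [0, 1], are read as introduction
# probabilities.

# Normalised variogram shapes: g(0) = 0, sill 1, range parameter 1.
variogram_shape <- function(hn, family) {
  hn <- pmax(hn, 0)
  switch(family,
    spherical = ifelse(hn >= 1, 1, 1.5 * hn - 0.5 * hn^3),
    exponential = 1 - exp(-hn),
    gaussian = 1 - exp(-hn^2),
    stop("unknown variogram family: ", family, call. = FALSE)
  )
}

#' Construct a variogram model
#'
#' Nugget-plus-structure model
#' `gamma(h) = nugget * 1(h > 0) + psill * g(h / range)` with `g` the
#' normalised spherical, exponential (e-folding range), or gaussian shape.
#' Geometric anisotropy stretches distances: separations are rotated by
#' `aniso_angle` (degrees, direction of maximum continuity) and the minor
#' axis is inflated by `aniso_factor >= 1` before `gamma` is evaluated, so
#' `range` is the range along the major axis.
#'
#' @param family `"spherical"`, `"exponential"`, or `"gaussian"`.
#' @param nugget Nugget variance (>= 0).
#' @param psill Partial sill (>= 0 for a direct variogram).
#' @param range Range parameter (km, > 0).
#' @param aniso_factor Anisotropy ratio (>= 1; 1 = isotropic).
#' @param aniso_angle Anisotropy angle in degrees.
#' @return Object of class `variogram_model`.
#' @export
variogram_model <- function(family = "spherical", nugget = 0, psill = 1,
                            range = 1, aniso_factor = 1, aniso_angle = 0) {
  stopifnot(nugget >= 0, range > 0, aniso_factor >= 1)
  structure(
    list(family = family, nugget = nugget, psill = psill, range = range,
         aniso_factor = aniso_factor, aniso_angle = aniso_angle),
    class = "variogram_model"
  )
}

#' Evaluate a variogram model at separation distances
#'
#' @param model A [variogram_model()].
#' @param h Isotropic (or anisotropy-corrected) separation distances.
#' @return `gamma(h)`; `gamma(0) = 0` exactly.
#' @export
vgm_gamma <- function(model, h) {
  g <- model$nugget * as.numeric(h > 0) +
    model$psill * variogram_shape(h / model$range, model$family)
  g
}

# Effective (anisotropy-corrected) separation lengths of displacement
# vectors (dx, dy).
aniso_distance <- function(dx, dy, aniso_factor = 1, aniso_angle = 0) {
  if (aniso_factor == 1) return(sqrt(dx^2 + dy^2))
  th <- aniso_angle * pi / 180
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  sqrt(u^2 + (aniso_factor * v)^2)
}

empirical_variogram_core <- function(coords, prod_fun, lag_size, n_lags,
                                     aniso_factor, aniso_angle) {
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (lag_size <= 0) stop("lag_size must be positive", call. = FALSE)
  low <- which(lower.tri(matrix(0, n, n)))
  dx <- outer(coords[, 1], coords[, 1], "-")[low]
  dy <- outer(coords[, 2], coords[, 2], "-")[low]
  h <- aniso_distance(dx, dy, aniso_factor, aniso_angle)
  cross <- prod_fun(low)
  bin <- floor(h / lag_size) + 1L
  keep <- bin >= 1L & bin <= n_lags
  bin <- bin[keep]
  h <- h[keep]
  cross <- cross[keep]
  npairs <- tabulate(bin, nbins = n_lags)
  ssum <- rep(0, n_lags)
  dsum <- rep(0, n_lags)
  if (length(bin) > 0) {
    ssum[seq_len(max(bin))] <- tapply_sum(cross, bin, n_lags)
    dsum[seq_len(max(bin))] <- tapply_sum(h, bin, n_lags)
  }
  gamma <- ifelse(npairs > 0, ssum / (2 * npairs), NA_real_)
  data.frame(
    lag = seq_len(n_lags),
    dist = ifelse(npairs > 0, dsum / npairs, NA_real_),
    gamma = gamma,
    npairs = npairs
  )
}

tapply_sum <- function(x, g, nbins) {
  out <- rep(0, max(g))
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all point pairs by separation into `[k * lag_size, (k + 1) *
#' lag_size)` intervals and computes `gamma(h) = sum (z_i - z_j)^2 / (2
#' N(h))` per bin. Anisotropic binning applies the elliptical distance
#' correction before binning.
#'
#' @param coords Two-column coordinate matrix (km).
#' @param values Numeric values at the coordinates.
#' @param lag_size Lag width in km (default 0.04).
#' @param n_lags Number of lags (default 12).
#' @param aniso_factor,aniso_angle Geometric anisotropy of the binning.
#' @return Object of class `empirical_variogram`: data frame with columns
#'   `lag`, `dist` (mean separation), `gamma`, `npairs`, plus attributes
#'   `lag_size`, `n_lags`, `kind`, `vars`.
#' @export
empirical_semivariogram <- function(coords, values, lag_size = 0.04,
                                    n_lags = 12, aniso_factor = 1,
                                    aniso_angle = 0) {
  stopifnot(length(values) == nrow(coords))
  out <- empirical_variogram_core(
    coords,
    function(low) (outer(values, values, "-")[low])^2,
    lag_size, n_lags, aniso_factor, aniso_angle
  )
  structure(out, lag_size = lag_size, n_lags = n_lags, kind = "direct",
            vars = NULL, class = c("empirical_variogram", "data.frame"))
}

#' Empirical cross-semivariogram
#'
#' The product-moment analogue of the Matheron estimator for two variables
#' observed at common locations:
#' `gamma_ab(h) = sum (a_i - a_j)(b_i - b_j) / (2 N(h))`.
#'
#' @inheritParams empirical_semivariogram
#' @param values_a,values_b The two co-located variables.
#' @return An `empirical_variogram` with `kind = "cross"`.
#' @export
empirical_cross_semivariogram <- function(coords, values_a, values_b,
                                          lag_size = 0.04, n_lags = 12,
                                          aniso_factor = 1,
                                          aniso_angle = 0) {
  stopifnot(length(values_a) == nrow(coords),
            length(values_b) == nrow(coords))
  out <- empirical_variogram_core(
    coords,
    function(low) {
      outer(values_a, values_a, "-")[low] *
        outer(values_b, values_b, "-")[low]
    },
    lag_size, n_lags, aniso_factor, aniso_angle
  )
  structure(out, lag_size = lag_size, n_lags = n_lags, kind = "cross",
            vars = NULL, class = c("empirical_variogram", "data.frame"))
}

# Weighted linear fit of (nugget, psill) at fixed range; direct variograms
# are clamped to non-negative coefficients.
wls_coefs <- function(g, gamma_hat, w, nonneg) {
  X <- cbind(1, g)
  WX <- X * w
  coef <- tryCatch(solve(crossprod(WX, X), crossprod(WX, gamma_hat)),
                   error = function(e) NULL)
  if (is.null(coef)) coef <- c(0, 0)
  coef <- unname(drop(coef))
  if (nonneg && (coef[1] < 0 || coef[2] < 0)) {
    # boundary alternatives: nugget = 0 or psill = 0, keep the better
    b1 <- max(0, sum(w * g * gamma_hat) / max(sum(w * g^2), 1e-300))
    alt1 <- c(0, b1)
    b0 <- max(0, sum(w * gamma_hat) / max(sum(w), 1e-300))
    alt2 <- c(b0, 0)
    sse <- function(cf) sum(w * (gamma_hat - cf[1] - cf[2] * g)^2)
    coef <- if (sse(alt1) <= sse(alt2)) alt1 else alt2
  }
  coef
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Iterated weighted least squares: at a trial range, the nugget and
#' partial sill solve a weighted linear problem; the range minimises the
#' weighted residual sum of squares over `[lag_size, 4 * max lag]` (coarse
#' grid search then golden-section refinement). Weights start at the pair
#' counts and are updated to `npairs / gamma_model^2` (Cressie weights)
#' over `n_iter` passes.
#'
#' @param empirical An `empirical_variogram` (direct kind).
#' @param family Variogram family (default `"spherical"`).
#' @param aniso_factor,aniso_angle Anisotropy recorded on the fitted model
#'   (the empirical variogram is assumed binned consistently).
#' @param n_iter Weight-update iterations (default 4).
#' @return A fitted [variogram_model()] with attribute `sse`.
#' @export
fit_variogram_model <- function(empirical, family = "spherical",
                                aniso_factor = 1, aniso_angle = 0,
                                n_iter = 4) {
  occ <- !is.na(empirical$gamma) & empirical$npairs > 0
  if (sum(occ) < 3) {
    stop("need at least 3 occupied lags to fit a variogram", call. = FALSE)
  }
  h <- empirical$dist[occ]
  gh <- empirical$gamma[occ]
  np <- empirical$npairs[occ]
  lag_size <- attr(empirical, "lag_size")
  if (all(gh == 0)) {
    m <- variogram_model(family, 0, 0, max(h), aniso_factor, aniso_angle)
    attr(m, "sse") <- 0
    return(m)
  }
  lo <- max(lag_size, 1e-9)
  hi <- 4 * max(h)
  w <- np
  coef <- c(0, 1)
  rng <- max(h)
  for (iter in seq_len(n_iter)) {
    obj <- function(a) {
      g <- variogram_shape(h / a, family)
      cf <- wls_coefs(g, gh, w, nonneg = TRUE)
      sum(w * (gh - cf[1] - cf[2] * g)^2)
    }
    grid <- exp(seq(log(lo), log(hi), length.out = 80))
    vals <- vapply(grid, obj, numeric(1))
    k <- which.min(vals)
    bl <- grid[max(1, k - 1)]
    bu <- grid[min(length(grid), k + 1)]
    rng <- if (bu > bl) optimize(obj, c(bl, bu), tol = 1e-10)$minimum
           else grid[k]
    g <- variogram_shape(h / rng, family)
    coef <- wls_coefs(g, gh, w, nonneg = TRUE)
    gm <- coef[1] + coef[2] * g
    w <- np / pmax(gm, 1e-8)^2
  }
  m <- variogram_model(family, coef[1], coef[2], rng,
                       aniso_factor, aniso_angle)
  g <- variogram_shape(h / rng, family)
  attr(m, "sse") <- sum(np * (gh - vgm_gamma(m, h))^2)
  m
}

# nearest-PSD projection by eigenvalue clipping
psd_project <- function(M) {
  dn <- dimnames(M)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dn
  out
}

#' Fit a linear model of coregionalization
#'
#' Joint model for all direct and cross variograms of `vars`: a nugget
#' structure plus one `family` structure with a single shared range,
#' `gamma_ij(h) = B0[i,j] 1(h > 0) + B1[i,j] g(h / range)`. The shared
#' range is taken from a free fit to the primary (first) variable's direct
#' variogram unless supplied; each pair's coefficients then solve a
#' weighted linear problem at that range, and the coefficient matrices are
#' projected to the nearest positive semidefinite matrix (eigenvalue
#' clipping), which guarantees a valid co-kriging system.
#'
#' @param empirical Named list of `empirical_variogram`s: direct entries
#'   named by variable (e.g. `"v1_zm"`), cross entries `"a:b"`.
#' @param vars Character vector of variable names; the first is the
#'   primary.
#' @param family Shared structure family.
#' @param range Shared range; `NULL` (default) fits it from the primary.
#' @param aniso_factor,aniso_angle Anisotropy carried into the model.
#' @param max_points,radius Default kriging neighborhood stored on the
#'   model: nearest `max_points` data per variable within `radius` km
#'   (`Inf` radius = global).
#' @return Object of class `cokriging_model`: `vars`, `primary`, `family`,
#'   `range`, `B0`, `B1` (PSD coefficient matrices), anisotropy, and
#'   `neighborhood`.
#' @export
fit_lmc <- function(empirical, vars, family = "spherical", range = NULL,
                    aniso_factor = 1, aniso_angle = 0,
                    max_points = 16, radius = Inf) {
  if (length(empirical) == 0 || length(vars) == 0) {
    stop("no variograms supplied", call. = FALSE)
  }
  if (!all(vars %in% names(empirical))) {
    stop("missing direct variogram for: ",
         paste(setdiff(vars, names(empirical)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(range)) {
    prim_fit <- fit_variogram_model(empirical[[vars[1]]], family,
                                    aniso_factor, aniso_angle)
    range <- prim_fit$range
  }
  m <- length(vars)
  B0 <- matrix(0, m, m, dimnames = list(vars, vars))
  B1 <- matrix(0, m, m, dimnames = list(vars, vars))
  for (i in seq_len(m)) {
    for (j in i:m) {
      key <- if (i == j) vars[i] else {
        k1 <- paste(vars[i], vars[j], sep = ":")
        k2 <- paste(vars[j], vars[i], sep = ":")
        if (k1 %in% names(empirical)) k1 else k2
      }
      emp <- empirical[[key]]
      if (is.null(emp)) {
        stop("missing cross variogram for pair ", vars[i], ", ", vars[j],
             call. = FALSE)
      }
      occ <- !is.na(emp$gamma) & emp$npairs > 0
      h <- emp$dist[occ]
      gh <- emp$gamma[occ]
      np <- emp$npairs[occ]
      g <- variogram_shape(h / range, family)
      coef <- wls_coefs(g, gh, np, nonneg = (i == j))
      # one Cressie weight update
      gm <- pmax(coef[1] + coef[2] * g, 1e-8)
      coef <- wls_coefs(g, gh, np / gm^2, nonneg = (i == j))
      B0[i, j] <- B0[j, i] <- coef[1]
      B1[i, j] <- B1[j, i] <- coef[2]
    }
  }
  structure(
    list(vars = vars, primary = vars[1], family = family, range = range,
         B0 = psd_project(B0), B1 = psd_project(B1),
         aniso_factor = aniso_factor, aniso_angle = aniso_angle,
         neighborhood = list(max_points = max_points, radius = radius)),
    class = "cokriging_model"
  )
}

# Covariance between variables i and j of an LMC at separations h
# (anisotropy-corrected): C_ij(h) = B0_ij 1(h == 0) + B1_ij (1 - g(h)).
# i, j may be scalars (with h a vector/matrix) or vectors parallel to h.
lmc_cov <- function(model, i, j, h) {
  if (length(i) == 1 && length(j) == 1) {
    b0 <- model$B0[i, j]
    b1 <- model$B1[i, j]
  } else {
    b0 <- model$B0[cbind(i, j)]
    b1 <- model$B1[cbind(i, j)]
  }
  out <- b0 * as.numeric(h < 1e-9) +
    b1 * (1 - variogram_shape(as.numeric(h) / model$range, model$family))
  if (is.matrix(h)) dim(out) <- dim(h)
  out
}

#' Convert presence statuses to the kriging indicator
#'
#' Confirmed-infested waterbodies carry indicator 1; waterbodies without an
#' infestation report carry plain 0 (the package's declared convention for
#' unreported locations).
#'
#' @param status Per-waterbody status (0/1 or logical).
#' @return Numeric 0/1 vector.
#' @export
indicator <- function(status) {
  as.numeric(as.numeric(status) > 0)
}

# Internal solver state shared by cokrige_point / cokrige_scores:
# stacked data with per-variable index, full data-data covariance.
cokrige_prepare <- function(model, data) {
  vars <- model$vars
  if (!all(vars %in% names(data))) {
    stop("data missing variables: ",
         paste(setdiff(vars, names(data)), collapse = ", "), call. = FALSE)
  }
  coords <- do.call(rbind, lapply(vars, function(v) data[[v]]$coords))
  values <- unlist(lapply(vars, function(v) data[[v]]$values),
                   use.names = FALSE)
  var_of <- rep(seq_along(vars),
                vapply(vars, function(v) length(data[[v]]$values), 0L))
  N <- nrow(coords)
  dx <- outer(coords[, 1], coords[, 1], "-")
  dy <- outer(coords[, 2], coords[, 2], "-")
  H <- aniso_distance(dx, dy, model$aniso_factor, model$aniso_angle)
  C <- matrix(0, N, N)
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      ii <- var_of == i
      jj <- var_of == j
      C[ii, jj] <- lmc_cov(model, i, j, H[ii, jj, drop = FALSE])
    }
  }
  list(coords = coords, values = values, var_of = var_of, C = C,
       nvar = length(vars))
}

cokrige_solve_one <- function(model, prep, target,
                              max_points, radius,
                              exclude_colocated_primary = FALSE) {
  dx <- prep$coords[, 1] - target[1]
  dy <- prep$coords[, 2] - target[2]
  h0 <- aniso_distance(dx, dy, model$aniso_factor, model$aniso_angle)
  sel <- integer(0)
  for (v in seq_len(prep$nvar)) {
    idx <- which(prep$var_of == v)
    if (v == 1 && exclude_colocated_primary) {
      idx <- idx[h0[idx] >= 1e-9]
    }
    idx <- idx[h0[idx] <= radius]
    if (length(idx) > max_points) {
      idx <- idx[order(h0[idx])[seq_len(max_points)]]
    }
    sel <- c(sel, idx)
  }
  if (!any(prep$var_of[sel] == 1)) {
    stop("no primary data in the kriging neighborhood", call. = FALSE)
  }
  M <- length(sel)
  vsel <- prep$var_of[sel]
  Fc <- matrix(0, M, prep$nvar)
  Fc[cbind(seq_len(M), vsel)] <- 1
  A <- rbind(cbind(prep$C[sel, sel, drop = FALSE], Fc),
             cbind(t(Fc), matrix(0, prep$nvar, prep$nvar)))
  c0 <- lmc_cov(model, vsel, rep(1L, M), h0[sel])
  rhs <- c(c0, 1, rep(0, prep$nvar - 1))
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    diag(A)[seq_len(M)] <- diag(A)[seq_len(M)] + 1e-10
    sol <- tryCatch(solve(A, rhs), error = function(e) {
      stop("co-kriging system is singular", call. = FALSE)
    })
  }
  w <- sol[seq_len(M)]
  c00 <- model$B0[1, 1] + model$B1[1, 1]
  list(
    prediction = sum(w * prep$values[sel]),
    variance = max(0, c00 - sum(sol * rhs)),
    weights = setNames(w, paste0(model$vars[vsel], "#", sel)),
    var_of = vsel,
    lagrange = sol[M + seq_len(prep$nvar)]
  )
}

#' Ordinary co-kriging prediction at one target location
#'
#' Solves the ordinary co-kriging system: weights on the primary variable
#' sum to 1, weights on each secondary sum to 0, and the weighted average
#' minimises the prediction-error variance under the model's LMC. The
#' neighborhood takes the nearest `max_points` data per variable within
#' `radius`; a singular system is retried once with a 1e-10 diagonal
#' jitter.
#'
#' @param model A `cokriging_model` from [fit_lmc()].
#' @param data Named list over `model$vars`; each element
#'   `list(coords, values)` with a two-column coordinate matrix.
#' @param target Length-2 numeric target location.
#' @param max_points,radius Neighborhood control; defaults from the model.
#' @param exclude_colocated_primary Drop a primary datum lying exactly at
#'   the target (leave-one-out scoring of data locations).
#' @return List: `prediction`, `variance` (kriging variance), `weights`,
#'   `lagrange`.
#' @export
cokrige_point <- function(model, data, target,
                          max_points = model$neighborhood$max_points,
                          radius = model$neighborhood$radius,
                          exclude_colocated_primary = FALSE) {
  prep <- cokrige_prepare(model, data)
  cokrige_solve_one(model, prep, target, max_points, radius,
                    exclude_colocated_primary)
}

#' Ordinary co-kriging predictions at many targets
#'
#' Vector version of [cokrige_point()] sharing one covariance
#' precomputation across targets.
#'
#' @inheritParams cokrige_point
#' @param targets Two-column matrix of target locations.
#' @return Numeric vector of predictions (unclamped).
#' @export
cokrige_scores <- function(model, data, targets,
                           max_points = model$neighborhood$max_points,
                           radius = model$neighborhood$radius,
                           exclude_colocated_primary = FALSE) {
  prep <- cokrige_prepare(model, data)
  apply(targets, 1, function(tg) {
    cokrige_solve_one(model, prep, tg, max_points, radius,
                      exclude_colocated_primary)$prediction
  })
}

#' Regular prediction grid over an extent
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in km.
#' @param cell Cell size in km.
#' @return Object of class `grid_spec`: origin, cell size, and cell counts
#'   `nx`, `ny`.
#' @export
grid_spec <- function(extent, cell) {
  stopifnot(cell > 0, extent[2] > extent[1], extent[4] > extent[3])
  structure(
    list(x0 = extent[1], y0 = extent[3], cell = cell,
         nx = ceiling((extent[2] - extent[1]) / cell),
         ny = ceiling((extent[4] - extent[3]) / cell)),
    class = "grid_spec"
  )
}

grid_cell_index <- function(grid, x, y) {
  ix <- floor((x - grid$x0) / grid$cell) + 1L
  iy <- floor((y - grid$y0) / grid$cell) + 1L
  # points sitting exactly on the upper boundary belong to the last cell
  ix[x == grid$x0 + grid$nx * grid$cell] <- grid$nx
  iy[y == grid$y0 + grid$ny * grid$cell] <- grid$ny
  cbind(ix, iy)
}

#' Water mask for a prediction grid
#'
#' Marks the grid cells occupied by at least one waterbody point; the risk
#' surface is defined only there and is exactly 0 elsewhere (introductions
#' cannot occur where there is no waterbody).
#'
#' @param grid A [grid_spec()].
#' @param waterbodies `data.frame(id, x, y, ...)`.
#' @return Logical `nx` x `ny` matrix, `TRUE` for water cells.
#' @export
water_mask <- function(grid, waterbodies) {
  mask <- matrix(FALSE, grid$nx, grid$ny)
  ij <- grid_cell_index(grid, waterbodies$x, waterbodies$y)
  ok <- ij[, 1] >= 1 & ij[, 1] <= grid$nx & ij[, 2] >= 1 & ij[, 2] <= grid$ny
  mask[ij[ok, , drop = FALSE]] <- TRUE
  mask
}

#' Predict the introduction-probability surface on a water-masked grid
#'
#' Runs ordinary co-kriging at the centre of every water cell, clamps
#' predictions to `[0, 1]`, and sets masked (no-waterbody) cells to exactly
#' 0.
#'
#' @inheritParams cokrige_point
#' @param grid A [grid_spec()].
#' @param mask Logical `nx` x `ny` water mask (e.g. [water_mask()]);
#'   `NULL` predicts every cell.
#' @return Object of class `risk_surface`: `grid`, `prob` (`nx` x `ny`
#'   matrix), `mask`.
#' @export
predict_surface <- function(model, data, grid, mask = NULL,
                            max_points = model$neighborhood$max_points,
                            radius = model$neighborhood$radius) {
  if (is.null(mask)) mask <- matrix(TRUE, grid$nx, grid$ny)
  stopifnot(nrow(mask) == grid$nx, ncol(mask) == grid$ny)
  prob <- matrix(0, grid$nx, grid$ny)
  cells <- which(mask, arr.ind = TRUE)
  if (nrow(cells) > 0) {
    centers <- cbind(grid$x0 + (cells[, 1] - 0.5) * grid$cell,
                     grid$y0 + (cells[, 2] - 0.5) * grid$cell)
    preds <- cokrige_scores(model, data, centers, max_points, radius)
    prob[cells] <- pmin(1, pmax(0, preds))
  }
  structure(list(grid = grid, prob = prob, mask = mask),
            class = "risk_surface")
}

#' Extract surface probabilities at waterbody locations
#'
#' Returns the value of the cell containing each waterbody point (no
#' interpolation between cells).
#'
#' @param surface A `risk_surface`.
#' @param waterbodies `data.frame(id, x, y, ...)`.
#' @return Named numeric vector of probabilities per waterbody.
#' @export
extract_at_waterbodies <- function(surface, waterbodies) {
  g <- surface$grid
  ij <- grid_cell_index(g, waterbodies$x, waterbodies$y)
  bad <- ij[, 1] < 1 | ij[, 1] > g$nx | ij[, 2] < 1 | ij[, 2] > g$ny
  if (any(bad)) {
    stop("waterbodies outside the prediction grid: ",
         paste(head(waterbodies$id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  setNames(surface$prob[ij], waterbodies$id)
}
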
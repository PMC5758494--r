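# Synthetic landscape generator ------------------------------------------
#
# Emulates the data layers the risk-mapping pipeline consumes: clustered
# waterbody point locations, stream polylines carrying route identifiers
# ("kittle numbers"), major-road polylines, per-species invasion histories
# over two census years, watercraft-inspection survey records, and a
# reporting process biased toward accessible, high-traffic waterbodies.
# Everything is seeded; a given config reproduces byte-identical output.

#' Configuration for the synthetic landscape generator
#'
#' Defaults describe the desk-scale study system: 600 waterbodies clustered
#' on a 30 x 30 km plane (Thomas process), two invasive species ("zm",
#' "ewm") whose first-census prevalence and census-to-census growth mirror
#' the magnitudes of a state-wide zebra-mussel / watermilfoil system scaled
#' down to a testable size, and a public-reporting observation process whose
#' detection probability increases with road access and boater traffic.
#'
#' @param n_waterbodies Number of waterbody points (> 0).
#' @param extent Bounding box `c(xmin, xmax, ymin, ymax)` in km.
#' @param n_parents Number of Thomas-process cluster parents.
#' @param offspring_sd Cluster spread (km); 0 collapses offspring onto
#'   parents.
#' @param river_fraction Fraction of points flagged as river midpoints
#'   rather than lake centroids.
#' @param n_streams,n_roads Number of stream / major-road polylines.
#' @param base_prevalence_t1 Named per-species first-census prevalence
#'   probabilities in `[0, 1]`.
#' @param growth_factor Named per-species multiplier of infested counts
#'   between the two censuses (>= 1; 2.2 mirrors a 57 -> 125 growth).
#' @param effects Named list of latent risk-score coefficients:
#'   `traffic` (eigenvector centrality), `road` (road access), `field`
#'   (spatially autocorrelated Gaussian field), `proximity` (distance decay
#'   from first-census infestations), `connectivity` (shared-stream
#'   connectivity to first-census infestations). Set all to 0 for a null
#'   landscape.
#' @param field_range Range (km) of the exponential covariance of the
#'   latent Gaussian field.
#' @param proximity_scale Distance-decay scale (km) of the proximity effect.
#' @param reporting List with `intercept` and `bias`: detection probability
#'   of a true infestation is `plogis(intercept + bias * (road z-score +
#'   traffic z-score))`. `bias = 0` with a large intercept gives perfect
#'   reporting; the rate itself is deliberately a free parameter.
#' @param survey_count Number of watercraft inspection survey records.
#' @param ineligible_fraction Fraction of survey records flagged ineligible
#'   (0.79 mirrors the reported 21% eligibility rate).
#' @param missing_end_prob Probability that the previous (or next) waterbody
#'   field of a survey record is absent.
#' @param seed Master seed; every sub-generator derives a named substream
#'   from it.
#' @return A validated list of class `landscape_config`.
#' @export
landscape_config <- function(n_waterbodies = 600,
                             extent = c(0, 30, 0, 30),
                             n_parents = 40,
                             offspring_sd = 1.2,
                             river_fraction = 0.05,
                             n_streams = 25,
                             n_roads = 8,
                             base_prevalence_t1 = c(zm = 0.05, ewm = 0.08),
                             growth_factor = c(zm = 2.2, ewm = 1.2),
                             effects = list(traffic = 1.2, road = 0.8,
                                            field = 1.0, proximity = 2.0,
                                            connectivity = 1.0),
                             field_range = 4,
                             proximity_scale = 2,
                             reporting = list(intercept = 1.5, bias = 1.0),
                             survey_count = 5000,
                             ineligible_fraction = 0.79,
                             missing_end_prob = 0.1,
                             seed = 1) {
  cfg <- list(
    n_waterbodies = n_waterbodies, extent = extent,
    n_parents = n_parents, offspring_sd = offspring_sd,
    river_fraction = river_fraction,
    n_streams = n_streams, n_roads = n_roads,
    base_prevalence_t1 = base_prevalence_t1,
    growth_factor = growth_factor,
    effects = effects, field_range = field_range,
    proximity_scale = proximity_scale,
    reporting = reporting,
    survey_count = survey_count,
    ineligible_fraction = ineligible_fraction,
    missing_end_prob = missing_end_prob,
    seed = seed
  )
  validate_landscape_config(cfg)
  class(cfg) <- "landscape_config"
  cfg
}

validate_landscape_config <- function(cfg) {
  if (!is.numeric(cfg$n_waterbodies) || cfg$n_waterbodies <= 0) {
    stop("invalid config: n_waterbodies must be positive", call. = FALSE)
  }
  if (length(cfg$extent) != 4 ||
      cfg$extent[2] <= cfg$extent[1] || cfg$extent[4] <= cfg$extent[3]) {
    stop("invalid config: extent must be c(xmin, xmax, ymin, ymax)",
         call. = FALSE)
  }
  probs <- c(cfg$base_prevalence_t1, cfg$ineligible_fraction,
             cfg$missing_end_prob, cfg$river_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("invalid config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("zm", "ewm")) {
    if (is.na(cfg$base_prevalence_t1[nm]) || is.na(cfg$growth_factor[nm])) {
      stop("invalid config: per-species parameters need names zm, ewm",
           call. = FALSE)
    }
  }
  if (any(c(cfg$n_parents, cfg$n_streams, cfg$n_roads,
            cfg$survey_count) < 0)) {
    stop("invalid config: counts must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate clustered waterbody point locations
#'
#' Draws a Thomas-type cluster process: `n_parents` parent centres uniform
#' on the extent, each waterbody attached to a random parent with isotropic
#' Gaussian offset `offspring_sd`, clamped to the extent. A
#' `river_fraction` of points is flagged as river midpoints.
#'
#' @param config A [landscape_config()].
#' @return `data.frame(id, x, y, kind)` with unique ids.
#' @export
generate_waterbodies <- function(config) {
  validate_landscape_config(config)
  n <- config$n_waterbodies
  ext <- config$extent
  with_substream(config$seed, "waterbodies", {
    px <- runif(config$n_parents, ext[1], ext[2])
    py <- runif(config$n_parents, ext[3], ext[4])
    parent <- sample.int(config$n_parents, n, replace = TRUE)
    x <- pmin(ext[2], pmax(ext[1], px[parent] + rnorm(n, 0, config$offspring_sd)))
    y <- pmin(ext[4], pmax(ext[3], py[parent] + rnorm(n, 0, config$offspring_sd)))
    kind <- ifelse(runif(n) < config$river_fraction, "river", "lake")
    data.frame(
      id = sprintf("W%04d", seq_len(n)),
      x = x, y = y, kind = kind,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate stream and road polylines
#'
#' Each stream threads a handful of mutually nearby waterbody locations
#' (its vertices pass exactly through them, so geometric stream assignment
#' recovers the threading) and carries a unique kittle-style route id.
#' Roads are long polylines spanning the extent.
#'
#' @param config A [landscape_config()].
#' @param waterbodies Output of [generate_waterbodies()].
#' @return List with `streams` (each `list(kittle_id, vertices)`), `roads`
#'   (each `list(road_class, vertices)`), and `threading`, the generating
#'   waterbody-to-stream map (named list of kittle-id character vectors).
#' @export
generate_streams_roads <- function(config, waterbodies) {
  validate_landscape_config(config)
  ext <- config$extent
  wb <- waterbodies
  with_substream(config$seed, "streams_roads", {
    streams <- vector("list", config$n_streams)
    threading <- setNames(
      replicate(nrow(wb), character(0), simplify = FALSE), wb$id
    )
    for (s in seq_len(config$n_streams)) {
      kid <- sprintf("H%03d", s)
      anchor <- sample.int(nrow(wb), 1)
      k <- min(nrow(wb), rpois(1, 5) + 2L)
      d <- sqrt((wb$x - wb$x[anchor])^2 + (wb$y - wb$y[anchor])^2)
      members <- order(d)[seq_len(k)]
      members <- members[order(wb$x[members], wb$y[members])]
      verts <- cbind(wb$x[members], wb$y[members])
      # extend both ends so the polyline reads as a through-flowing stream
      if (nrow(verts) >= 2) {
        first <- verts[1, ] + (verts[1, ] - verts[2, ]) * 0.5 +
          rnorm(2, 0, 0.2)
        last <- verts[nrow(verts), ] +
          (verts[nrow(verts), ] - verts[nrow(verts) - 1, ]) * 0.5 +
          rnorm(2, 0, 0.2)
        verts <- rbind(first, verts, last)
      } else {
        verts <- rbind(verts, verts + rnorm(2, 0, 0.5))
      }
      streams[[s]] <- list(kittle_id = kid, vertices = unname(verts))
      for (m in members) {
        threading[[wb$id[m]]] <- c(threading[[wb$id[m]]], kid)
      }
    }
    roads <- vector("list", config$n_roads)
    for (r in seq_len(config$n_roads)) {
      horizontal <- runif(1) < 0.5
      nseg <- 4L
      if (horizontal) {
        xs <- seq(ext[1], ext[2], length.out = nseg + 1)
        ys <- runif(1, ext[3], ext[4]) + cumsum(c(0, rnorm(nseg, 0, 1)))
        ys <- pmin(ext[4], pmax(ext[3], ys))
      } else {
        ys <- seq(ext[3], ext[4], length.out = nseg + 1)
        xs <- runif(1, ext[1], ext[2]) + cumsum(c(0, rnorm(nseg, 0, 1)))
        xs <- pmin(ext[2], pmax(ext[1], xs))
      }
      roads[[r]] <- list(
        road_class = sample(c("interstate", "arterial", "collector"), 1),
        vertices = unname(cbind(xs, ys))
      )
    }
    list(streams = streams, roads = roads, threading = threading)
  })
}

#' Generate watercraft inspection survey records
#'
#' Station locations are drawn proportional to a per-waterbody visitation
#' propensity; previous and next waterbodies follow a gravity-style kernel,
#' propensity over distance from the station. A fraction of records is
#' flagged ineligible, and either trip end may be missing.
#'
#' @param waterbodies Output of [generate_waterbodies()].
#' @param propensity Non-negative per-waterbody visitation propensity,
#'   aligned with `waterbodies`; `NULL` draws a lognormal propensity from
#'   the config's seed.
#' @param config A [landscape_config()].
#' @return `data.frame(station_id, prev_id, next_id, eligible)`; absent trip
#'   ends are `NA`.
#' @export
generate_surveys <- function(waterbodies, propensity = NULL, config) {
  validate_landscape_config(config)
  n <- nrow(waterbodies)
  if (is.null(propensity)) {
    propensity <- with_substream(config$seed, "propensity",
                                 rlnorm(n, 0, 1))
  }
  stopifnot(length(propensity) == n, all(propensity >= 0))
  m <- config$survey_count
  if (m == 0) {
    return(data.frame(station_id = character(0), prev_id = character(0),
                      next_id = character(0), eligible = logical(0),
                      stringsAsFactors = FALSE))
  }
  with_substream(config$seed, "surveys", {
    station <- sample.int(n, m, replace = TRUE, prob = propensity)
    prev <- integer(m)
    nxt <- integer(m)
    for (s in unique(station)) {
      idx <- which(station == s)
      d <- sqrt((waterbodies$x - waterbodies$x[s])^2 +
                  (waterbodies$y - waterbodies$y[s])^2)
      w <- propensity / (d + 0.5)
      prev[idx] <- sample.int(n, length(idx), replace = TRUE, prob = w)
      nxt[idx] <- sample.int(n, length(idx), replace = TRUE, prob = w)
    }
    prev_id <- waterbodies$id[prev]
    next_id <- waterbodies$id[nxt]
    prev_id[runif(m) < config$missing_end_prob] <- NA_character_
    next_id[runif(m) < config$missing_end_prob] <- NA_character_
    eligible <- runif(m) >= config$ineligible_fraction
    data.frame(
      station_id = waterbodies$id[station],
      prev_id = prev_id, next_id = next_id, eligible = eligible,
      stringsAsFactors = FALSE
    )
  })
}

# Solve the intercept a s.t. mean(plogis(a + s)) == target over the latent
# scores s.  Returns -Inf for target 0 and +Inf for target 1.
calibrate_intercept <- function(s, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  uniroot(function(a) mean(stats::plogis(a + s)) - target,
          lower = -60, upper = 60, tol = 1e-10)$root
}

# Standardise a covariate to z-scores; constant vectors map to zeros.
zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate true per-species invasion statuses for two censuses
#'
#' First-census statuses are Bernoulli draws from a logistic latent risk
#' score combining boater-traffic centrality, road access, and a spatially
#' autocorrelated Gaussian field (exponential covariance). The intercept is
#' calibrated so the expected first-census prevalence equals
#' `base_prevalence_t1`. Second-census statuses add new infestations whose
#' probability increases with proximity to first-census infestations and
#' shared-stream connectivity (plus the same latent score), calibrated so
#' the expected second-census count is `growth_factor` times the first.
#' Status never decreases between censuses.
#'
#' @param waterbodies Output of [generate_waterbodies()].
#' @param threading Waterbody-to-stream map (named list of kittle ids), as
#'   returned by [generate_streams_roads()].
#' @param traffic_scores,road_scores Per-waterbody covariate scores aligned
#'   with `waterbodies` (names checked when present).
#' @param config A [landscape_config()].
#' @return `data.frame(id, zm_t1, zm_t2, ewm_t1, ewm_t2)` of 0/1 statuses.
#' @export
generate_true_invasions <- function(waterbodies, threading,
                                    traffic_scores, road_scores, config) {
  validate_landscape_config(config)
  n <- nrow(waterbodies)
  for (v in list(traffic_scores, road_scores)) {
    if (length(v) != n) {
      stop("covariate scores are not aligned with waterbodies",
           call. = FALSE)
    }
    if (!is.null(names(v)) && !identical(names(v), waterbodies$id)) {
      stop("covariate scores are not aligned with waterbodies",
           call. = FALSE)
    }
  }
  eff <- config$effects
  zt <- zstd(traffic_scores)
  zr <- zstd(log(pmax(road_scores, 1e-12)))
  out <- data.frame(id = waterbodies$id, stringsAsFactors = FALSE)
  coords <- cbind(waterbodies$x, waterbodies$y)
  grf <- with_substream(config$seed, "risk_field", {
    if (eff$field == 0) {
      rep(0, n)
    } else {
      simulate_gaussian_field(coords, family = "exponential",
                              range = config$field_range, sill = 1)
    }
  })
  for (sp in c("zm", "ewm")) {
    s1 <- eff$traffic * zt + eff$road * zr + eff$field * grf
    a1 <- calibrate_intercept(s1, config$base_prevalence_t1[[sp]])
    t1 <- with_substream(config$seed, paste0("t1_", sp), {
      rbinom(n, 1, stats::plogis(a1 + s1))
    })
    n1 <- sum(t1)
    target_new <- max(0, (config$growth_factor[[sp]] - 1) * n1)
    t2 <- t1
    if (n1 > 0 && target_new > 0 && n1 < n) {
      dmin <- rep(Inf, n)
      inf_idx <- which(t1 == 1)
      for (i in seq_len(n)) {
        dmin[i] <- sqrt(min((coords[inf_idx, 1] - coords[i, 1])^2 +
                              (coords[inf_idx, 2] - coords[i, 2])^2))
      }
      prox <- exp(-dmin / config$proximity_scale)
      conn <- shared_route_flags(threading, waterbodies$id[t1 == 1])
      s2 <- s1 + eff$proximity * prox + eff$connectivity * conn
      sus <- which(t1 == 0)
      p_target <- min(1, target_new / length(sus))
      a2 <- calibrate_intercept(s2[sus], p_target)
      new <- with_substream(config$seed, paste0("t2_", sp), {
        rbinom(length(sus), 1, stats::plogis(a2 + s2[sus]))
      })
      t2[sus] <- new
      t2 <- pmax(t1, t2)
    }
    out[[paste0(sp, "_t1")]] <- t1
    out[[paste0(sp, "_t2")]] <- t2
  }
  out[, c("id", "zm_t1", "zm_t2", "ewm_t1", "ewm_t2")]
}

#' Generate reported (observed) invasion statuses
#'
#' Each true infestation is detected with probability
#' `plogis(intercept + bias * (road z-score + traffic z-score))`, so
#' accessible, high-traffic waterbodies are over-represented among reports.
#' There are no false positives (reported is a subset of true), and a report
#' is never retracted: second-census reports contain first-census reports.
#'
#' @param true_status Output of [generate_true_invasions()].
#' @param road_scores,traffic_scores Per-waterbody scores aligned with
#'   `true_status`.
#' @param config A [landscape_config()].
#' @return Data frame shaped like `true_status` with reported 0/1 statuses.
#' @export
generate_reported_invasions <- function(true_status, road_scores,
                                        traffic_scores, config) {
  validate_landscape_config(config)
  n <- nrow(true_status)
  zt <- zstd(traffic_scores)
  zr <- zstd(log(pmax(road_scores, 1e-12)))
  lin <- config$reporting$intercept +
    config$reporting$bias * (zr + zt)
  p_det <- stats::plogis(lin)
  out <- true_status
  with_substream(config$seed, "reporting", {
    for (sp in c("zm", "ewm")) {
      t1 <- true_status[[paste0(sp, "_t1")]]
      t2 <- true_status[[paste0(sp, "_t2")]]
      d1 <- rbinom(n, 1, p_det)
      d2 <- rbinom(n, 1, p_det)
      r1 <- t1 * d1
      r2 <- pmax(r1, t2 * d2)
      out[[paste0(sp, "_t1")]] <- r1
      out[[paste0(sp, "_t2")]] <- r2
    }
  })
  out
}

#' Simulate a complete synthetic landscape
#'
#' Runs the whole generator chain: waterbodies, streams and roads, survey
#' records, the boater-traffic network and its eigenvector centrality, road
#' access, true invasion histories, and biased reports.
#'
#' @param config A [landscape_config()].
#' @return List of class `ais_landscape`: `waterbodies`, `streams`, `roads`,
#'   `threading`, `surveys`, `network`, `traffic` (eigenvector centrality),
#'   `road_access` (inverse road distance), `truth`, `reported`, `config`.
#' @export
simulate_landscape <- function(config = landscape_config()) {
  validate_landscape_config(config)
  wb <- generate_waterbodies(config)
  geo <- generate_streams_roads(config, wb)
  road_access <- inverse_road_distance(wb, geo$roads)
  surveys <- generate_surveys(wb, propensity = NULL, config = config)
  net <- build_traffic_network(surveys, wb$id)
  traffic <- eigenvector_centrality(net)
  traffic_full <- setNames(rep(0, nrow(wb)), wb$id)
  traffic_full[names(traffic$score)] <- traffic$score
  truth <- generate_true_invasions(wb, geo$threading, traffic_full,
                                   road_access, config)
  reported <- generate_reported_invasions(truth, road_access, traffic_full,
                                          config)
  structure(
    list(waterbodies = wb, streams = geo$streams, roads = geo$roads,
         threading = geo$threading, surveys = surveys, network = net,
         traffic = traffic_full, road_access = road_access,
         truth = truth, reported = reported, config = config),
    class = "ais_landscape"
  )
}

#' Simulate a Gaussian random field at point locations
#'
#' Draws one realisation of a zero-mean Gaussian field with an exponential
#' or spherical covariance at the supplied coordinates, by Cholesky
#' factorisation of the covariance matrix (intended for n up to a few
#' thousand).
#'
#' @param coords Two-column coordinate matrix (km).
#' @param family Covariance family, `"exponential"` or `"spherical"`.
#' @param range Range parameter (km).
#' @param sill Marginal variance.
#' @param nugget Nugget variance added on the diagonal.
#' @return Numeric vector of field values, one per coordinate row.
#' @export
simulate_gaussian_field <- function(coords, family = "exponential",
                                    range = 1, sill = 1, nugget = 0) {
  h <- as.matrix(dist(coords))
  g <- variogram_shape(h / range, family)
  C <- sill * (1 - g)
  diag(C) <- sill + nugget + 1e-9
  L <- chol(C)
  drop(crossprod(L, rnorm(nrow(coords))))
}
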
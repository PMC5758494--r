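# Waterbody-specific covariates ------------------------------------------
#
# The six predictors: per-species invasion status (v1, v2), per-species
# stream connectivity to an invaded waterbody (v3, v4), eigenvector
# centrality of the boater-traffic network (v5), and inverse Euclidean
# distance to the nearest major road (v6).

#' Inverse distance to the nearest major road
#'
#' Minimum Euclidean point-to-polyline distance over all major-road
#' segments, inverted. Distances below `d_min` are floored at `d_min` so
#' a waterbody sitting on a road maps to `1 / d_min` rather than infinity.
#'
#' @param waterbodies `data.frame(id, x, y, ...)`.
#' @param roads List of `list(road_class, vertices)` polylines.
#' @param d_min Distance floor in km (default 0.01, i.e. 10 m).
#' @return Named vector of inverse distances (1/km) per waterbody.
#' @export
inverse_road_distance <- function(waterbodies, roads, d_min = 0.01) {
  if (length(roads) == 0) {
    stop("no road layer supplied", call. = FALSE)
  }
  d <- rep(Inf, nrow(waterbodies))
  for (r in roads) {
    d <- pmin(d, point_polyline_distance(waterbodies$x, waterbodies$y,
                                         r$vertices))
  }
  setNames(1 / pmax(d, d_min), waterbodies$id)
}

#' Assemble the six-variable covariate table for one census year
#'
#' All inputs must be aligned by waterbody id (names are checked when
#' present). Waterbodies absent from the traffic network carry a
#' centrality of 0; traffic and road access are shared across census years
#' by construction, so only statuses and connectivity differ between the
#' tables for the two censuses.
#'
#' @param waterbodies `data.frame(id, x, y, ...)`.
#' @param status_zm,status_ewm Per-species 0/1 invasion status for the
#'   requested census.
#' @param conn_zm,conn_ewm Per-species 0/1 stream connectivity for the
#'   requested census.
#' @param centrality Traffic centrality scores (0 where unsurveyed).
#' @param road_scores Inverse road distances.
#' @param year Census label stored in the table (e.g. "t1").
#' @return `data.frame(id, x, y, v1_zm, v2_ewm, v3_conn_zm, v4_conn_ewm,
#'   v5_eig, v6_invroad, year)` of class `covariate_table`.
#' @export
assemble_covariates <- function(waterbodies, status_zm, status_ewm,
                                conn_zm, conn_ewm, centrality,
                                road_scores, year = "t1") {
  n <- nrow(waterbodies)
  cols <- list(v1_zm = status_zm, v2_ewm = status_ewm,
               v3_conn_zm = conn_zm, v4_conn_ewm = conn_ewm,
               v5_eig = centrality, v6_invroad = road_scores)
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (length(v) != n) {
      stop("covariate '", nm, "' is not aligned with the waterbody table",
           call. = FALSE)
    }
    if (!is.null(names(v)) && !identical(names(v), waterbodies$id)) {
      stop("covariate '", nm, "' ids do not match the waterbody table",
           call. = FALSE)
    }
    if (anyNA(v)) {
      stop("covariate '", nm, "' contains missing values", call. = FALSE)
    }
  }
  out <- data.frame(
    id = waterbodies$id, x = waterbodies$x, y = waterbodies$y,
    v1_zm = as.numeric(status_zm), v2_ewm = as.numeric(status_ewm),
    v3_conn_zm = as.numeric(conn_zm), v4_conn_ewm = as.numeric(conn_ewm),
    v5_eig = as.numeric(centrality),
    v6_invroad = as.numeric(road_scores),
    year = year, stringsAsFactors = FALSE
  )
  class(out) <- c("covariate_table", "data.frame")
  out
}

covariate_names <- function() {
  c("v1_zm", "v2_ewm", "v3_conn_zm", "v4_conn_ewm", "v5_eig", "v6_invroad")
}

#' Pearson screening of covariates against each primary status
#'
#' Computes the full 6 x 6 Pearson correlation matrix of the covariate
#' columns (binary columns enter as 0/1 numerics, i.e. point-biserial) and,
#' for each primary variable (v1 zm status, v2 ewm status), the candidate
#' secondary set: all other variables with `r >= threshold` against that
#' primary. The other species' status is an eligible candidate.
#' Zero-variance columns get `NA` correlations and are excluded from
#' candidacy, with a warning.
#'
#' @param table A `covariate_table`.
#' @param threshold Inclusion threshold on Pearson r (default 0.1; the
#'   comparison is `>=`).
#' @return List: `matrix` (6 x 6 correlations), `threshold`, `candidates`
#'   (named list with entries `zm`, `ewm` of candidate column names).
#' @export
pearson_screen <- function(table, threshold = 0.1) {
  vars <- covariate_names()
  X <- as.matrix(as.data.frame(table)[, vars])
  if (nrow(X) < 3) stop("need at least 3 waterbodies", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  degenerate <- vars[sds == 0]
  if (length(degenerate) > 0) {
    warning("zero-variance covariates excluded from screening: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  M <- suppressWarnings(cor(X))
  M[degenerate, ] <- NA_real_
  M[, degenerate] <- NA_real_
  diag(M) <- ifelse(vars %in% degenerate, NA_real_, 1)
  candidates <- list()
  for (sp in c("zm", "ewm")) {
    primary <- if (sp == "zm") "v1_zm" else "v2_ewm"
    r <- M[primary, ]
    ok <- names(r)[!is.na(r) & r >= threshold & names(r) != primary]
    candidates[[sp]] <- ok
  }
  list(matrix = M, threshold = threshold, candidates = candidates)
}
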
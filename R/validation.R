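# Model selection and validation -----------------------------------------

#' Kriging parameter set for the pipeline
#'
#' Collects the tunable co-kriging parameters: empirical variogram lag
#' size and lag count, variogram family, geometric anisotropy, the
#' neighborhood (nearest `max_points` data per variable within `radius`),
#' and the treatment of unreported waterbodies (`zeros = "include"` keeps
#' all indicator-0 data; `"subsample"` keeps all 1s plus a seeded fraction
#' of 0s).
#'
#' @param lag_size Lag width in km.
#' @param n_lags Number of lags.
#' @param family Variogram family.
#' @param aniso_factor,aniso_angle Geometric anisotropy (factor 1 = off).
#' @param max_points Nearest data per variable entering each solve.
#' @param radius Neighborhood search radius in km (`Inf` = global search
#'   limited by `max_points`).
#' @param zeros `"include"` or `"subsample"`.
#' @param zeros_fraction Fraction of indicator-0 data kept under
#'   `"subsample"`.
#' @param zeros_seed Seed for the subsample draw.
#' @return A list of class `kriging_params`.
#' @export
kriging_params <- function(lag_size = 0.5, n_lags = 12,
                           family = "spherical",
                           aniso_factor = 1, aniso_angle = 0,
                           max_points = 16, radius = Inf,
                           zeros = c("include", "subsample"),
                           zeros_fraction = 0.25, zeros_seed = 1) {
  structure(
    list(lag_size = lag_size, n_lags = n_lags, family = family,
         aniso_factor = aniso_factor, aniso_angle = aniso_angle,
         max_points = max_points, radius = radius,
         zeros = match.arg(zeros), zeros_fraction = zeros_fraction,
         zeros_seed = zeros_seed),
    class = "kriging_params"
  )
}

primary_column <- function(species) {
  switch(species, zm = "v1_zm", ewm = "v2_ewm",
         stop("unknown species: ", species, call. = FALSE))
}

# Build the co-kriging data list (primary indicator + secondaries) from a
# covariate table, applying the zeros policy to the primary variable.
cokrige_data <- function(cov, species, secondaries, params,
                         drop_primary_ids = character(0)) {
  primary <- primary_column(species)
  coords <- cbind(cov$x, cov$y)
  z <- indicator(cov[[primary]])
  keep <- !(cov$id %in% drop_primary_ids)
  if (params$zeros == "subsample") {
    keep_zero <- with_substream(params$zeros_seed, "zeros_subsample", {
      runif(length(z)) < params$zeros_fraction
    })
    keep <- keep & (z == 1 | keep_zero)
  }
  data <- list()
  data[[primary]] <- list(coords = coords[keep, , drop = FALSE],
                          values = z[keep])
  for (s in secondaries) {
    data[[s]] <- list(coords = coords, values = as.numeric(cov[[s]]))
  }
  data
}

# Empirical direct + cross variograms for primary and secondaries and the
# fitted LMC.
fit_species_model <- function(cov, species, secondaries, params) {
  primary <- primary_column(species)
  vars <- c(primary, secondaries)
  coords <- cbind(cov$x, cov$y)
  vals <- lapply(vars, function(v) {
    if (v == primary) indicator(cov[[v]]) else as.numeric(cov[[v]])
  })
  names(vals) <- vars
  emps <- list()
  for (i in seq_along(vars)) {
    emps[[vars[i]]] <- empirical_semivariogram(
      coords, vals[[i]], params$lag_size, params$n_lags,
      params$aniso_factor, params$aniso_angle
    )
    for (j in seq_len(i - 1)) {
      key <- paste(vars[j], vars[i], sep = ":")
      emps[[key]] <- empirical_cross_semivariogram(
        coords, vals[[j]], vals[[i]], params$lag_size, params$n_lags,
        params$aniso_factor, params$aniso_angle
      )
    }
  }
  fit_lmc(emps, vars, family = params$family,
          aniso_factor = params$aniso_factor,
          aniso_angle = params$aniso_angle,
          max_points = params$max_points, radius = params$radius)
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' The probability that a random positive outranks a random negative, with
#' tied scores counted one half; computed from rank sums.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 (or logical) outcome labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(as.numeric(labels) > 0)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop("AUC undefined: need both positive and negative labels",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Sensitivity and specificity at a threshold risk rank
#'
#' Predicted-positive is rank >= threshold. With `rank = NULL` the
#' threshold is chosen automatically as the rank maximising sensitivity +
#' specificity (Youden's J), ties resolved to the lower rank.
#'
#' @param ranking A `risk_ranking` or integer rank vector.
#' @param labels 0/1 outcome labels aligned with the ranking.
#' @param rank Threshold rank (default 3); `NULL` for auto-threshold.
#' @return List: `sensitivity`, `specificity`, `rank`.
#' @export
sens_spec_at_rank <- function(ranking, labels, rank = 3) {
  rk <- if (inherits(ranking, "risk_ranking")) ranking$rank else ranking
  labels <- as.numeric(as.numeric(labels) > 0)
  stopifnot(length(rk) == length(labels))
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("sensitivity/specificity undefined: single-class labels",
         call. = FALSE)
  }
  eval_at <- function(thr) {
    pred <- rk >= thr
    list(sensitivity = sum(pred & labels == 1) / sum(labels == 1),
         specificity = sum(!pred & labels == 0) / sum(labels == 0),
         rank = thr)
  }
  if (is.null(rank)) {
    cand <- lapply(1:5, eval_at)
    youden <- vapply(cand, function(z) z$sensitivity + z$specificity, 0)
    cand[[which.max(youden)]]  # which.max takes the lowest tied rank
  } else {
    if (rank < 1 || rank > 5) stop("rank must lie in 1..5", call. = FALSE)
    eval_at(rank)
  }
}

#' Temporal (census-to-census) validation of a co-kriging model
#'
#' Fits the co-kriging model to first-census statuses and scores every
#' waterbody not reported infested at the first census by leave-one-out
#' co-kriging (the target's own primary indicator datum is excluded from
#' its neighborhood; its secondary data are kept). Positives are
#' waterbodies newly reported by the second census; negatives are
#' waterbodies never reported. Reports AUC plus sensitivity/specificity at
#' the threshold rank over the quantile ranking of the test scores.
#'
#' @param cov_t1,cov_t2 `covariate_table`s for the two censuses.
#' @param species `"zm"` or `"ewm"`.
#' @param secondaries Two (or more) secondary covariate names.
#' @param params A [kriging_params()].
#' @param threshold_rank Rank used for sensitivity/specificity (default 3).
#' @return A `validation_report`: scheme, species, secondaries, `auc`,
#'   `sensitivity`, `specificity`, `threshold_rank`, `scores`, `labels`,
#'   and the fitted `model`.
#' @export
true_validation <- function(cov_t1, cov_t2, species, secondaries,
                            params = kriging_params(),
                            threshold_rank = 3) {
  primary <- primary_column(species)
  stopifnot(identical(cov_t1$id, cov_t2$id))
  model <- fit_species_model(cov_t1, species, secondaries, params)
  data <- cokrige_data(cov_t1, species, secondaries, params)
  test <- which(indicator(cov_t1[[primary]]) == 0)
  targets <- cbind(cov_t1$x[test], cov_t1$y[test])
  scores <- cokrige_scores(model, data, targets,
                           exclude_colocated_primary = TRUE)
  scores <- setNames(pmin(1, pmax(0, scores)), cov_t1$id[test])
  labels <- indicator(cov_t2[[primary]])[test]
  if (sum(labels) == 0) {
    stop("AUC undefined: no new infestations between censuses",
         call. = FALSE)
  }
  auc <- roc_auc(scores, labels)
  ranking <- rank_by_quantiles(scores)
  ss <- sens_spec_at_rank(ranking, labels, threshold_rank)
  structure(
    list(scheme = "true_validation", species = species,
         secondaries = secondaries, auc = auc,
         sensitivity = ss$sensitivity, specificity = ss$specificity,
         threshold_rank = ss$rank, scores = scores, labels = labels,
         model = model),
    class = "validation_report"
  )
}

# Partition ids into k seeded folds of near-equal size (the first
# n %% k folds get one extra member).
make_folds <- function(ids, k, seed) {
  shuffled <- with_substream(seed, "folds", sample(ids))
  sizes <- rep(length(ids) %/% k, k) +
    c(rep(1, length(ids) %% k), rep(0, k - length(ids) %% k))
  split(shuffled, factor(rep(seq_len(k), times = sizes),
                         levels = seq_len(k)))
}

#' k-fold cross-validation of a co-kriging model
#'
#' Infested (indicator 1) waterbodies are partitioned into `k` seeded
#' folds, and uninfested waterbodies into `k` folds likewise. For each
#' fold, the fold's infested waterbodies are withheld from the fitting
#' data and scored, together with the fold's uninfested waterbodies, by
#' leave-one-out co-kriging under variogram parameters held fixed at the
#' full-data fit. Scores are pooled over folds for the AUC and the
#' sensitivity/specificity at the threshold rank.
#'
#' @param cov A `covariate_table` for one census.
#' @param species `"zm"` or `"ewm"`.
#' @param secondaries Secondary covariate names.
#' @param k Number of folds (default 5; 80/20 train/test splits).
#' @param seed Fold-assignment seed.
#' @param params A [kriging_params()].
#' @param threshold_rank Rank for sensitivity/specificity (default 3).
#' @return A `validation_report` with scheme `"kfold"` and a `folds`
#'   element listing the withheld infested ids per fold.
#' @export
kfold_cv <- function(cov, species, secondaries, k = 5, seed = 1,
                     params = kriging_params(), threshold_rank = 3) {
  primary <- primary_column(species)
  z <- indicator(cov[[primary]])
  pos_ids <- cov$id[z == 1]
  neg_ids <- cov$id[z == 0]
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (length(pos_ids) < k) {
    stop("fewer infested waterbodies than folds", call. = FALSE)
  }
  model <- fit_species_model(cov, species, secondaries, params)
  pos_folds <- make_folds(pos_ids, k, seed)
  neg_folds <- make_folds(neg_ids, k, seed + 1)
  scores <- numeric(0)
  labels <- numeric(0)
  for (f in seq_len(k)) {
    held_pos <- pos_folds[[f]]
    held_neg <- neg_folds[[f]]
    data <- cokrige_data(cov, species, secondaries, params,
                         drop_primary_ids = held_pos)
    ids <- c(held_pos, held_neg)
    rows <- match(ids, cov$id)
    sc <- cokrige_scores(model, data, cbind(cov$x[rows], cov$y[rows]),
                         exclude_colocated_primary = TRUE)
    scores <- c(scores, setNames(pmin(1, pmax(0, sc)), ids))
    labels <- c(labels, rep(c(1, 0), c(length(held_pos), length(held_neg))))
  }
  auc <- roc_auc(scores, labels)
  ranking <- rank_by_quantiles(scores)
  ss <- sens_spec_at_rank(ranking, labels, threshold_rank)
  structure(
    list(scheme = "kfold", species = species, secondaries = secondaries,
         k = k, auc = auc, sensitivity = ss$sensitivity,
         specificity = ss$specificity, threshold_rank = ss$rank,
         scores = scores, labels = labels, folds = pos_folds,
         model = model),
    class = "validation_report"
  )
}

#' Select the best secondary-variable pair by temporal-validation AUC
#'
#' Evaluates every unordered pair of screened candidate secondaries (the
#' other species' status participates when screened in) by
#' [true_validation()] AUC and returns the argmax; ties resolve to the
#' lexicographically first pair. Pairs whose validation fails (e.g. a
#' degenerate fold) are recorded with `NA` AUC and skipped.
#'
#' @param cov_t1,cov_t2 `covariate_table`s for the two censuses.
#' @param species `"zm"` or `"ewm"`.
#' @param candidates Candidate secondary names (>= 2), e.g. from
#'   [pearson_screen()].
#' @param params A [kriging_params()].
#' @return List of class `model_selection`: `table` (pairs and AUCs),
#'   `secondaries` (chosen pair), `auc`, and the chosen pair's full
#'   `report`.
#' @export
select_model <- function(cov_t1, cov_t2, species, candidates,
                         params = kriging_params()) {
  candidates <- sort(unique(candidates))
  if (length(candidates) < 2) {
    stop("need at least two candidate secondary variables", call. = FALSE)
  }
  pairs <- utils::combn(candidates, 2)
  aucs <- rep(NA_real_, ncol(pairs))
  reports <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    rep_p <- tryCatch(
      true_validation(cov_t1, cov_t2, species, pairs[, p], params),
      error = function(e) NULL
    )
    if (!is.null(rep_p)) {
      aucs[p] <- rep_p$auc
      reports[[p]] <- rep_p
    }
  }
  if (all(is.na(aucs))) {
    stop("no candidate pair could be validated", call. = FALSE)
  }
  best <- which.max(aucs)  # first maximum = lexicographically first pair
  structure(
    list(
      table = data.frame(sec1 = pairs[1, ], sec2 = pairs[2, ], auc = aucs,
                         stringsAsFactors = FALSE),
      secondaries = pairs[, best], auc = aucs[best],
      report = reports[[best]]
    ),
    class = "model_selection"
  )
}
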
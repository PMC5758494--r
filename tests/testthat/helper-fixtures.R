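# Shared fixtures and independent oracles --------------------------------

# Small, fast landscape configs. signal_config keeps the default effect
# sizes; null_config switches every effect and the reporting bias off.
signal_config <- function(seed, n = 600) {
  landscape_config(n_waterbodies = n, seed = seed)
}

null_config <- function(seed, n = 600) {
  landscape_config(
    n_waterbodies = n,
    effects = list(traffic = 0, road = 0, field = 0,
                   proximity = 0, connectivity = 0),
    reporting = list(intercept = 20, bias = 0),
    seed = seed
  )
}

# Assemble both census covariate tables from a simulated landscape using
# only exported package functions.
covariates_from_landscape <- function(ls) {
  wb <- ls$waterbodies
  v5 <- eigenvector_centrality(ls$network)$score[wb$id]
  conn <- function(yr, sp) {
    inv <- wb$id[ls$reported[[paste0(sp, "_", yr)]] == 1]
    asg <- assign_streams(wb, ls$streams, invaded_ids = inv)
    unname(connectivity_to_invaded(asg, inv))
  }
  mk <- function(yr) {
    assemble_covariates(
      wb,
      status_zm = ls$reported[[paste0("zm_", yr)]],
      status_ewm = ls$reported[[paste0("ewm_", yr)]],
      conn_zm = conn(yr, "zm"), conn_ewm = conn(yr, "ewm"),
      centrality = unname(v5), road_scores = unname(ls$road_access),
      year = yr
    )
  }
  list(t1 = mk("t1"), t2 = mk("t2"))
}

# Brute-force Matheron (cross-)semivariogram by explicit double loop.
brute_semivariogram <- function(coords, va, vb = va, lag_size, n_lags) {
  npairs <- rep(0, n_lags)
  ssum <- rep(0, n_lags)
  dsum <- rep(0, n_lags)
  n <- nrow(coords)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      h <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      bin <- floor(h / lag_size) + 1
      if (bin >= 1 && bin <= n_lags) {
        npairs[bin] <- npairs[bin] + 1
        ssum[bin] <- ssum[bin] + (va[i] - va[j]) * (vb[i] - vb[j])
        dsum[bin] <- dsum[bin] + h
      }
    }
  }
  list(gamma = ifelse(npairs > 0, ssum / (2 * npairs), NA_real_),
       npairs = npairs,
       dist = ifelse(npairs > 0, dsum / npairs, NA_real_))
}

# Exhaustive pairwise-concordance AUC (ties count one half).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive shortest-path betweenness on a tiny undirected graph given as
# an edge data frame: enumerate all simple paths per pair by depth-first
# search, keep the shortest, and count interior visits.
brute_betweenness <- function(nodes, edges) {
  adj <- setNames(replicate(length(nodes), character(0), simplify = FALSE),
                  nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(visited))
    out <- list()
    for (nb in adj[[from]]) {
      if (!(nb %in% visited)) {
        out <- c(out, all_paths(nb, to, c(visited, nb)))
      }
    }
    out
  }
  btw <- setNames(rep(0, length(nodes)), nodes)
  pairs <- utils::combn(nodes, 2)
  for (k in seq_len(ncol(pairs))) {
    paths <- all_paths(pairs[1, k], pairs[2, k], pairs[1, k])
    if (length(paths) == 0) next
    lens <- vapply(paths, length, 0L)
    shortest <- paths[lens == min(lens)]
    for (v in nodes) {
      if (v %in% pairs[, k]) next
      frac <- mean(vapply(shortest, function(p) v %in% p, TRUE))
      btw[v] <- btw[v] + frac
    }
  }
  btw
}

# Hand-assembled ordinary co-kriging solve: full dense system over all
# data, no neighborhood logic shared with the implementation.
brute_cokrige <- function(model, data, target) {
  vars <- model$vars
  coords <- do.call(rbind, lapply(vars, function(v) data[[v]]$coords))
  values <- unlist(lapply(vars, function(v) data[[v]]$values))
  vof <- rep(seq_along(vars),
             vapply(vars, function(v) length(data[[v]]$values), 0L))
  N <- length(values)
  covf <- function(i, j, h) {
    g <- switch(model$family,
                spherical = ifelse(h / model$range >= 1, 1,
                                   1.5 * h / model$range -
                                     0.5 * (h / model$range)^3),
                exponential = 1 - exp(-h / model$range))
    model$B0[i, j] * (h < 1e-9) + model$B1[i, j] * (1 - g)
  }
  A <- matrix(0, N + length(vars), N + length(vars))
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      h <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      A[i, j] <- covf(vof[i], vof[j], h)
    }
    A[i, N + vof[i]] <- 1
    A[N + vof[i], i] <- 1
  }
  rhs <- numeric(N + length(vars))
  for (i in seq_len(N)) {
    h <- sqrt(sum((coords[i, ] - target)^2))
    rhs[i] <- covf(vof[i], 1, h)
  }
  rhs[N + 1] <- 1
  sol <- solve(A, rhs)
  list(weights = sol[seq_len(N)], var_of = vof,
       prediction = sum(sol[seq_len(N)] * values))
}

# Construct an LMC model object directly from coefficient matrices.
make_lmc <- function(vars, B0, B1, range, family = "spherical",
                     max_points = 64, radius = Inf) {
  structure(
    list(vars = vars, primary = vars[1], family = family, range = range,
         B0 = B0, B1 = B1, aniso_factor = 1, aniso_angle = 0,
         neighborhood = list(max_points = max_points, radius = radius)),
    class = "cokriging_model"
  )
}
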
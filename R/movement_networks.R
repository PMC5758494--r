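# Boater-traffic network and stream connectivity -------------------------

#' Build the boater-traffic network from survey records
#'
#' Each eligible, completed survey record contributes up to two undirected
#' edges: previous waterbody to station, and station to next waterbody.
#' Missing trip ends contribute nothing, self-loops (previous or next equal
#' to the station) are dropped, and repeated pairs accumulate an integer
#' multiplicity weight. Ineligible records are ignored entirely.
#'
#' @param records `data.frame(station_id, prev_id, next_id, eligible)`;
#'   `NA` marks an absent trip end.
#' @param waterbody_ids Character vector of known waterbody identifiers;
#'   any record referencing an unknown id is a referential-integrity error.
#' @return Object of class `traffic_network`: list with `nodes` (all known
#'   waterbody ids) and `edges`, a data frame `from`, `to`, `weight` with
#'   `from < to` lexicographically.
#' @export
build_traffic_network <- function(records, waterbody_ids) {
  stopifnot(is.character(waterbody_ids), !anyDuplicated(waterbody_ids))
  ref <- c(records$station_id, records$prev_id, records$next_id)
  ref <- ref[!is.na(ref)]
  unknown <- setdiff(unique(ref), waterbody_ids)
  if (length(unknown) > 0) {
    stop("survey records reference unknown waterbodies: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  el <- records[records$eligible, , drop = FALSE]
  from <- c(el$prev_id, el$station_id)
  to <- c(el$station_id, el$next_id)
  keep <- !is.na(from) & !is.na(to) & from != to
  from <- from[keep]
  to <- to[keep]
  a <- pmin(from, to)
  b <- pmax(from, to)
  if (length(a) == 0) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(a, b, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[`, "", 1),
      to = vapply(parts, `[`, "", 2),
      weight = as.integer(tab),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = waterbody_ids, edges = edges),
            class = "traffic_network")
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE)
  )
}

surveyed_nodes <- function(network) {
  unique(c(network$edges$from, network$edges$to))
}

new_centrality <- function(measure, score) {
  structure(list(measure = measure, score = score), class = "centrality")
}

#' Eigenvector centrality of the traffic network
#'
#' Dominant eigenvector of the weighted adjacency matrix of the largest
#' connected component (by node count), computed by dense symmetric
#' eigen-decomposition; the dominant eigenvector of a connected
#' non-negative matrix is sign-fixed to be non-negative
#' (Perron-Frobenius) and normalised to unit Euclidean norm. Nodes outside
#' the largest component, including unsurveyed waterbodies, score 0.
#'
#' @param network A `traffic_network`.
#' @return A `centrality` object; `score` is a named vector over all nodes.
#' @export
eigenvector_centrality <- function(network) {
  if (nrow(network$edges) == 0) {
    stop("traffic network has no edges", call. = FALSE)
  }
  g <- as_igraph(network)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  members <- names(comp$membership)[comp$membership == big]
  sub <- igraph::induced_subgraph(g, members)
  A <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "weight",
                                             sparse = TRUE))
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  score <- setNames(rep(0, length(network$nodes)), network$nodes)
  score[igraph::V(sub)$name] <- v
  new_centrality("eigenvector", score)
}

#' Betweenness centrality of the traffic network
#'
#' Shortest-path betweenness over unweighted hop counts (edge
#' multiplicities carry visit intensity, not a distance, so they are not
#' used as path lengths).
#'
#' @param network A `traffic_network`.
#' @return A `centrality` object with non-negative scores over all nodes.
#' @export
betweenness_centrality <- function(network) {
  if (nrow(network$edges) == 0) {
    stop("traffic network has no edges", call. = FALSE)
  }
  g <- as_igraph(network)
  b <- igraph::betweenness(g, weights = NA, directed = FALSE)
  new_centrality("betweenness", b[network$nodes])
}

#' Weighted degree centrality of the traffic network
#'
#' Sum of incident edge multiplicities per node.
#'
#' @param network A `traffic_network`.
#' @return A `centrality` object.
#' @export
degree_centrality <- function(network) {
  if (nrow(network$edges) == 0) {
    stop("traffic network has no edges", call. = FALSE)
  }
  score <- setNames(rep(0, length(network$nodes)), network$nodes)
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    score[e$from] <- score[e$from] + e$weight
    score[e$to] <- score[e$to] + e$weight
  }
  new_centrality("degree", score)
}

#' Choose the centrality measure most correlated with invasion status
#'
#' Computes the Pearson correlation of each candidate centrality with each
#' species' invasion status and returns the measure maximising the mean
#' correlation over species. Ties break by the fixed order eigenvector >
#' betweenness > degree; zero-variance vectors are skipped with a warning.
#'
#' @param centralities Named list of `centrality` objects (names are
#'   measures).
#' @param status Data frame or named list of per-species 0/1 status vectors
#'   aligned with the centrality score names.
#' @return List: `measure` (chosen name), `correlations` (measure x species
#'   matrix of Pearson r).
#' @export
select_centrality <- function(centralities, status) {
  stopifnot(length(centralities) >= 1)
  order_pref <- c("eigenvector", "betweenness", "degree")
  measures <- names(centralities)
  status <- as.data.frame(status)
  cors <- matrix(NA_real_, length(measures), ncol(status),
                 dimnames = list(measures, names(status)))
  for (m in measures) {
    sc <- centralities[[m]]$score
    if (stats::sd(sc) == 0) {
      warning("centrality '", m, "' has zero variance; skipped",
              call. = FALSE)
      next
    }
    for (sp in names(status)) {
      st <- status[[sp]]
      if (stats::sd(st) == 0) next
      cors[m, sp] <- cor(sc, st)
    }
  }
  mean_r <- rowMeans(cors, na.rm = TRUE)
  mean_r[!is.finite(mean_r)] <- NA_real_
  if (all(is.na(mean_r))) {
    stop("no centrality measure has a defined correlation", call. = FALSE)
  }
  best <- max(mean_r, na.rm = TRUE)
  cand <- measures[!is.na(mean_r) & mean_r == best]
  pref <- intersect(order_pref, cand)
  chosen <- if (length(pref) > 0) pref[1] else cand[1]
  list(measure = chosen, correlations = cors)
}

#' Assign waterbodies to streams by geometric intersection
#'
#' A waterbody is assigned the kittle ids of every stream polyline it lies
#' on (within a numerical tolerance). An invaded waterbody that intersects
#' no stream is additionally assigned its nearest stream within the buffer
#' distance; beyond the buffer nothing is assigned.
#'
#' @param waterbodies `data.frame(id, x, y, ...)`.
#' @param streams List of `list(kittle_id, vertices)` polylines.
#' @param invaded_ids Waterbody ids treated as invaded for the buffer rule
#'   (default none).
#' @param buffer_km Buffer distance for invaded waterbodies (default 0.1 km,
#'   i.e. 100 m).
#' @param tol Intersection tolerance in km.
#' @return Named list mapping each waterbody id to a character vector of
#'   kittle ids (possibly empty).
#' @export
assign_streams <- function(waterbodies, streams, invaded_ids = character(0),
                           buffer_km = 0.1, tol = 1e-6) {
  n <- nrow(waterbodies)
  if (length(streams) == 0) {
    return(setNames(replicate(n, character(0), simplify = FALSE),
                    waterbodies$id))
  }
  dmat <- matrix(NA_real_, n, length(streams))
  kids <- vapply(streams, function(s) s$kittle_id, "")
  for (j in seq_along(streams)) {
    dmat[, j] <- point_polyline_distance(waterbodies$x, waterbodies$y,
                                         streams[[j]]$vertices)
  }
  out <- vector("list", n)
  invaded <- waterbodies$id %in% invaded_ids
  for (i in seq_len(n)) {
    hit <- which(dmat[i, ] <= tol)
    if (length(hit) == 0 && invaded[i]) {
      j <- which.min(dmat[i, ])
      if (dmat[i, j] <= buffer_km) hit <- j
    }
    out[[i]] <- kids[hit]
  }
  setNames(out, waterbodies$id)
}

# Flag (0/1) waterbodies sharing at least one route id with any of the
# given invaded waterbodies.  Shared core of connectivity_to_invaded and
# the generator's second-census connectivity effect.
shared_route_flags <- function(assignments, invaded_ids) {
  invaded_routes <- unique(unlist(assignments[
    names(assignments) %in% invaded_ids
  ], use.names = FALSE))
  if (length(invaded_routes) == 0) {
    return(setNames(rep(0, length(assignments)), names(assignments)))
  }
  flags <- vapply(assignments, function(k) {
    as.numeric(length(k) > 0 && any(k %in% invaded_routes))
  }, numeric(1))
  setNames(flags, names(assignments))
}

#' Connectivity to an invaded waterbody via shared stream routes
#'
#' A waterbody is flagged connected when it shares at least one kittle id
#' with any invaded waterbody; spread is assumed both up- and downstream,
#' so flow direction is ignored. Invaded waterbodies assigned to a stream
#' are themselves flagged. Computed separately per species and census by
#' passing the relevant invaded set.
#'
#' @param assignments Waterbody-to-stream map from [assign_streams()].
#' @param invaded_ids Ids of invaded waterbodies for one species and
#'   census.
#' @return Named 0/1 vector over all waterbodies in `assignments`.
#' @export
connectivity_to_invaded <- function(assignments, invaded_ids) {
  shared_route_flags(assignments, invaded_ids)
}
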
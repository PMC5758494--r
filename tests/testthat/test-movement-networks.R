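records <- function(...) {
  rows <- list(...)
  data.frame(
    station_id = vapply(rows, `[[`, "", 2),
    prev_id = vapply(rows, function(r) r[[1]] %||% NA_character_, ""),
    next_id = vapply(rows, function(r) r[[3]] %||% NA_character_, ""),
    eligible = vapply(rows, function(r) isTRUE(r$eligible %||% TRUE), TRUE),
    stringsAsFactors = FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("each completed survey contributes exactly two edges", {
  net <- build_traffic_network(
    records(list("A", "B", "C")), c("A", "B", "C")
  )
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("A B", "B C"))
  expect_true(all(net$edges$weight == 1))

  # a missing trip end yields a single edge
  one <- build_traffic_network(
    records(list(NULL, "B", "C")), c("A", "B", "C")
  )
  expect_equal(nrow(one$edges), 1)

  # repeated pairs accumulate multiplicity; direction is ignored
  two <- build_traffic_network(
    records(list("A", "B", NULL), list("B", "A", NULL)),
    c("A", "B")
  )
  expect_equal(two$edges$weight, 2)

  # ineligible records and self-loops contribute nothing
  empty <- build_traffic_network(
    records(list("A", "B", "C", eligible = FALSE), list("B", "B", NULL)),
    c("A", "B", "C")
  )
  expect_equal(nrow(empty$edges), 0)

  expect_error(
    build_traffic_network(records(list("A", "Z", NULL)), c("A", "B")),
    "unknown"
  )
})

test_that("network construction is permutation invariant", {
  cfg <- landscape_config(n_waterbodies = 60, survey_count = 500, seed = 9)
  wb <- generate_waterbodies(cfg)
  sv <- generate_surveys(wb, config = cfg)
  n1 <- build_traffic_network(sv, wb$id)
  perm <- with_substream(1, "perm", sample(nrow(sv)))
  n2 <- build_traffic_network(sv[perm, ], wb$id)
  expect_identical(n1$edges, n2$edges)
})

test_that("eigenvector centrality matches closed forms on canonical graphs", {
  # complete graph on 4 nodes: all scores equal, 0.5 after unit norm
  k4 <- build_traffic_network(
    records(list("A", "B", NULL), list("A", "C", NULL),
            list("A", "D", NULL), list("B", "C", NULL),
            list("B", "D", NULL), list("C", "D", NULL)),
    c("A", "B", "C", "D")
  )
  ek4 <- eigenvector_centrality(k4)
  expect_equal(unname(ek4$score), rep(0.5, 4), tolerance = 1e-10)

  # star: hub-to-leaf ratio sqrt(3)
  star <- build_traffic_network(
    records(list("H", "L1", NULL), list("H", "L2", NULL),
            list("H", "L3", NULL)),
    c("H", "L1", "L2", "L3")
  )
  es <- eigenvector_centrality(star)
  expect_equal(es$score[["H"]] / es$score[["L1"]], sqrt(3),
               tolerance = 1e-10)

  # path A-B-C: centre-to-end ratio sqrt(2)
  path <- build_traffic_network(
    records(list("A", "B", "C")), c("A", "B", "C")
  )
  ep <- eigenvector_centrality(path)
  expect_equal(ep$score[["B"]] / ep$score[["A"]], sqrt(2),
               tolerance = 1e-10)
  expect_equal(sqrt(sum(ep$score^2)), 1, tolerance = 1e-12)

  expect_error(
    eigenvector_centrality(
      build_traffic_network(records(list("A", "B", NULL))[0, ],
                            c("A", "B"))
    ),
    "no edges"
  )
})

test_that("eigenvector centrality agrees with an independent solver on random graphs", {
  for (s in 1:8) {
    cfg <- landscape_config(n_waterbodies = 8, survey_count = 12,
                            missing_end_prob = 0.2,
                            ineligible_fraction = 0, seed = s)
    wb <- generate_waterbodies(cfg)
    sv <- generate_surveys(wb, config = cfg)
    net <- build_traffic_network(sv, wb$id)
    if (nrow(net$edges) == 0) next
    ours <- eigenvector_centrality(net)$score
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    comp <- igraph::components(g)
    big <- igraph::induced_subgraph(
      g, names(comp$membership)[comp$membership == which.max(comp$csize)]
    )
    ref <- igraph::eigen_centrality(big,
                                    weights = igraph::E(big)$weight)$vector
    ref <- ref / sqrt(sum(ref^2))
    expect_equal(ours[names(ref)], ref, tolerance = 1e-8)
    off <- setdiff(net$nodes, names(ref))
    expect_true(all(ours[off] == 0))
  }
})

test_that("betweenness and degree match canonical values and a brute-force oracle", {
  path <- build_traffic_network(
    records(list("A", "B", "C")), c("A", "B", "C")
  )
  b <- betweenness_centrality(path)$score
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))
  d <- degree_centrality(path)$score
  expect_equal(unname(d[c("A", "B", "C")]), c(1, 2, 1))

  # complete graph: no shortest path passes through an interior node
  k4 <- build_traffic_network(
    records(list("A", "B", NULL), list("A", "C", NULL),
            list("A", "D", NULL), list("B", "C", NULL),
            list("B", "D", NULL), list("C", "D", NULL)),
    c("A", "B", "C", "D")
  )
  expect_true(all(betweenness_centrality(k4)$score == 0))

  for (s in 1:6) {
    cfg <- landscape_config(n_waterbodies = 7, survey_count = 10,
                            ineligible_fraction = 0, seed = s + 100)
    wb <- generate_waterbodies(cfg)
    sv <- generate_surveys(wb, config = cfg)
    net <- build_traffic_network(sv, wb$id)
    if (nrow(net$edges) == 0) next
    ours <- betweenness_centrality(net)$score
    oracle <- brute_betweenness(net$nodes, net$edges)
    expect_equal(ours[net$nodes], oracle[net$nodes], tolerance = 1e-10)
  }
})

test_that("centrality selection maximises mean correlation with fixed tie order", {
  mk <- function(score) structure(list(measure = "x", score = score),
                                  class = "centrality")
  status <- list(zm = c(1, 0, 0, 1, 0), ewm = c(0, 1, 0, 1, 0))
  strong <- mk(c(2, 1, 0, 3, 0))
  weak <- mk(c(0, 0, 1, 0, 2))
  sel <- select_centrality(
    list(eigenvector = weak, betweenness = strong, degree = weak), status
  )
  expect_equal(sel$measure, "betweenness")
  # hand-computed Pearson correlations
  expect_equal(sel$correlations["betweenness", "zm"],
               cor(c(2, 1, 0, 3, 0), c(1, 0, 0, 1, 0)), tolerance = 1e-12)

  # exact ties resolve eigenvector > betweenness > degree
  tie <- select_centrality(
    list(degree = strong, eigenvector = strong, betweenness = strong),
    status
  )
  expect_equal(tie$measure, "eigenvector")

  expect_warning(
    select_centrality(
      list(eigenvector = mk(rep(1, 5)), degree = strong), status
    ),
    "zero variance"
  )
})

test_that("stream assignment honors intersection, buffer, and cutoff rules", {
  wb <- data.frame(id = c("A", "B", "C"),
                   x = c(0, 1, 2), y = c(0, 0.09, 0.15),
                   stringsAsFactors = FALSE)
  streams <- list(list(kittle_id = "H026",
                       vertices = cbind(c(-1, 3), c(0, 0))))
  # A lies on the stream; B is within the 100 m buffer but only assigned
  # when invaded; C is beyond the buffer always
  asg <- assign_streams(wb, streams)
  expect_equal(asg$A, "H026")
  expect_equal(length(asg$B), 0)
  asg_inv <- assign_streams(wb, streams, invaded_ids = c("B", "C"))
  expect_equal(asg_inv$B, "H026")
  expect_equal(length(asg_inv$C), 0)
})

test_that("connectivity flags propagate along shared kittle ids", {
  asg <- list(A = "H026", B = "H026", C = "H031", D = character(0))
  conn <- connectivity_to_invaded(asg, "A")
  expect_equal(unname(conn[c("A", "B", "C", "D")]), c(1, 1, 0, 0))
  expect_equal(sum(connectivity_to_invaded(asg, character(0))), 0)

  # symmetry of the sharing relation and idempotence
  conn_b <- connectivity_to_invaded(asg, "B")
  expect_equal(conn_b[["A"]], 1)
  expect_identical(conn, connectivity_to_invaded(asg, "A"))

  # random fixture equals a brute-force pairwise shared-id scan
  cfg <- landscape_config(n_waterbodies = 50, n_streams = 8, seed = 31)
  wb <- generate_waterbodies(cfg)
  geo <- generate_streams_roads(cfg, wb)
  invaded <- wb$id[c(3, 17, 40)]
  asg50 <- assign_streams(wb, geo$streams, invaded_ids = invaded)
  ours <- connectivity_to_invaded(asg50, invaded)
  brute <- vapply(wb$id, function(id) {
    as.numeric(any(vapply(invaded, function(iv) {
      length(intersect(asg50[[id]], asg50[[iv]])) > 0
    }, TRUE)))
  }, numeric(1))
  expect_equal(unname(ours[wb$id]), unname(brute))
})
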
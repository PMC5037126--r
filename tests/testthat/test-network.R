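test_that("build_network validates its edge table", {
  rn <- make_repnodes(c("n1", "n2", "n3"))
  ssn <- build_network(rn, make_edges("n1", "n2", -20), stringency = -5)
  expect_s3_class(ssn, "ssn")
  expect_equal(nrow(ssn$edges), 1L)

  empty <- build_network(rn, make_edges(character(), character(), numeric()),
                         stringency = -5)
  expect_equal(nrow(empty$edges), 0L)

  expect_error(build_network(rn, make_edges("n1", "zz", -20)), "zz")
  expect_error(build_network(
    rn, make_edges(c("n1", "n2"), c("n2", "n1"), c(-20, -30))), "duplicate")
  expect_error(build_network(
    rn, data.frame(query_id = "n1", subject_id = "n1", logE = -20,
                   pct_identity = 100)), "self-edges")
  expect_error(build_network(rn, make_edges("n1", "n2", -3),
                             stringency = -5), "stringency")
})

test_that("thresholding keeps <= semantics and refuses to loosen", {
  rn <- make_repnodes(sprintf("n%d", 1:4))
  ssn <- build_network(rn, make_edges(c("n1", "n1", "n2"),
                                      c("n2", "n3", "n4"),
                                      c(-10, -20, -60)), stringency = -5)
  at13 <- apply_threshold(ssn, -13)
  expect_equal(sort(at13$edges$logE), c(-60, -20))
  at56 <- apply_threshold(at13, -56)
  expect_equal(at56$edges$logE, -60)
  expect_equal(apply_threshold(at13, -13)$edges, at13$edges)  # identity
  expect_error(apply_threshold(at56, -13), "loosen")
  expect_equal(nrow(at56$nodes), 4L)  # nodes are never removed
})

test_that("connected components label clusters canonically", {
  rn <- make_repnodes(sprintf("n%d", 1:5))
  ssn <- build_network(rn, make_edges(c("n1", "n2", "n4"),
                                      c("n2", "n3", "n5"),
                                      c(-10, -12, -15)), stringency = -5)
  p <- connected_components(ssn)
  expect_equal(unname(p$assignment[c("n1", "n2", "n3")]), rep("n1", 3))
  expect_equal(unname(p$assignment[c("n4", "n5")]), rep("n4", 2))
  expect_equal(sort(p$clusters$label), c("n1", "n4"))
  expect_equal(sum(p$clusters$protein_count), 5L)

  edgeless <- build_network(rn, make_edges(character(), character(),
                                           numeric()), stringency = -5)
  p0 <- connected_components(edgeless)
  expect_equal(nrow(p0$clusters), 5L)
  expect_equal(unname(p0$assignment), rn$rep_id)

  # complete graph collapses to one component
  pairs <- t(combn(rn$rep_id, 2))
  full <- build_network(rn, make_edges(pairs[, 1], pairs[, 2],
                                       rep(-30, nrow(pairs))),
                        stringency = -5)
  expect_equal(nrow(connected_components(full)$clusters), 1L)

  # labels are invariant to node input order
  perm <- rn[c(3, 1, 5, 2, 4), ]
  ssn_p <- build_network(perm, make_edges(c("n1", "n2", "n4"),
                                          c("n2", "n3", "n5"),
                                          c(-10, -12, -15)), stringency = -5)
  p2 <- connected_components(ssn_p)
  expect_equal(p2$assignment[names(p$assignment)], p$assignment)
})

test_that("threshold sweeps refine and conserve protein totals", {
  set.seed(77)
  n <- 30
  rn <- make_repnodes(sprintf("n%02d", 1:n),
                      sizes = sample(1:5, n, replace = TRUE))
  pairs <- t(combn(rn$rep_id, 2))
  keep <- sample(nrow(pairs), 90)
  edges <- make_edges(pairs[keep, 1], pairs[keep, 2],
                      runif(90, -70, -6))
  ssn <- build_network(rn, edges, stringency = -5)
  chain <- c(-13, -20, -30, -56, -65)   # classic preset
  parts <- threshold_sweep(ssn, chain)
  expect_equal(length(parts), 5L)
  total <- sum(rn$size)
  for (p in parts) expect_equal(sum(p$clusters$protein_count), total)
  # refinement: clusters at a stricter threshold nest inside looser ones
  for (k in 2:length(parts)) {
    loose <- parts[[k - 1]]$assignment
    strict <- parts[[k]]$assignment
    expect_true(all(tapply(loose[names(strict)], strict,
                           function(x) length(unique(x))) == 1L))
  }
  # component count never decreases as stringency rises
  ncomp <- vapply(parts, function(p) nrow(p$clusters), integer(1))
  expect_true(all(diff(ncomp) >= 0))

  expect_error(threshold_sweep(ssn, c(-20, -13)), "decreasing")
  expect_error(threshold_sweep(ssn, c(-4, -20)), "stringency")

  single <- threshold_sweep(ssn, -25)[[1]]
  direct <- connected_components(apply_threshold(ssn, -25))
  expect_equal(single$assignment, direct$assignment)
})

test_that("major clusters use a strict protein-count cut", {
  rn <- make_repnodes(c("a", "b", "c", "d"), sizes = c(60, 51, 50, 3))
  ssn <- build_network(rn, make_edges(character(), character(), numeric()),
                       stringency = -5)
  p <- connected_components(ssn)
  expect_equal(major_clusters(p, 50), c("a", "b"))
  expect_equal(major_clusters(p, 100), character(0))
  expect_equal(major_clusters(p, 1), c("a", "b", "c", "d"))
})

test_that("graph exports round-trip and carry node attributes", {
  rec <- toy_records()
  rn <- make_repnodes(c("r1", "r3"),
                      member_ids = list(c("r1", "r2"), c("r3", "r4", "r5")))
  ssn <- build_network(rn, make_edges("r1", "r3", -25), records = rec,
                       stringency = -5)
  pre <- withr::local_tempfile()
  paths <- export_graph(ssn, pre, "edge-tsv")
  back <- read_edges(paths[1])
  expect_equal(back$node_a, ssn$edges$node_a)
  expect_equal(back$logE, ssn$edges$logE, tolerance = 1e-12)
  nodes <- read.delim(paths[2])
  expect_equal(nrow(nodes), 2L)
  expect_true(all(c("kingdom_major", "has_characterized", "size",
                    "substrate_summary") %in% names(nodes)))
  expect_equal(nodes$kingdom_major[nodes$rep_id == "r1"], "animal")

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(ssn, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 1)
  expect_equal(sort(igraph::V(g)$name), c("r1", "r3"))

  xg <- withr::local_tempfile(fileext = ".xgmml")
  export_graph(ssn, xg, "xgmml")
  txt <- readLines(xg)
  expect_equal(sum(grepl("<node ", txt)), 2L)
  expect_equal(sum(grepl("<edge ", txt)), 1L)

  expect_error(export_graph(ssn, pre, "dot"))
})

test_that("saved SSNs reload with identical structure", {
  gen <- generate(synth_config(seed = 9, n_families = 2,
                               subfamilies_per_family = 1,
                               seqs_per_subfamily = 5, n_background = 4))
  pipe <- ssn_pipeline(gen$records)
  part <- connected_components(pipe$ssn)
  summ <- summarize_clusters(part, pipe$records)
  dir <- withr::local_tempdir()
  save_ssn(pipe$ssn, pipe$records, dir, summaries = summ)
  back <- load_ssn(dir)
  expect_equal(back$ssn$stringency, pipe$ssn$stringency)
  expect_equal(back$ssn$edges$node_a, pipe$ssn$edges$node_a)
  expect_equal(back$ssn$edges$logE, pipe$ssn$edges$logE, tolerance = 1e-9)
  expect_equal(back$ssn$nodes$all_fused_b5, pipe$ssn$nodes$all_fused_b5)
  p2 <- connected_components(back$ssn)
  expect_equal(p2$assignment, part$assignment)
  expect_equal(back$summaries$consensus_substrate, summ$consensus_substrate)
})
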
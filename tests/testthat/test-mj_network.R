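test_that("pairwise distances count determinate differing characters", {
  m <- rbind(h1 = c("0", "0", "0"), h2 = c("1", "1", "0"))
  expect_equal(pairwise_distances(m)["h1", "h2"], 2L)
  expect_equal(pairwise_distances(m)["h1", "h1"], 0L)
  for (s in 1:6) {
    set.seed(s)
    mm <- matrix(sample(c("0", "1"), 72, TRUE), 6, 12,
                 dimnames = list(paste0("h", 1:6), NULL))
    expect_equal(unname(pairwise_distances(mm)), unname(brute_pairwise(mm)))
    mm[sample(72, 8)] <- NA
    expect_equal(unname(pairwise_distances(mm)), unname(brute_pairwise(mm)))
  }
})

test_that("degenerate median-joining inputs behave", {
  one <- matrix(c("0", "1"), 1, 2, dimnames = list("h1", NULL))
  net1 <- median_joining(one)
  expect_equal(nrow(net1$states), 1L)
  expect_equal(nrow(net1$edges), 0L)
  two <- rbind(h1 = c("0", "0"), h2 = c("0", "1"))
  net2 <- median_joining(two)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$weight, 1L)
  expect_equal(sum(net2$kind == "median"), 0L)
  expect_error(median_joining(two, epsilon = -1), "epsilon")
  expect_error(median_joining(two, epsilon = NA), "epsilon")
})

test_that("the classic three-haplotype case yields exactly one median", {
  m <- rbind(h1 = c("0", "0", "0"), h2 = c("1", "1", "0"), h3 = c("1", "0", "1"))
  net <- median_joining(m)
  expect_equal(sum(net$kind == "median"), 1L)
  med <- net$states[net$kind == "median", ]
  expect_equal(unname(med), c("1", "0", "0"))
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$weight == 1L))
})

test_that("every observed MST connection survives as a bottleneck-bounded path", {
  # median insertion may replace a direct MST link by a refined path; the
  # connection must persist using only links no heavier than the MST edge
  for (s in 1:15) {
    set.seed(s)
    n <- sample(3:6, 1); k <- sample(3:8, 1)
    m <- unique(matrix(sample(c("0", "1"), n * k, TRUE), n, k))
    rownames(m) <- paste0("h", seq_len(nrow(m)))
    if (nrow(m) < 2) next
    net <- median_joining(m)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = rownames(net$states))
    gd <- igraph::distances(g, weights = igraph::E(g)$weight)
    # independent MST oracle on the observed haplotypes
    d <- brute_pairwise(m)
    dimnames(d) <- list(rownames(m), rownames(m))
    go <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
    mst <- igraph::as_data_frame(igraph::mst(go, weights = igraph::E(go)$weight))
    for (e in seq_len(nrow(mst))) {
      u <- mst$from[e]
      v <- mst$to[e]
      w <- d[match(u, rownames(m)), match(v, rownames(m))]
      keep <- net$edges$weight <= w
      gb <- igraph::graph_from_data_frame(net$edges[keep, , drop = FALSE],
                                          directed = FALSE,
                                          vertices = rownames(net$states))
      expect_true(is.finite(igraph::distances(gb, u, v)[1, 1]))
    }
    # medians lie in the metric span: on a geodesic between observed pairs
    obs <- rownames(m)
    for (md in rownames(net$states)[net$kind == "median"]) {
      on_path <- FALSE
      for (a in obs) for (b in obs) {
        if (a == b) next
        if (abs(gd[a, md] + gd[md, b] - gd[a, b]) < 1e-9) on_path <- TRUE
      }
      expect_true(on_path)
    }
  }
})

test_that("median-joining output is invariant to haplotype input order", {
  for (s in 1:6) {
    set.seed(100 + s)
    m <- unique(matrix(sample(c("0", "1"), 5 * 6, TRUE), 5, 6))
    rownames(m) <- paste0("h", seq_len(nrow(m)))
    net1 <- median_joining(m)
    perm <- sample(nrow(m))
    m2 <- m[perm, , drop = FALSE]
    rownames(m2) <- paste0("h", seq_len(nrow(m2)))
    net2 <- median_joining(m2)
    expect_equal(network_edge_keys(net1), network_edge_keys(net2))
  }
})

test_that("multistate ties expand to quasi-medians deterministically", {
  m <- rbind(h1 = c("A", "A"), h2 = c("C", "A"), h3 = c("G", "A"))
  # all three edges in MSN (pairwise distance 1 each), median char1 is a
  # 3-way tie -> quasi-medians are the parental states, already present
  net <- median_joining(m)
  expect_equal(sum(net$kind == "median"), 0L)
  # frequencies are carried for display from a recoded matrix
  a <- multi_aln(c(s1 = "AATT", s2 = "AATT", s3 = "ACTT", s4 = "ACTA"))
  rm <- recode(a)
  net2 <- median_joining(rm)
  expect_equal(unname(net2$frequency["h1"]), 2L)
})

test_that("group collapsing computes dimensions and minimum between-group edges", {
  # path a-b-c-d with unit edges
  edges <- data.frame(u = c("a", "b", "c"), v = c("b", "c", "d"),
                      weight = c(1L, 1L, 1L))
  states <- matrix(c("0","0","0", "1","0","0", "1","1","0", "1","1","1"),
                   4, 3, byrow = TRUE, dimnames = list(c("a","b","c","d"), NULL))
  net <- structure(list(states = states, kind = rep("observed", 4),
                        frequency = stats::setNames(rep(1L, 4), c("a","b","c","d")),
                        edges = edges), class = "haplo_network")
  cn <- collapse_groups(net, c(a = "G1", b = "G1", c = "G2", d = "G2"))
  expect_equal(unname(cn$dimension), c(1, 1))
  expect_equal(nrow(cn$group_edges), 1L)
  expect_equal(cn$group_edges$weight, 1L)
  # singleton groups: identity collapse
  cs <- collapse_groups(net, c(a = "1", b = "2", c = "3", d = "4"))
  expect_equal(unname(cs$dimension), rep(0, 4))
  expect_equal(sort(cs$group_edges$weight), sort(edges$weight))
  # total collapse
  ct <- collapse_groups(net, c(a = "all", b = "all", c = "all", d = "all"))
  expect_equal(length(ct$groups), 1L)
  expect_equal(nrow(ct$group_edges), 0L)
  expect_equal(unname(ct$dimension), 3)
  # missing nodes rejected without auto-assign
  expect_error(collapse_groups(net, c(a = "G1", b = "G1", c = "G2")), "cover")
})

test_that("medians are auto-assigned to the nearest group", {
  m <- rbind(h1 = c("0", "0", "0"), h2 = c("1", "1", "0"), h3 = c("1", "0", "1"))
  net <- median_joining(m)
  cn <- collapse_groups(net, c(h1 = "A", h2 = "B", h3 = "B"))
  med <- rownames(net$states)[net$kind == "median"]
  expect_true(med %in% unlist(cn$groups))
  expect_true(med %in% cn$groups$A)   # equidistant: alphabetically first group
})
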
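test_that("simulations are fully deterministic given the configuration", {
  cfg <- sim_config(seed = 7, n_taxa = 12, seq_length = 300, branch_scale = 0.05,
                    indel_rate = 0.005, lp_rate = 0.002, onm_rate = 0.002,
                    inversion_rate = 0.001)
  t1 <- simulate_tree(cfg); t2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  s1 <- evolve_alignment(t1, cfg); s2 <- evolve_alignment(t2, cfg)
  expect_identical(unclass(s1$alignment)[, ], unclass(s2$alignment)[, ])
  expect_identical(s1$truth$events$start, s2$truth$events$start)
})

test_that("tree shapes have the right size and Yule trees are binary", {
  cfg <- sim_config(seed = 3, n_taxa = 50)
  tr <- simulate_tree(cfg)
  expect_equal(length(tr$tip.label), 50L)
  expect_equal(tr$Nnode, 49L)
  expect_true(all(tr$edge.length > 0))
  expect_error(simulate_tree(sim_config(seed = 1, n_taxa = 1)), "n_taxa")
})

test_that("zero rates on a zero-length tree copy the root everywhere", {
  tr <- ape::read.tree(text = "(a:0,b:0,c:0);")
  cfg <- sim_config(seed = 5, n_taxa = 3, tree_model = "fixed", tree = tr,
                    seq_length = 200)
  sim <- evolve_alignment(tr, cfg)
  m <- unclass(sim$alignment)
  expect_true(all(m[1, ] == m[2, ]) && all(m[1, ] == m[3, ]))
  expect_equal(nrow(sim$truth$events), 0L)
})

test_that("substitution counts match the JC analytic expectation", {
  L <- 10000
  t_tot <- 0.3
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t_tot / 2, t_tot / 2))
  cfg <- sim_config(seed = 17, n_taxa = 2, tree_model = "fixed", tree = tr,
                    seq_length = L, model = subst_model("JC"))
  sim <- evolve_alignment(tr, cfg)
  m <- unclass(sim$alignment)
  p <- 0.75 * (1 - exp(-4 * t_tot / 3))
  diff <- sum(m["a", ] != m["b", ])
  expect_lt(abs(diff - L * p), 3 * sqrt(L * p * (1 - p)))
})

test_that("event channels are independent: each rate controls its own category", {
  base <- list(seed = 23, n_taxa = 10, seq_length = 400, branch_scale = 0.05)
  cfg_ind <- do.call(sim_config, c(base, list(indel_rate = 0.01)))
  sim <- evolve_alignment(simulate_tree(cfg_ind), cfg_ind)
  expect_true(nrow(sim$truth$events) > 0)
  expect_true(all(sim$truth$events$category == "INDEL"))
  cfg_onm <- do.call(sim_config, c(base, list(onm_rate = 0.01)))
  sim2 <- evolve_alignment(simulate_tree(cfg_onm), cfg_onm)
  expect_true(all(sim2$truth$events$category == "ONM"))
  # no channels -> gap-free alignment identical in width to the backbone
  cfg0 <- do.call(sim_config, c(base))
  sim0 <- evolve_alignment(simulate_tree(cfg0), cfg0)
  expect_equal(ncol(sim0$alignment), 400L)
  expect_false(any(unclass(sim0$alignment) == "-"))
})

test_that("planted gap intervals are exactly the gapped columns of the alignment", {
  cfg <- sim_config(seed = 29, n_taxa = 10, seq_length = 400, branch_scale = 0.05,
                    indel_rate = 0.01, lp_rate = 0.004)
  sim <- evolve_alignment(simulate_tree(cfg), cfg)
  m <- unclass(sim$alignment)
  ev <- sim$truth$events
  in_event <- rep(FALSE, ncol(m))
  for (i in seq_len(nrow(ev))) {
    cols <- ev$start[i]:ev$end[i]
    gt <- ev$gap_taxa[[i]]
    if (length(gt) > 0) expect_true(all(m[gt, cols] == "-"))
    in_event[cols] <- TRUE
  }
  expect_false(any(m[, !in_event] == "-"))
})

test_that("inversions reverse-complement the window for carriers only", {
  cfg <- sim_config(seed = 41, n_taxa = 8, seq_length = 300, branch_scale = 0.02,
                    inversion_rate = 0.01)
  sim <- evolve_alignment(simulate_tree(cfg), cfg)
  ev <- sim$truth$events
  expect_true(nrow(ev) > 0)
  expect_true(all(ev$note == "inversion"))
})

test_that("tree-set mixtures hit their weights and are reproducible", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  ts <- simulate_treeset(c(t1, t2), c(0.667, 0.333), 600, seed = 9)
  n1 <- sum(attr(ts, "draws") == 1)
  expect_lt(abs(n1 - 600 * 0.667), 3 * sqrt(600 * 0.667 * 0.333))
  ts2 <- simulate_treeset(c(t1, t2), c(0.667, 0.333), 600, seed = 9)
  expect_identical(attr(ts, "draws"), attr(ts2, "draws"))
  one <- simulate_treeset(c(t1), 1, 5, seed = 2)
  expect_true(all(sapply(one, function(x) ape::write.tree(x) == ape::write.tree(t1))))
})

test_that("leaf base composition converges to the stationary frequencies", {
  freqs <- c(.4, .1, .2, .3)
  cfg <- sim_config(seed = 61, n_taxa = 4, seq_length = 20000,
                    model = subst_model("GTR", rates = rep(1, 6), base_freqs = freqs))
  sim <- evolve_alignment(simulate_tree(cfg), cfg)
  m <- unclass(sim$alignment)
  obs <- table(factor(m[1, ], levels = c("A", "C", "G", "T"))) / ncol(m)
  for (b in 1:4)
    expect_lt(abs(obs[b] - freqs[b]), 3 * sqrt(freqs[b] * (1 - freqs[b]) / 20000))
})

test_that("planted query truths reference real edges and mirror the pendant limit", {
  cfg <- sim_config(seed = 83, n_taxa = 6, seq_length = 300)
  tr <- simulate_tree(cfg)
  ids <- haplonet:::edge_ids(tr)
  for (ek in c(1L, nrow(tr$edge))) {
    pq <- plant_query(tr, ek, cfg)
    expect_true(pq$truth$edge_id %in% ids)
    expect_true("query1" %in% rownames(pq$alignment))
  }
  # pendant -> 0 on a leaf's pendant edge makes the query near-identical to it
  leaf_edge <- which(tr$edge[, 2] == match("t2", tr$tip.label))
  pq0 <- plant_query(tr, leaf_edge, cfg, pendant = 1e-8)
  m <- unclass(pq0$alignment)
  # half the (scaled) pendant edge separates query and leaf; far below the
  # ~0.7 mismatch of unrelated sequences
  expect_lt(mean(m["query1", ] != m["t2", ]), 0.2)
  expect_error(plant_query(tr, 999L, cfg), "invalid edge")
})

test_that("infinite-sites generator yields unique genotypes and fresh mutations", {
  sim <- simulate_infinite_sites(n_genotypes = 12, seed = 4)
  expect_equal(nrow(unique(sim$states)), 12L)
  expect_equal(ncol(sim$states), 11L)
  # every character mutates exactly once: derived state forms one clade of
  # the birth tree (all carriers descend from the genotype that gained it)
  expect_true(all(colSums(sim$states == "1") >= 1))
})
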
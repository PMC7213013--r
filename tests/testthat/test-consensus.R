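test_that("tree sets are read with label checking and empty files flagged", {
  f <- write_temp(rep("((A,B),(C,D));", 3), ".nwk")
  ts <- read_treeset(f)
  expect_length(ts, 3)
  expect_setequal(ts[[1]]$tip.label, c("A", "B", "C", "D"))
  expect_error(read_treeset(f, taxa = c("A", "B", "C")), "unknown taxon")
  empty <- write_temp(character(0), ".nwk")
  expect_warning(ts0 <- read_treeset(empty), "empty")
  expect_length(ts0, 0)
})

test_that("split frequencies count bipartitions; stars and strict consensus behave", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  ident <- structure(rep(c(t1), 5), class = "multiPhylo")
  ss <- split_frequencies(ident)
  expect_true(all(ss$splits$freq == 1))
  expect_equal(nrow(ss$splits), 2L)   # AB and CD
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  s2 <- split_frequencies(structure(c(star), class = "multiPhylo"))
  expect_equal(nrow(s2$splits), 0L)
})

test_that("a 600-tree topology mixture reproduces direct counting exactly", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  ts <- simulate_treeset(c(t1, t2), c(2 / 3, 1 / 3), 600, seed = 71)
  n1 <- sum(attr(ts, "draws") == 1L)
  ss <- split_frequencies(ts)
  expect_equal(sort(ss$splits$count), sort(c(n1, n1, 600 - n1, 600 - n1)))
  expect_equal(ss$splits$freq, ss$splits$count / 600)
  # consensus network: both incompatible splits retained at 0.2, majority only at 0.5
  cn_low <- consensus_network(ss, 0.2)
  expect_equal(nrow(cn_low$splits), 4L)
  comp <- sapply(seq_len(4), function(i) sapply(seq_len(4), function(j)
    haplonet:::splits_compatible(cn_low$splits$key[i], cn_low$splits$key[j])))
  expect_false(all(comp))              # the box is present
  cn_maj <- consensus_network(ss, 0.5)
  expect_equal(sort(cn_maj$splits$count), rep(n1, 2))
  # support for the reference clades
  sup <- clade_support(t1, ts)
  expect_equal(sort(unique(sup$support)), 100 * n1 / 600)
  # reference split absent from all trees scores 0
  t3 <- ape::read.tree(text = "((A,D),(B,C),E);")
  sup3 <- clade_support(t3, ts)
  expect_true(all(sup3$support == 0))
})

test_that("split extraction agrees with an independent rooted-clade oracle", {
  for (s in 1:6) {
    set.seed(600 + s)
    trees <- structure(lapply(1:15, function(i) ape::rtree(8)), class = "multiPhylo")
    taxa <- sort(trees[[1]]$tip.label)
    ss <- split_frequencies(trees, taxa)
    # oracle: root every tree at taxon 1; clades of the rooted trees not
    # containing taxon 1 are exactly the nontrivial splits
    counts <- list()
    for (tr in trees) {
      rt <- ape::root(tr, outgroup = taxa[1], resolve.root = TRUE)
      pp <- ape::prop.part(rt)
      labs <- attr(pp, "labels")
      keys <- unique(vapply(pp, function(cl) {
        side <- sort(labs[cl])
        paste(side, collapse = "|")
      }, character(1)))
      keys <- keys[!vapply(strsplit(keys, "|", fixed = TRUE), function(x)
        taxa[1] %in% x || length(x) <= 1 || length(x) >= length(taxa) - 1,
        logical(1))]
      for (k in keys) counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
    }
    got <- vapply(ss$splits$key, function(k) {
      mask <- strsplit(k, "")[[1]] == "1"
      side <- if (taxa[1] %in% taxa[mask]) taxa[!mask] else taxa[mask]
      paste(sort(side), collapse = "|")
    }, character(1))
    expect_setequal(got, names(counts))
    expect_equal(unname(ss$splits$count[match(names(counts), got)]),
                 unname(unlist(counts)))
  }
})

test_that("consensus threshold is monotone and >0.5 sets are compatible", {
  set.seed(77)
  trees <- structure(lapply(1:20, function(i) ape::rtree(7)), class = "multiPhylo")
  ss <- split_frequencies(trees)
  prev <- Inf
  for (th in c(0.05, 0.2, 0.5, 0.8, 1)) {
    n <- nrow(consensus_network(ss, th)$splits)
    expect_lte(n, prev)
    prev <- n
  }
  maj <- consensus_network(ss, 0.51)$splits$key
  if (length(maj) > 1)
    for (i in seq_along(maj)) for (j in seq_along(maj))
      expect_true(haplonet:::splits_compatible(maj[i], maj[j]))
  expect_error(consensus_network(ss, 0), "threshold")
  expect_error(consensus_network(ss, 1.2), "threshold")
})

test_that("greedy extended-majority consensus keeps all majority splits, compatibly", {
  set.seed(31)
  for (s in 1:4) {
    trees <- structure(lapply(1:12, function(i) ape::rtree(8)), class = "multiPhylo")
    ss <- split_frequencies(trees)
    emc <- extended_majority_consensus(ss)
    maj <- ss$splits$key[ss$splits$freq > 0.5]
    expect_true(all(maj %in% emc$splits$key))
    ks <- emc$splits$key
    for (i in seq_along(ks)) for (j in seq_along(ks))
      expect_true(haplonet:::splits_compatible(ks[i], ks[j]))
  }
})

test_that("bootstopping converges immediately on identical trees and is seed-deterministic", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  ident <- structure(rep(c(t1), 200), class = "multiPhylo")
  bs <- bootstop(ident, step = 50, permutations = 25, seed = 5)
  expect_true(bs$converged)
  expect_equal(bs$nbs, 50L)
  expect_equal(bs$checkpoints$prop_converged[1], 1)
  bs2 <- bootstop(ident, step = 50, permutations = 25, seed = 5)
  expect_identical(bs$checkpoints, bs2$checkpoints)
  expect_error(bootstop(ident, step = 1), "step")
  expect_error(bootstop(ident, permutations = 0), "permutations")
})

test_that("stable topology mixtures bootstop consistently across seeds", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  nbs <- sapply(1:3, function(s) {
    ts <- simulate_treeset(c(t1, t2), c(0.85, 0.15), 300, seed = 40 + s)
    bootstop(ts, step = 50, permutations = 50, seed = s)$nbs
  })
  expect_lte(diff(range(nbs)), 50L)
})

test_that("an adversarial alternating prefix delays convergence versus an iid shuffle", {
  tA <- ape::read.tree(text = "((A,B),(C,D),E);")
  tB <- ape::read.tree(text = "((A,C),(B,D),E);")
  # multiset: 50 B up front interleaved with 50 A, then 200 A
  adv <- structure(c(rep(c(tA, tB), 50), rep(c(tA), 200)), class = "multiPhylo")
  set.seed(8)
  iid <- adv[sample(length(adv))]
  class(iid) <- "multiPhylo"
  b_adv <- bootstop(adv, step = 50, permutations = 30, seed = 2)
  b_iid <- bootstop(iid, step = 50, permutations = 30, seed = 2)
  expect_gt(b_adv$nbs, b_iid$nbs)
})

test_that("split systems export as a SplitsTree NEXUS splits block", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  ss <- split_frequencies(structure(rep(c(t1), 3), class = "multiPhylo"))
  f <- tempfile(fileext = ".nex")
  write_splits_nexus(ss, f)
  txt <- readLines(f)
  expect_true(any(grepl("BEGIN Splits;", txt)))
  expect_true(any(grepl("nsplits=2", txt)))
})
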
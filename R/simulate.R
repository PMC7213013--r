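# Seeded synthetic data: trees, sequences with planted indel / tract /
# motif / inversion events, infinite-sites genotype samples, tree-set
# mixtures and planted query placements. Everything is deterministic given
# the configuration seed; event channels are independent, so disabling a
# rate removes exactly that category from the recorded truth.

#' Simulation configuration
#'
#' @param seed integer seed; identical configurations give identical
#'   outputs.
#' @param n_taxa number of leaves.
#' @param tree_model `"yule"`, `"coalescent"` or `"fixed"` (supply `tree`).
#' @param tree optional fixed `phylo` (for `tree_model = "fixed"`).
#' @param seq_length sites in the substitution backbone.
#' @param model a [subst_model()] (default HKY, kappa 2).
#' @param branch_scale multiplier applied to simulated branch lengths;
#'   default 0.1 puts pairwise divergences in the few-percent range typical
#'   of intrageneric plastid spacers.
#' @param indel_rate,lp_rate,onm_rate,inversion_rate events per site per
#'   unit branch length (defaults 0: channels off unless requested).
#' @param indel_mean_length mean of the geometric indel length (default 4).
#' @param lp_tract_length planted homopolymer tract width (default 6).
#' @param onm_width,inversion_width motif window widths.
#' @param insertion_prob probability that an indel event is a duplication
#'   rather than a deletion (default 0.2: duplications and deletions
#'   dominate over insertions in plastid spacers).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_taxa = 10L, tree_model = c("yule", "coalescent", "fixed"),
                       tree = NULL, seq_length = 1000L, model = subst_model("HKY", kappa = 2),
                       branch_scale = 0.1, indel_rate = 0, lp_rate = 0,
                       onm_rate = 0, inversion_rate = 0,
                       indel_mean_length = 4, lp_tract_length = 6L,
                       onm_width = 5L, inversion_width = 6L,
                       insertion_prob = 0.2) {
  tree_model <- match.arg(tree_model)
  stopifnot(seq_length >= 1L, n_taxa >= 2L,
            indel_rate >= 0, lp_rate >= 0, onm_rate >= 0, inversion_rate >= 0)
  if (tree_model == "fixed" && is.null(tree)) stop("tree_model='fixed' needs a tree")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a binary tree
#'
#' @param cfg a [sim_config()].
#' @return `phylo` with `n_taxa` leaves `t1..tn` and positive branch
#'   lengths, deterministic given `cfg$seed`.
#' @export
simulate_tree <- function(cfg) {
  if (cfg$n_taxa < 2L) stop("n_taxa must be >= 2")
  set.seed(cfg$seed)
  tr <- switch(cfg$tree_model,
    yule = ape::rphylo(cfg$n_taxa, birth = 1, death = 0),
    coalescent = ape::rcoal(cfg$n_taxa),
    fixed = cfg$tree)
  if (cfg$tree_model != "fixed") {
    tr$tip.label <- paste0("t", seq_len(cfg$n_taxa))
    tr$edge.length <- tr$edge.length * cfg$branch_scale
    tr$edge.length[tr$edge.length <= 0] <- 1e-6
  }
  tr
}

# indices of tips below each edge's child
edge_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (k in seq_len(nrow(po$edge)))
    below[[po$edge[k, 1L]]] <- c(below[[po$edge[k, 1L]]], below[[po$edge[k, 2L]]])
  lapply(tree$edge[, 2L], function(ch) sort(below[[ch]]))
}

# simulate substitution states (integers 1..4) down the tree
simulate_states <- function(tree, model, L) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  root <- po$edge[nrow(po$edge), 1L]
  pre <- rev(seq_len(nrow(po$edge)))         # parent-before-child order
  states <- matrix(NA_integer_, ntip + tree$Nnode, L)
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = model$base_freqs)
  for (k in pre) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    P <- prob_matrix(model, po$edge.length[k])
    s <- states[p, ]
    out <- integer(L)
    for (from in 1:4) {
      sel <- which(s == from)
      if (length(sel))
        out[sel] <- sample.int(4L, length(sel), replace = TRUE, prob = P[from, ])
    }
    states[ch, ] <- out
  }
  states[seq_len(ntip), , drop = FALSE]
}

#' Evolve an alignment on a tree with planted mutation events
#'
#' Substitutions follow the configured model; on top of that, four event
#' channels run as Poisson processes on branches, mirroring the mutation
#' classes of length-polymorphic plastid spacers: indels (deletions and
#' duplications, geometric lengths), length-polymorphic homopolymer tracts
#' drifting by one copy per event, oligo-nucleotide motif variant switches
#' (3-variant alphabet), and window inversions (reverse complement).
#' Event intervals are kept disjoint (with a one-column buffer) so the
#' recorded truth identifies every event unambiguously.
#'
#' @param tree `phylo` (e.g. from [simulate_tree()]).
#' @param cfg a [sim_config()]; randomness is seeded with `cfg$seed + 1`.
#' @return list with `alignment` (a [multi_aln()]) and `truth`: list with
#'   `tree` and `events` (data frame `category`, `start`, `end` in final
#'   alignment coordinates, `gap_taxa` = taxa displaying gaps over the
#'   interval, `taxa` = event carriers, `note`).
#' @export
evolve_alignment <- function(tree, cfg) {
  set.seed(cfg$seed + 1L)
  L <- cfg$seq_length
  ntip <- length(tree$tip.label)
  bases <- c("A", "C", "G", "T")
  chars <- matrix(bases[simulate_states(tree, cfg$model, L)], nrow = ntip)
  rownames(chars) <- tree$tip.label
  clades <- edge_clades(tree)
  elen <- tree$edge.length
  total <- sum(elen)
  occupied <- rep(FALSE, L)
  draw_events <- function(rate, width_fun) {
    n <- stats::rpois(1L, rate * L * total)
    out <- list()
    for (i in seq_len(n)) {
      k <- sample.int(length(elen), 1L, prob = elen)
      carriers <- clades[[k]]
      if (length(carriers) == ntip) next        # no outgroup contrast
      w <- width_fun()
      for (try in 1:200) {
        s <- sample.int(L - w + 1L, 1L)
        idx <- max(1L, s - 1L):min(L, s + w)    # 1-column buffer
        if (!any(occupied[idx])) {
          occupied[idx] <<- TRUE
          out[[length(out) + 1L]] <- list(start = s, end = s + w - 1L,
                                          carriers = carriers)
          break
        }
      }
    }
    out
  }
  geom_len <- function() 1L + stats::rgeom(1L, prob = 1 / cfg$indel_mean_length)
  ev_indel <- draw_events(cfg$indel_rate, geom_len)
  ev_lp <- draw_events(cfg$lp_rate, function() cfg$lp_tract_length)
  ev_onm <- draw_events(cfg$onm_rate, function() cfg$onm_width)
  ev_inv <- draw_events(cfg$inversion_rate, function() cfg$inversion_width)
  truth <- list()
  insertions <- list()   # list(pos, block matrix, gap_taxa, category, note)
  # --- indels: deletions in place, duplications as insertions ---
  for (ev in ev_indel) {
    cols <- ev$start:ev$end
    if (stats::runif(1) < cfg$insertion_prob) {
      blk <- matrix("-", ntip, length(cols))
      blk[ev$carriers, ] <- chars[ev$carriers, cols, drop = FALSE]
      insertions[[length(insertions) + 1L]] <-
        list(pos = ev$end, block = blk,
             gap_taxa = rownames(chars)[-ev$carriers],
             carriers = rownames(chars)[ev$carriers],
             category = "INDEL", note = "duplication")
    } else {
      chars[ev$carriers, cols] <- "-"
      truth[[length(truth) + 1L]] <-
        list(category = "INDEL", start = ev$start, end = ev$end,
             gap_taxa = rownames(chars)[ev$carriers],
             carriers = rownames(chars)[ev$carriers], note = "deletion")
    }
  }
  # --- LP tracts: conserved homopolymer, copy-number drift ---
  for (ev in ev_lp) {
    X <- sample(bases, 1L)
    chars[, ev$start:ev$end] <- X
    if (stats::runif(1) < 0.5) {
      chars[ev$carriers, ev$end] <- "-"         # -1 copy
      truth[[length(truth) + 1L]] <-
        list(category = "LP", start = ev$end, end = ev$end,
             gap_taxa = rownames(chars)[ev$carriers],
             carriers = rownames(chars)[ev$carriers], note = "tract -1")
    } else {
      blk <- matrix("-", ntip, 1L)
      blk[ev$carriers, ] <- X                   # +1 copy
      insertions[[length(insertions) + 1L]] <-
        list(pos = ev$end, block = blk,
             gap_taxa = rownames(chars)[-ev$carriers],
             carriers = rownames(chars)[ev$carriers],
             category = "LP", note = "tract +1")
    }
  }
  # --- ONM: linked motif variants over a fixed window ---
  for (ev in ev_onm) {
    w <- ev$end - ev$start + 1L
    variants <- replicate(3L, paste(sample(bases, w, replace = TRUE), collapse = ""))
    v1 <- strsplit(variants[1L], "")[[1]]
    chars[, ev$start:ev$end] <- matrix(v1, ntip, w, byrow = TRUE)
    alt <- strsplit(variants[1L + sample.int(2L, 1L)], "")[[1]]
    chars[ev$carriers, ev$start:ev$end] <-
      matrix(alt, length(ev$carriers), w, byrow = TRUE)
    truth[[length(truth) + 1L]] <-
      list(category = "ONM", start = ev$start, end = ev$end,
           gap_taxa = character(0),
           carriers = rownames(chars)[ev$carriers], note = "motif switch")
  }
  # --- inversions: reverse complement of the window ---
  for (ev in ev_inv) {
    for (i in ev$carriers)
      chars[i, ev$start:ev$end] <- reverse_complement(chars[i, ev$start:ev$end])
    truth[[length(truth) + 1L]] <-
      list(category = "ONM", start = ev$start, end = ev$end,
           gap_taxa = character(0),
           carriers = rownames(chars)[ev$carriers], note = "inversion")
  }
  # --- apply insertions right to left; then map truth to final coordinates ---
  ins_pos <- vapply(insertions, `[[`, numeric(1), "pos")
  ins_len <- vapply(insertions, function(x) ncol(x$block), integer(1))
  for (i in order(ins_pos, decreasing = TRUE)) {
    p <- insertions[[i]]$pos
    chars <- cbind(chars[, seq_len(p), drop = FALSE], insertions[[i]]$block,
                   if (p < ncol(chars)) chars[, (p + 1L):ncol(chars), drop = FALSE])
  }
  shift <- function(x) x + sum(ins_len[ins_pos < x])
  rows <- lapply(truth, function(tv)
    data.frame(category = tv$category, start = shift(tv$start),
               end = shift(tv$end), note = tv$note,
               gap_taxa = I(list(tv$gap_taxa)), taxa = I(list(tv$carriers))))
  for (i in seq_along(insertions)) {
    p <- insertions[[i]]$pos
    s <- p + sum(ins_len[ins_pos < p]) + sum(ins_len[ins_pos == p & seq_along(ins_pos) < i]) + 1L
    rows[[length(rows) + 1L]] <-
      data.frame(category = insertions[[i]]$category, start = s,
                 end = s + ins_len[i] - 1L, note = insertions[[i]]$note,
                 gap_taxa = I(list(insertions[[i]]$gap_taxa)),
                 taxa = I(list(insertions[[i]]$carriers)))
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(0), start = integer(0), end = integer(0),
               note = character(0), gap_taxa = I(list()), taxa = I(list()))
  events <- events[order(events$start), , drop = FALSE]
  rownames(events) <- NULL
  list(alignment = multi_aln(chars), truth = list(tree = tree, events = events))
}

#' Sample a tree set from a weighted topology mixture
#'
#' @param topologies `multiPhylo` (or list of `phylo`).
#' @param weights sampling weights summing to 1.
#' @param n_trees sample size.
#' @param seed integer seed.
#' @return `multiPhylo` of `n_trees` i.i.d. draws; attribute `draws` holds
#'   the sampled topology indices.
#' @export
simulate_treeset <- function(topologies, weights, n_trees, seed = 1L) {
  if (inherits(topologies, "phylo")) topologies <- c(topologies)
  if (length(topologies) < 1L) stop("need at least one topology")
  stopifnot(length(weights) == length(topologies),
            abs(sum(weights) - 1) < 1e-8)
  set.seed(seed)
  draws <- sample.int(length(topologies), n_trees, replace = TRUE, prob = weights)
  out <- topologies[draws]
  class(out) <- "multiPhylo"
  attr(out, "draws") <- draws
  out
}

#' Infinite-sites genotype sample with sampled ancestors
#'
#' Sequential-birth infinite-sites model: starting from an ancestral
#' genotype, each new genotype copies a uniformly chosen existing genotype
#' and adds one mutation at a fresh character. Every character therefore
#' mutates exactly once and every ancestral genotype is sampled, so the
#' true genealogy is exactly recoverable: its unrooted topology is the
#' unique minimum spanning tree and total tree length equals the number of
#' variable characters.
#'
#' @param n_genotypes number of genotypes.
#' @param seed integer seed.
#' @return list with `states` (binary character matrix, one column per
#'   mutation) and `parent` (birth-tree parent index per genotype, NA for
#'   the ancestor).
#' @export
simulate_infinite_sites <- function(n_genotypes = 10L, seed = 1L) {
  stopifnot(n_genotypes >= 1L)
  set.seed(seed)
  n_char <- n_genotypes - 1L
  states <- matrix("0", n_genotypes, max(n_char, 1L))
  if (n_char == 0L) states <- matrix(character(0), 1L, 0L)
  parent <- rep(NA_integer_, n_genotypes)
  for (g in seq_len(n_genotypes)[-1L]) {
    p <- sample.int(g - 1L, 1L)
    states[g, ] <- states[p, ]
    states[g, g - 1L] <- "1"
    parent[g] <- p
  }
  rownames(states) <- paste0("g", seq_len(n_genotypes))
  list(states = states, parent = parent)
}

#' Plant a query on a known edge of a tree
#'
#' Attaches a query tip at the midpoint of the chosen edge, evolves
#' sequences on the extended tree, and returns the query-free reference
#' together with the truth. Fixture for placement-recovery experiments.
#'
#' @param tree reference `phylo`.
#' @param edge_k row index into `tree$edge` for the planted edge.
#' @param cfg a [sim_config()]; randomness seeded with `cfg$seed + 2`.
#' @param pendant pendant branch length for the planted query (default:
#'   mean reference edge length).
#' @return list with `reference` (the input tree), `alignment` (reference
#'   plus query rows) and `truth` (list: `edge_id` of the planted edge,
#'   `query`).
#' @export
plant_query <- function(tree, edge_k, cfg, pendant = NULL) {
  if (edge_k < 1L || edge_k > nrow(tree$edge)) stop("invalid edge index")
  if (is.null(pendant)) pendant <- mean(tree$edge.length)
  query <- "query1"
  ext <- insert_tip_at_edge(tree, edge_k, query, pendant)
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1L   # evolve_alignment adds 1 -> seed + 2
  sim <- evolve_alignment(ext, cfg2)
  list(reference = tree, alignment = sim$alignment,
       truth = list(edge_id = edge_ids(tree)[edge_k], query = query))
}
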
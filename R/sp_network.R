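# Statistical parsimony genotype networks under an infinite-site model.
#
# Genotypes are connected by a deterministic minimum spanning tree on
# substitution (Hamming) distances; every tree edge of length d is
# subdivided by d-1 missing-intermediate nodes (one mutational step per
# edge), and equal-cost substitutes discovered while components merge are
# emitted as dashed "alternative links". No connection limit is applied:
# the network is connected in full.

#' Statistical parsimony network
#'
#' @param genotypes a `genotype_set` (from [collapse_to_genotypes()]) or a
#'   character state matrix (rows = genotypes; identical rows are collapsed
#'   first, frequencies summed).
#' @return object of class `sp_network`: list with `nodes` (data frame
#'   `id`, `kind` in \{genotype, intermediate\}, `frequency`), `edges`
#'   (data frame `u`, `v`, `steps`, `alternative`; non-alternative edges
#'   all have `steps = 1` and form a spanning tree once intermediates are
#'   included), `states` (genotype state matrix) and `tree_edges` (the
#'   genotype-level MST with mutation counts).
#' @export
sp_network <- function(genotypes) {
  if (inherits(genotypes, "genotype_set")) {
    states <- genotypes$states
    freq <- genotypes$frequency
  } else {
    states <- as.matrix(genotypes)
    key <- apply(states, 1L, function(r) paste(ifelse(is.na(r), "\x01", r), collapse = "\x02"))
    first <- !duplicated(key)
    freq <- as.integer(table(match(key, key[first]))[as.character(seq_len(sum(first)))])
    states <- states[first, , drop = FALSE]
  }
  n <- nrow(states)
  if (n < 1L) stop("need at least one genotype")
  if (is.null(rownames(states))) rownames(states) <- paste0("g", seq_len(n))
  labs <- rownames(states)
  d <- pairwise_distances(states)
  tree <- data.frame(u = character(0), v = character(0), steps = integer(0))
  alts <- data.frame(u = character(0), v = character(0), steps = integer(0))
  if (n > 1L) {
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    ord <- order(d[pairs], pairs[, 1L], pairs[, 2L])   # weight, then id pair
    pairs <- pairs[ord, , drop = FALSE]
    uf <- uf_new(n)
    members <- lapply(seq_len(n), identity)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      ri <- uf_find(uf, i); rj <- uf_find(uf, j)
      if (ri == rj) next
      w <- d[i, j]
      # equal-cost substitutes across the two merging components
      for (x in members[[ri]]) for (y in members[[rj]]) {
        if ((x == i && y == j) || (x == j && y == i)) next
        if (d[x, y] == w)
          alts <- rbind(alts, data.frame(u = labs[min(x, y)], v = labs[max(x, y)],
                                         steps = w))
      }
      tree <- rbind(tree, data.frame(u = labs[i], v = labs[j], steps = w))
      uf_union(uf, ri, rj)
      members[[uf_find(uf, ri)]] <- c(members[[ri]], members[[rj]])
    }
  }
  # subdivide tree edges into unit steps through missing intermediates
  nodes <- data.frame(id = labs, kind = "genotype", frequency = as.integer(freq),
                      stringsAsFactors = FALSE)
  edges <- data.frame(u = character(0), v = character(0), steps = integer(0),
                      alternative = logical(0))
  n_int <- 0L
  if (nrow(tree) > 0L) for (k in seq_len(nrow(tree))) {
    w <- tree$steps[k]
    chain <- tree$u[k]
    if (w > 1L) {
      ints <- paste0("x", n_int + seq_len(w - 1L))
      n_int <- n_int + w - 1L
      nodes <- rbind(nodes, data.frame(id = ints, kind = "intermediate",
                                       frequency = 0L))
      chain <- c(chain, ints)
    }
    chain <- c(chain, tree$v[k])
    edges <- rbind(edges, data.frame(u = chain[-length(chain)], v = chain[-1L],
                                     steps = 1L, alternative = FALSE))
  }
  if (nrow(alts) > 0L) {
    alts <- unique(alts)
    edges <- rbind(edges, data.frame(u = alts$u, v = alts$v, steps = alts$steps,
                                     alternative = TRUE))
  }
  structure(list(nodes = nodes, edges = edges, states = states,
                 tree_edges = tree),
            class = "sp_network")
}

#' @export
print.sp_network <- function(x, ...) {
  cat("Statistical parsimony network: ",
      sum(x$nodes$kind == "genotype"), " genotypes, ",
      sum(x$nodes$kind == "intermediate"), " missing intermediates, ",
      sum(x$edges$alternative), " alternative links\n", sep = "")
  invisible(x)
}

#' Ancestral-versus-derived classification of genotypes
#'
#' Genotypes in the centre of the network are candidate ancestors, those in
#' the periphery most derived. Two per-genotype measures are reported: the
#' Hamming distance to the consensus sequence (`ancestral_score`, 0 =
#' consensus-identical) and the graph eccentricity in mutational steps
#' (maximum step distance to any other genotype, alternative links
#' included as paths).
#'
#' @param net an `sp_network` (must be connected).
#' @param consensus character state vector, e.g. from
#'   [consensus_sequence()] on the same genotype set.
#' @return data frame `genotype`, `ancestral_score`, `eccentricity`.
#' @export
classify_centrality <- function(net, consensus) {
  states <- net$states
  if (length(consensus) != ncol(states))
    stop("consensus length (", length(consensus),
         ") does not match character count (", ncol(states), ")")
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes$id)
  if (igraph::components(g)$no > 1L) stop("network is disconnected")
  gd <- igraph::distances(g, weights = net$edges$steps)
  gl <- net$nodes$id[net$nodes$kind == "genotype"]
  data.frame(
    genotype = gl,
    ancestral_score = vapply(gl, function(v) {
      det <- !is.na(states[v, ]) & !is.na(consensus)
      sum(states[v, det] != consensus[det])
    }, numeric(1)),
    eccentricity = vapply(gl, function(v) max(gd[v, gl]), numeric(1)),
    row.names = NULL)
}
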
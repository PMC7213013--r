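# Outgroup placement rooting: maximum-likelihood attachment of query
# sequences to every branch of a fixed ingroup tree, likelihood weight
# ratios, and the per-scenario root probability estimate p_R.

# Canonical edge identifiers: the sorted tip labels of the smaller side of
# the split the edge induces (ties: the side holding the alphabetically
# first tip), joined by "|". Stable across rerooting and tip order.
edge_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  taxa <- sort(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  masks <- matrix(FALSE, ntip + tree$Nnode, ntip)
  masks[cbind(seq_len(ntip), match(tree$tip.label, taxa))] <- TRUE
  for (k in seq_len(nrow(po$edge)))
    masks[po$edge[k, 1L], ] <- masks[po$edge[k, 1L], ] | masks[po$edge[k, 2L], ]
  vapply(seq_len(nrow(tree$edge)), function(k) {
    m <- masks[tree$edge[k, 2L], ]
    s <- sum(m)
    if (s * 2L > ntip || (s * 2L == ntip && !m[1L])) m <- !m
    paste(taxa[m], collapse = "|")
  }, character(1))
}

#' Canonical edge id for the edge subtending a clade
#'
#' Convenience for writing rooting scenarios: returns the id of the edge
#' above the smallest clade containing `taxa`.
#'
#' @param tree `phylo`.
#' @param taxa tip labels.
#' @return edge id string usable in [aggregate_root()] scenarios.
#' @export
clade_edge_id <- function(tree, taxa) {
  stopifnot(all(taxa %in% tree$tip.label))
  node <- if (length(taxa) == 1L) match(taxa, tree$tip.label) else
    ape::getMRCA(tree, taxa)
  k <- which(tree$edge[, 2L] == node)
  if (length(k) != 1L) stop("clade has no subtending edge (is it the root?)")
  edge_ids(tree)[k]
}

# Insert a new tip on edge `edge_k` of `tree` at relative position `at`,
# with pendant branch length `pendant`. Pure edge-matrix surgery.
insert_tip_at_edge <- function(tree, edge_k, label, pendant, at = 0.5) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  len <- tree$edge.length
  # renumber: old internal nodes shift by +1 to make room for the new tip
  edge[edge > ntip] <- edge[edge > ntip] + 1L
  new_tip <- ntip + 1L
  new_node <- ntip + 1L + tree$Nnode + 1L
  p <- edge[edge_k, 1L]; ch <- edge[edge_k, 2L]; t_full <- len[edge_k]
  edge[edge_k, ] <- c(p, new_node)
  len[edge_k] <- t_full * at
  edge <- rbind(edge, c(new_node, ch), c(new_node, new_tip))
  len <- c(len, t_full * (1 - at), pendant)
  structure(list(edge = edge, edge.length = len,
                 tip.label = c(tree$tip.label, label),
                 Nnode = tree$Nnode + 1L),
            class = "phylo")
}

#' Place a query sequence on every edge of a reference tree
#'
#' Evolutionary placement: the query is attached at the midpoint of each
#' reference edge in turn, only its pendant branch length is optimized
#' (bounded one-dimensional maximization), and the per-edge log-likelihoods
#' are normalized into likelihood weight ratios (LWR, summing to 1 over
#' edges).
#'
#' @param reference `phylo` with branch lengths; must not contain the query.
#' @param aln [multi_aln()] holding reference and query sequences.
#' @param query taxon label of the query in `aln`.
#' @param model a [subst_model()].
#' @param pendant_bounds search interval for the pendant branch length.
#' @param tol optimization tolerance.
#' @return object of class `placement`: list with `query`, `per_edge`
#'   (data frame `edge_id`, `loglik`, `pendant`, `lwr`, sorted by
#'   decreasing `lwr`) and `best_edge` (ties broken by lexicographically
#'   smallest edge id).
#' @export
place_query <- function(reference, aln, query, model,
                        pendant_bounds = c(1e-8, 2), tol = 1e-4) {
  if (!query %in% rownames(aln)) stop("query '", query, "' not in alignment")
  if (query %in% reference$tip.label)
    stop("query '", query, "' already a leaf of the reference tree")
  ids <- edge_ids(reference)
  labs <- c(reference$tip.label, query)
  cp <- compress_patterns(unclass(aln)[labs, , drop = FALSE])
  n_edge <- nrow(reference$edge)
  ll <- numeric(n_edge)
  pend <- numeric(n_edge)
  for (k in seq_len(n_edge)) {
    f <- function(x) {
      ext <- insert_tip_at_edge(reference, k, query, x)
      sum(cp$weights * site_logliks(ext, cp$mat, model))
    }
    opt <- stats::optimize(f, interval = pendant_bounds, maximum = TRUE, tol = tol)
    ll[k] <- opt$objective
    pend[k] <- opt$maximum
  }
  lwr <- exp(ll - logsumexp(ll))
  o <- order(-ll, ids)
  per_edge <- data.frame(edge_id = ids[o], loglik = ll[o], pendant = pend[o],
                         lwr = lwr[o], stringsAsFactors = FALSE)
  structure(list(query = query, per_edge = per_edge,
                 best_edge = per_edge$edge_id[1L]),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat("Placement of '", x$query, "': best edge ", x$best_edge,
      sprintf(" (lwr %.3f over %d edges)\n", x$per_edge$lwr[1L],
              nrow(x$per_edge)), sep = "")
  invisible(x)
}

#' Aggregate placements into root-scenario probabilities
#'
#' For each rooting scenario (a named, pairwise-disjoint set of candidate
#' root edges), the probability estimate p_R is the likelihood weight ratio
#' mass falling on the scenario's edges, averaged over all queried taxa.
#' Edges in no scenario are binned as `"other"`, so p_R over the reported
#' partition sums to 1.
#'
#' @param placements list of [place_query()] results.
#' @param scenarios named list of edge-id character vectors.
#' @return object of class `root_report`: data frame `scenario`, `p_R`,
#'   `n_best` (queries whose best edge lies in the scenario), sorted by
#'   decreasing p_R; attribute `n_queries`.
#' @export
aggregate_root <- function(placements, scenarios) {
  if (inherits(placements, "placement")) placements <- list(placements)
  stopifnot(length(placements) >= 1L)
  all_sc <- unlist(scenarios, use.names = FALSE)
  if (anyDuplicated(all_sc)) stop("scenario edge sets overlap")
  n_q <- length(placements)
  labels <- c(names(scenarios), "other")
  mass <- stats::setNames(numeric(length(labels)), labels)
  n_best <- stats::setNames(integer(length(labels)), labels)
  for (pl in placements) {
    bin <- rep("other", nrow(pl$per_edge))
    for (s in names(scenarios))
      bin[pl$per_edge$edge_id %in% scenarios[[s]]] <- s
    agg <- tapply(pl$per_edge$lwr, bin, sum)
    mass[names(agg)] <- mass[names(agg)] + agg
    best_bin <- bin[1L]
    n_best[best_bin] <- n_best[best_bin] + 1L
  }
  out <- data.frame(scenario = labels, p_R = unname(mass) / n_q,
                    n_best = unname(n_best), stringsAsFactors = FALSE)
  if (all(out$p_R[out$scenario == "other"] == 0) &&
      all(out$n_best[out$scenario == "other"] == 0))
    out <- out[out$scenario != "other", , drop = FALSE]
  out <- out[order(-out$p_R, out$scenario), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_queries") <- n_q
  class(out) <- c("root_report", "data.frame")
  out
}

#' @export
print.root_report <- function(x, ...) {
  cat("Root probability estimates over", attr(x, "n_queries"), "queries:\n")
  print.data.frame(x)
  invisible(x)
}
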
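# Median-joining haplotype networks and haplotype-group collapsing.
#
# The network is grown on the full quasi-median landscape: starting from the
# minimum spanning network (union of all minimum spanning trees, widened by
# a tolerance epsilon), median (majority-state) vectors of connected node
# triplets are added until closure, and median nodes that end up with degree
# <= 2 without lying on any shortest observed-pair path are pruned to a
# fixed point.

#' Pairwise mutation distances between haplotypes
#'
#' Number of characters with determinate, differing states ("no character
#' weighting"; missing states never contribute).
#'
#' @param x a `recoded_matrix` or plain character state matrix (rows =
#'   haplotypes, `NA` = missing).
#' @return symmetric integer matrix with zero diagonal.
#' @export
pairwise_distances <- function(x) {
  m <- unclass(x)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L || ncol(m) == 0L) return(d)
  # one-hot encoding per character: shared determinate characters minus
  # matches, all through BLAS (fast even with medians added)
  det <- !is.na(m)
  blocks <- lapply(seq_len(ncol(m)), function(j) {
    lv <- sort(unique(m[det[, j], j]))
    if (length(lv) == 0L) return(NULL)
    out <- matrix(0, n, length(lv))
    out[cbind(seq_len(n), match(m[, j], lv))[det[, j], , drop = FALSE]] <- 1
    out
  })
  X <- do.call(cbind, blocks)
  matches <- if (is.null(X)) matrix(0, n, n) else tcrossprod(X)
  shared <- tcrossprod(det * 1)
  dd <- round(shared - matches)
  storage.mode(dd) <- "integer"
  dimnames(dd) <- dimnames(d)
  dd
}

# Prim MST on a dense distance matrix; deterministic (smallest index wins
# ties). Returns edge matrix (2 columns of node indices).
mst_edges <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1L, ]; parent <- rep(1L, n)
  edges <- matrix(integer(0), 0L, 2L)
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    edges <- rbind(edges, c(parent[v], v))
    in_tree[v] <- TRUE
    upd <- !in_tree & d[v, ] < best
    best[upd] <- d[v, upd]
    parent[upd] <- v
  }
  edges
}

# Minimax (bottleneck) distance between all pairs: max edge weight on the
# MST path. O(n^2) by rooted traversal from each node.
minimax_distances <- function(d) {
  n <- nrow(d)
  mm <- matrix(0, n, n)
  if (n < 2L) return(mm)
  ed <- mst_edges(d)
  adj <- vector("list", n)
  for (k in seq_len(nrow(ed))) {
    i <- ed[k, 1L]; j <- ed[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n); seen[s] <- TRUE
    stack <- s
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      for (w in adj[[v]]) if (!seen[w]) {
        seen[w] <- TRUE
        mm[s, w] <- max(mm[s, v], d[v, w])
        stack <- c(stack, w)
      }
    }
  }
  mm
}

# Minimum spanning network edge list: pairs whose direct distance does not
# exceed the bottleneck connection cost plus epsilon. epsilon = 0 gives the
# union of all MSTs.
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  mm <- minimax_distances(d)
  out <- which(upper.tri(d) & d <= mm + epsilon, arr.ind = TRUE)
  unname(as.matrix(out))
}

# Median (quasi-median) vectors of a state triplet. Majority state per
# character; characters with a 2- or 3-way tie are expanded over all
# parental states (lexicographic order), capped at `cap` vectors.
median_vectors <- function(a, b, c, cap = 1000L) {
  m <- length(a)
  fixed <- character(m)
  options <- vector("list", m)
  n_opts <- rep(1L, m)
  for (k in seq_len(m)) {
    s <- c(a[k], b[k], c[k])
    det <- s[!is.na(s)]
    if (length(det) == 0L) { fixed[k] <- NA_character_; next }
    tab <- table(det)
    if (max(tab) >= 2L) { fixed[k] <- names(tab)[which.max(tab)]; next }
    opts <- sort(unique(det))
    options[[k]] <- opts
    n_opts[k] <- length(opts)
  }
  tie <- which(n_opts > 1L)
  if (length(tie) == 0L) return(matrix(fixed, nrow = 1L))
  total <- prod(n_opts[tie])
  n_out <- as.integer(min(total, cap))
  # mixed-radix enumeration, most significant digit = first tie character,
  # so vectors come out in lexicographic order without building the full grid
  out <- matrix(rep(fixed, each = n_out), nrow = n_out)
  radix <- n_opts[tie]
  period <- rev(cumprod(rev(c(radix[-1L], 1L))))  # stride of each digit
  for (z in seq_along(tie)) {
    digit <- ((seq_len(n_out) - 1L) %/% period[z]) %% radix[z]
    out[, tie[z]] <- options[[tie[z]]][digit + 1L]
  }
  out
}

node_key <- function(states) {
  apply(states, 1L, function(r)
    paste(ifelse(is.na(r), "\x01", r), collapse = "\x02"))
}

#' Median-joining haplotype network
#'
#' Implements the median-joining algorithm on a recoded character matrix:
#' (1) connect components through the minimum spanning network with
#' tolerance `epsilon`; (2) for connected node triplets, add new median
#' (majority-state) vectors, expanding ties as quasi-medians (cap
#' `quasi_cap`, deterministic lexicographic order); (3) iterate to closure;
#' (4) delete obsolete medians (degree <= 2, not on any shortest path
#' between observed haplotypes) to a fixed point after each round. The
#' result contains every minimum spanning tree of its node set and all
#' equally parsimonious connections.
#'
#' @param x a `recoded_matrix` or character state matrix (rows observed
#'   haplotypes; `NA` = missing state).
#' @param epsilon nonnegative integer widening of the connection cost
#'   (default 0, the program default used for published networks).
#' @param quasi_cap cap on quasi-median expansion per triplet.
#' @param max_nodes hard cap on total network nodes; exceeded only on
#'   inputs too homoplastic for a meaningful MJ network (warns and
#'   truncates).
#' @return object of class `haplo_network`: list with `states` (node x
#'   character matrix; observed haplotypes then medians `m1`, `m2`, ...),
#'   `kind` (`"observed"`/`"median"`), `frequency` (observed only; display
#'   metadata, never used for topology), and `edges` (data frame `u`, `v`
#'   node labels and `weight` = mutation count).
#' @export
median_joining <- function(x, epsilon = 0, quasi_cap = 1000L, max_nodes = 5000L) {
  if (length(epsilon) != 1L || is.na(epsilon) || !is.finite(epsilon) || epsilon < 0)
    stop("epsilon must be a nonnegative finite number")
  m <- unclass(x)
  if (nrow(m) < 1L) stop("need at least one haplotype")
  members <- attr(x, "members")
  freq <- if (!is.null(members)) lengths(members) else rep(1L, nrow(m))
  # collapse accidental duplicate rows
  key <- node_key(m)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    freq <- as.integer(tapply(freq, match(key, key[first]), sum))
    m <- m[first, , drop = FALSE]
    key <- key[first]
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("h", seq_len(nrow(m)))
  n_obs <- nrow(m)
  states <- m
  seen <- stats::setNames(seq_len(n_obs), key)
  n_med <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 60L) {
      warning("median-joining did not close after 60 rounds; returning current network")
      break
    }
    d <- pairwise_distances(states)
    ed <- msn_edges(d, epsilon)
    # adjacency for triplet search
    n <- nrow(states)
    nbr <- vector("list", n)
    for (k in seq_len(nrow(ed))) {
      nbr[[ed[k, 1L]]] <- c(nbr[[ed[k, 1L]]], ed[k, 2L])
      nbr[[ed[k, 2L]]] <- c(nbr[[ed[k, 2L]]], ed[k, 1L])
    }
    new_rows <- list()
    for (v in seq_len(n)) {
      ns <- nbr[[v]]
      if (length(ns) < 2L) next
      pairs <- utils::combn(sort(ns), 2L)
      for (p in seq_len(ncol(pairs))) {
        meds <- median_vectors(states[v, ], states[pairs[1L, p], ],
                               states[pairs[2L, p], ], cap = quasi_cap)
        for (r in seq_len(nrow(meds))) {
          k2 <- paste(ifelse(is.na(meds[r, ]), "\x01", meds[r, ]), collapse = "\x02")
          if (is.na(seen[k2])) {
            seen[k2] <- 0L  # placeholder; reindexed below
            new_rows[[length(new_rows) + 1L]] <- meds[r, ]
          }
        }
      }
    }
    if (length(new_rows) == 0L) break
    if (nrow(states) + length(new_rows) > max_nodes) {
      warning("median-joining node cap (max_nodes = ", max_nodes,
              ") reached; network truncated. The input is likely too ",
              "divergent/homoplastic for a meaningful MJ network.")
      new_rows <- new_rows[seq_len(max(0L, max_nodes - nrow(states)))]
      if (length(new_rows) == 0L) break
    }
    add <- do.call(rbind, new_rows)
    rownames(add) <- paste0("m", n_med + seq_len(nrow(add)))
    n_med <- n_med + nrow(add)
    states <- rbind(states, add)
    seen <- stats::setNames(seq_len(nrow(states)), node_key(states))
    states <- prune_obsolete(states, n_obs, epsilon)
    seen <- stats::setNames(seq_len(nrow(states)), node_key(states))
  }
  states <- prune_obsolete(states, n_obs, epsilon)
  d <- pairwise_distances(states)
  ed <- msn_edges(d, epsilon)
  edges <- data.frame(
    u = rownames(states)[ed[, 1L]],
    v = rownames(states)[ed[, 2L]],
    weight = d[ed],
    stringsAsFactors = FALSE)
  structure(list(
    states = states,
    kind = c(rep("observed", n_obs), rep("median", nrow(states) - n_obs)),
    frequency = stats::setNames(as.integer(freq), rownames(states)[seq_len(n_obs)]),
    edges = edges),
    class = "haplo_network")
}

# Remove median nodes of degree <= 2 that lie on no shortest path between
# observed nodes; repeat until stable. Observed nodes are rows 1..n_obs.
prune_obsolete <- function(states, n_obs, epsilon) {
  repeat {
    n <- nrow(states)
    if (n == n_obs) return(states)
    d <- pairwise_distances(states)
    ed <- msn_edges(d, epsilon)
    deg <- tabulate(c(ed), nbins = n)
    g <- igraph::make_graph(t(ed), n = n, directed = FALSE)
    gd <- igraph::distances(g, weights = d[ed])
    obs <- seq_len(n_obs)
    drop <- integer(0)
    for (v in (n_obs + 1L):n) {
      if (deg[v] > 2L) next
      thru <- outer(gd[obs, v], gd[v, obs], "+")   # cost a -> v -> b
      if (!any(abs(thru - gd[obs, obs]) < 1e-9)) drop <- c(drop, v)
    }
    if (length(drop) == 0L) return(states)
    states <- states[-drop, , drop = FALSE]
  }
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("Median-joining network: ", sum(x$kind == "observed"), " haplotypes + ",
      sum(x$kind == "median"), " medians, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Collapse a haplotype network into haplotype groups
#'
#' Summarizes a (possibly diffuse) network for visual interpretation: each
#' group becomes one node whose dimension is the maximum pairwise mutation
#' count among its haplotypes and connective medians (shortest-path cost
#' within the group's induced subgraph); edges between groups carry the
#' minimum mutation count between their members. Circle size in the
#' collapsed display is thus a within-group divergence, not a frequency.
#'
#' @param net a `haplo_network`.
#' @param grouping named character vector node label -> group id. Must cover
#'   all observed nodes; median nodes missing from it are auto-assigned to
#'   the nearest group (ties: alphabetically first group) when
#'   `auto_assign = TRUE`.
#' @param auto_assign assign unassigned median nodes to nearest group.
#' @return object of class `collapsed_network`: list with `groups` (group ->
#'   node labels), `dimension`, and `group_edges` (data frame `g1`, `g2`,
#'   `weight`).
#' @export
collapse_groups <- function(net, grouping, auto_assign = TRUE) {
  labs <- rownames(net$states)
  obs <- labs[net$kind == "observed"]
  if (!all(obs %in% names(grouping)))
    stop("grouping does not cover observed nodes: ",
         paste(setdiff(obs, names(grouping)), collapse = ", "))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = labs))
  gd <- igraph::distances(g, weights = igraph::E(g)$weight)
  assign <- stats::setNames(rep(NA_character_, length(labs)), labs)
  assign[names(grouping)] <- as.character(grouping)
  todo <- labs[is.na(assign)]
  if (length(todo) > 0L) {
    if (!auto_assign) stop("nodes missing from grouping: ",
                           paste(todo, collapse = ", "))
    grp_ids <- sort(unique(as.character(grouping)))
    for (v in todo) {
      dmin <- vapply(grp_ids, function(gi)
        min(gd[v, names(grouping)[grouping == gi], drop = TRUE]), numeric(1))
      assign[v] <- grp_ids[which.min(dmin)]
    }
  }
  grp_ids <- sort(unique(assign))
  groups <- lapply(grp_ids, function(gi) labs[assign == gi])
  names(groups) <- grp_ids
  dimension <- vapply(grp_ids, function(gi) {
    vs <- groups[[gi]]
    if (length(vs) < 2L) return(0)
    sub <- igraph::induced_subgraph(g, vs)
    sd2 <- igraph::distances(sub, weights = igraph::E(sub)$weight)
    sd2[!is.finite(sd2)] <- NA
    # disconnected inside the group: fall back to full-network distance
    full <- gd[rownames(sd2), colnames(sd2), drop = FALSE]
    sd2[is.na(sd2)] <- full[is.na(sd2)]
    max(sd2, na.rm = TRUE)
  }, numeric(1))
  # group edges: minimum direct edge weight between adjacent groups
  eg <- net$edges
  ga <- assign[eg$u]; gb <- assign[eg$v]
  cross <- ga != gb
  ge <- data.frame(g1 = pmin(ga[cross], gb[cross]),
                   g2 = pmax(ga[cross], gb[cross]),
                   weight = eg$weight[cross], stringsAsFactors = FALSE)
  if (nrow(ge) > 0L) {
    ge <- stats::aggregate(weight ~ g1 + g2, data = ge, FUN = min)
    ge <- ge[order(ge$g1, ge$g2), , drop = FALSE]
    rownames(ge) <- NULL
  }
  structure(list(groups = groups, dimension = dimension, group_edges = ge),
            class = "collapsed_network")
}

#' @export
print.collapsed_network <- function(x, ...) {
  cat("Collapsed network: ", length(x$groups), " groups, ",
      nrow(x$group_edges), " group edges\n", sep = "")
  for (g in names(x$groups))
    cat(sprintf("  %s: %d nodes, dimension %g\n", g, length(x$groups[[g]]),
                x$dimension[[g]]))
  invisible(x)
}
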
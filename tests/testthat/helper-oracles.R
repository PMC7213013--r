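# Independent oracles and fixture builders. Every oracle here deliberately
# takes the dumbest correct route (pairwise comparison, exhaustive state
# enumeration, direct counting) so it shares no code path with the package.

random_aln <- function(n, m, seed, gap_prob = 0.1) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T", "-", "?", "N"), n * m, replace = TRUE,
                  prob = c(rep((1 - gap_prob) / 4, 4), gap_prob * c(.6, .2, .2)))
  mat <- matrix(chars, n, m, dimnames = list(paste0("s", seq_len(n)), NULL))
  multi_aln(mat)
}

# brute-force diagnostics by pairwise identical() comparisons
brute_diagnostics <- function(aln, undetermined = c("-", "?", "N")) {
  mat <- unclass(aln)
  n <- nrow(mat); m <- ncol(mat)
  dup <- 0L
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    if (identical(mat[i, ], mat[j, ], ignore.environment = TRUE)) { dup <- dup + 1L; break }
  distinct_cols <- 0L
  for (j in seq_len(m)) {
    seen <- FALSE
    for (k in seq_len(j - 1L))
      if (all(mat[, j] == mat[, k])) { seen <- TRUE; break }
    if (!seen) distinct_cols <- distinct_cols + 1L
  }
  undet <- 0L
  for (i in seq_len(n)) for (j in seq_len(m))
    if (mat[i, j] %in% undetermined) undet <- undet + 1L
  list(nld = dup, puc = undet / (n * m), dap = distinct_cols)
}

brute_pairwise <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cnt <- 0L
    for (k in seq_len(ncol(m)))
      if (!is.na(m[i, k]) && !is.na(m[j, k]) && m[i, k] != m[j, k]) cnt <- cnt + 1L
    d[i, j] <- cnt
  }
  d
}

# exhaustive log-likelihood: sum over all internal-node state assignments
enum_loglik <- function(tree, aln, model) {
  mat <- unclass(aln)[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  rates <- if (is.null(model$gamma_shape)) 1 else
    haplonet:::gamma_category_rates(model$gamma_shape, model$n_categories)
  bases <- c("A", "C", "G", "T")
  comp <- function(ch) if (ch %in% names(haplonet:::IUPAC))
    match(haplonet:::IUPAC[[ch]], bases) else 1:4
  total <- 0
  for (site in seq_len(ncol(mat))) {
    site_lik <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(k)
        prob_matrix(model, tree$edge.length[k], r))
      grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        assign_state <- function(v) {
          if (v <= ntip) comp(mat[v, site]) else grid[g, v - ntip]
        }
        # sum over compatible tip states too (ambiguity = partial likelihood 1)
        tip_sets <- lapply(seq_len(ntip), function(v) comp(mat[v, site]))
        tip_grid <- as.matrix(expand.grid(tip_sets))
        for (tg in seq_len(nrow(tip_grid))) {
          st <- function(v) if (v <= ntip) tip_grid[tg, v] else grid[g, v - ntip]
          p <- model$base_freqs[st(root)]
          for (k in seq_len(nrow(tree$edge)))
            p <- p * Ps[[k]][st(tree$edge[k, 1]), st(tree$edge[k, 2])]
          lik <- lik + p
        }
      }
      site_lik <- site_lik + lik / length(rates)
    }
    total <- total + log(site_lik)
  }
  total
}

# contract degree-2 latent nodes; return canonical genotype-level edge table
# keyed by node state strings so that label conventions do not matter
contract_network <- function(edges, keep, weights) {
  # edges: data.frame u,v ; keep: labels of nodes that must survive
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$u, to = edges$v, weight = weights), directed = FALSE)
  repeat {
    deg <- igraph::degree(g)
    latent <- setdiff(names(deg)[deg == 2], keep)
    if (length(latent) == 0) break
    v <- latent[1]
    nb <- names(igraph::neighbors(g, v))
    w <- sum(igraph::edge_attr(g, "weight", igraph::incident(g, v)))
    g <- igraph::delete_vertices(g, v)
    if (length(nb) == 2)
      g <- igraph::add_edges(g, nb, attr = list(weight = w))
  }
  e <- igraph::as_data_frame(g, what = "edges")
  e <- data.frame(a = pmin(e$from, e$to), b = pmax(e$from, e$to), w = e$weight)
  e[order(e$a, e$b, e$w), ]
}

# canonical state-keyed edge set of a haplo_network (for isomorphism checks)
network_edge_keys <- function(net) {
  key <- apply(net$states, 1L, function(r)
    paste(ifelse(is.na(r), ".", r), collapse = ""))
  a <- key[net$edges$u]; b <- key[net$edges$v]
  sort(paste(pmin(a, b), pmax(a, b), net$edges$weight, sep = "/"))
}

# all k-subsets of the rows of a matrix, as a list of matrices
row_subsets <- function(mat, k) {
  idx <- utils::combn(nrow(mat), k)
  lapply(seq_len(ncol(idx)), function(j) mat[idx[, j], , drop = FALSE])
}

binary_vectors <- function(n_char) {
  m <- as.matrix(expand.grid(rep(list(c("0", "1")), n_char)))
  dimnames(m) <- list(paste0("h", seq_len(nrow(m))), NULL)
  m
}

write_temp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
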
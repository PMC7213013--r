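# Split systems from newick tree sets: bootstrap split frequencies,
# consensus networks, clade support, greedy extended majority-rule
# consensus and the bootstopping criterion fixing the number of
# pseudoreplicates.

#' Read a set of newick trees
#'
#' One newick string per line. Trees are interpreted as unrooted and must
#' share one taxon universe.
#'
#' @param path newick file.
#' @param taxa optional taxon list; labels outside it are an error.
#' @return `multiPhylo` object (possibly empty, with a warning).
#' @export
read_treeset <- function(path, taxa = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (all(trimws(lines) == "")) {
    warning("empty tree file: ", path)
    out <- structure(list(), class = "multiPhylo")
    return(out)
  }
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  labs <- unique(unlist(lapply(trees, `[[`, "tip.label")))
  if (!is.null(taxa) && length(setdiff(labs, taxa)) > 0L)
    stop("unknown taxon label(s): ",
         paste(setdiff(labs, taxa), collapse = ", "))
  trees
}

# Canonical split keys ("0"/"1" strings over the ordered taxon universe) for
# all nontrivial splits of one tree. Canonical side: the smaller one; on
# ties, the side containing the first taxon.
canonical_key <- function(mask) {
  n <- length(mask)
  s <- sum(mask)
  if (s * 2L > n || (s * 2L == n && !mask[1L])) mask <- !mask
  paste(as.integer(mask), collapse = "")
}

tree_split_keys <- function(tree, taxa) {
  n <- length(taxa)
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx)) stop("tree labels not in taxon universe: ",
                       paste(tree$tip.label[is.na(idx)], collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  masks <- matrix(FALSE, ntip + nnode, n)
  masks[cbind(seq_len(ntip), idx)] <- TRUE
  tree <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]; c <- tree$edge[k, 2L]
    masks[p, ] <- masks[p, ] | masks[c, ]
  }
  keys <- character(0)
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2L]
    if (child <= ntip) next                       # trivial (singleton)
    s <- sum(masks[child, ])
    if (s <= 1L || s >= n - 1L) next              # trivial on the universe
    keys <- c(keys, canonical_key(masks[child, ]))
  }
  unique(keys)
}

#' Split frequencies across a tree set
#'
#' @param trees `multiPhylo` (or list of `phylo`).
#' @param taxa optional ordered taxon universe; defaults to the sorted
#'   union of tip labels.
#' @return object of class `split_system`: list with `taxa`, `splits`
#'   (data frame `key` = canonical 0/1 membership string, `count`, `freq`)
#'   and `n_trees`.
#' @export
split_frequencies <- function(trees, taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) < 1L) stop("need at least one tree")
  if (is.null(taxa)) taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  counts <- integer(0)
  for (tr in trees) {
    keys <- tree_split_keys(tr, taxa)
    for (k in keys) counts[k] <- (if (is.na(counts[k])) 0L else counts[k]) + 1L
  }
  keys <- names(counts) %||% character(0)
  o <- order(-as.integer(counts), keys)
  splits <- data.frame(key = keys[o], count = unname(counts[o]),
                       freq = unname(counts[o]) / length(trees),
                       stringsAsFactors = FALSE)
  structure(list(taxa = taxa, splits = splits, n_trees = length(trees)),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat("Split system on ", length(x$taxa), " taxa: ", nrow(x$splits),
      " nontrivial splits from ", x$n_trees, " trees\n", sep = "")
  invisible(x)
}

key_to_mask <- function(key) strsplit(key, "", fixed = TRUE)[[1]] == "1"

# Two splits are compatible iff one of the four side intersections is empty.
splits_compatible <- function(k1, k2) {
  a <- key_to_mask(k1); b <- key_to_mask(k2)
  !all(c(any(a & b), any(a & !b), any(!a & b), any(!a & !b)))
}

#' Bootstrap consensus network
#'
#' Retains all splits whose frequency across the tree set reaches
#' `threshold`. Low thresholds display competing minority support patterns
#' (incompatible splits render as boxes in a splits graph); above 0.5 the
#' retained set is pairwise compatible, i.e. a tree.
#'
#' @param trees a tree set or a precomputed `split_system`.
#' @param threshold split frequency cutoff in (0, 1]; default 0.1.
#' @param taxa optional taxon universe (ignored for a `split_system`).
#' @return a `split_system` restricted to the retained splits.
#' @export
consensus_network <- function(trees, threshold = 0.1, taxa = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  ss <- if (inherits(trees, "split_system")) trees else split_frequencies(trees, taxa)
  ss$splits <- ss$splits[ss$splits$freq >= threshold, , drop = FALSE]
  rownames(ss$splits) <- NULL
  ss$threshold <- threshold
  ss
}

#' Bootstrap support for the clades of a reference tree
#'
#' @param reference `phylo` on the same taxa as the tree set.
#' @param trees tree set (e.g. bootstrap pseudoreplicates).
#' @return data frame `key`, `support` (percentage of trees containing the
#'   split), one row per internal split of the reference.
#' @export
clade_support <- function(reference, trees) {
  taxa <- sort(reference$tip.label)
  other <- unique(unlist(lapply(trees, `[[`, "tip.label")))
  if (!setequal(taxa, other))
    stop("taxon sets of reference and tree set differ")
  ss <- split_frequencies(trees, taxa)
  ref_keys <- tree_split_keys(reference, taxa)
  support <- 100 * ss$splits$freq[match(ref_keys, ss$splits$key)]
  support[is.na(support)] <- 0
  data.frame(key = ref_keys, support = support, stringsAsFactors = FALSE)
}

# Greedy extended majority-rule consensus: splits by descending frequency
# (ties: lexicographic key), accepted when compatible with all accepted.
greedy_consensus_keys <- function(ss) {
  sp <- ss$splits[order(-ss$splits$freq, ss$splits$key), , drop = FALSE]
  accepted <- character(0)
  for (i in seq_len(nrow(sp))) {
    k <- sp$key[i]
    if (all(vapply(accepted, splits_compatible, logical(1), k2 = k)))
      accepted <- c(accepted, k)
  }
  accepted
}

#' Extended majority-rule consensus split set
#'
#' @param trees tree set or `split_system`.
#' @param taxa optional taxon universe.
#' @return a `split_system` containing the greedily accepted splits (always
#'   a pairwise-compatible set; contains every split with frequency > 0.5).
#' @export
extended_majority_consensus <- function(trees, taxa = NULL) {
  ss <- if (inherits(trees, "split_system")) trees else split_frequencies(trees, taxa)
  keep <- greedy_consensus_keys(ss)
  ss$splits <- ss$splits[match(keep, ss$splits$key), , drop = FALSE]
  rownames(ss$splits) <- NULL
  ss
}

#' Bootstopping: how many bootstrap replicates are enough?
#'
#' Extended majority-rule convergence criterion: at checkpoints
#' n = step, 2 step, ... the first n trees are repeatedly split at random
#' into halves, an extended majority-rule consensus is built for each half,
#' and the normalized Robinson-Foulds distance between the two consensus
#' trees is recorded. The replicate number is sufficient at the first
#' checkpoint where at least `quorum` of the permutations fall at or below
#' `rf_cutoff`.
#'
#' @param trees tree set (pseudoreplicates, in generation order).
#' @param step checkpoint spacing (default 50).
#' @param permutations random half-splits per checkpoint (default 100).
#' @param rf_cutoff normalized RF threshold (default 0.03; RF is normalized
#'   by 2(n-3), the maximum for n taxa).
#' @param quorum fraction of permutations that must converge (default 0.99).
#' @param seed integer seed; the procedure is deterministic given it.
#' @return object of class `bootstop_report`: list with `nbs` (necessary
#'   replicates; the total tree count if never converged), `converged`,
#'   and `checkpoints` (data frame `n`, `prop_converged`).
#' @export
bootstop <- function(trees, step = 50L, permutations = 100L, rf_cutoff = 0.03,
                     quorum = 0.99, seed = 1L) {
  if (step < 2L) stop("step must be >= 2")
  if (permutations < 1L) stop("permutations must be >= 1")
  if (inherits(trees, "phylo")) trees <- c(trees)
  n_total <- length(trees)
  if (n_total < 2L) stop("need at least two trees")
  taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  keysets <- lapply(trees, tree_split_keys, taxa = taxa)
  norm <- max(1L, 2L * (length(taxa) - 3L))
  set.seed(seed)
  checkpoints <- data.frame(n = integer(0), prop_converged = numeric(0))
  nbs <- n_total
  converged <- FALSE
  n <- step
  consensus_of <- function(sets) {
    counts <- table(unlist(sets))
    ss <- list(splits = data.frame(key = names(counts),
                                   freq = as.numeric(counts) / length(sets),
                                   stringsAsFactors = FALSE))
    greedy_consensus_keys(ss)
  }
  while (n <= n_total) {
    ok <- logical(permutations)
    for (p in seq_len(permutations)) {
      perm <- sample.int(n)
      half <- n %/% 2L
      c1 <- consensus_of(keysets[perm[seq_len(half)]])
      c2 <- consensus_of(keysets[perm[(half + 1L):n]])
      rf <- (length(setdiff(c1, c2)) + length(setdiff(c2, c1))) / norm
      ok[p] <- rf <= rf_cutoff
    }
    checkpoints <- rbind(checkpoints,
                         data.frame(n = n, prop_converged = mean(ok)))
    if (mean(ok) >= quorum) {
      nbs <- n
      converged <- TRUE
      break
    }
    n <- n + step
  }
  structure(list(nbs = nbs, converged = converged, checkpoints = checkpoints),
            class = "bootstop_report")
}

#' @export
print.bootstop_report <- function(x, ...) {
  cat("Bootstopping: ", if (x$converged) "converged" else "NOT converged",
      " at NBS = ", x$nbs, "\n", sep = "")
  invisible(x)
}

#' Write a split system as a SplitsTree-readable NEXUS splits block
#'
#' @param ss a `split_system`.
#' @param path output path.
#' @export
write_splits_nexus <- function(ss, path) {
  taxa <- ss$taxa
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#nexus", "",
    "BEGIN Taxa;",
    sprintf("DIMENSIONS ntax=%d;", length(taxa)),
    "TAXLABELS"), con)
  writeLines(sprintf("[%d] '%s'", seq_along(taxa), taxa), con)
  writeLines(c(";", "END; [Taxa]", "",
               "BEGIN Splits;",
               sprintf("DIMENSIONS ntax=%d nsplits=%d;",
                       length(taxa), nrow(ss$splits)),
               "FORMAT labels=no weights=yes confidences=no intervals=no;",
               "MATRIX"), con)
  for (i in seq_len(nrow(ss$splits))) {
    side <- which(key_to_mask(ss$splits$key[i]))
    writeLines(sprintf("[%d, size=%d] \t%.6f \t %s,", i, length(side),
                       ss$splits$freq[i], paste(side, collapse = " ")), con)
  }
  writeLines(c(";", "END; [Splits]"), con)
  invisible(path)
}
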
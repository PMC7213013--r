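# Reversible substitution models and the pruning log-likelihood engine
# underlying query placement.

#' Reversible nucleotide substitution model
#'
#' JC, HKY or GTR, optionally with discrete-Gamma rate variation across
#' sites. Exchangeabilities are given in alphabetical pair order
#' (A-C, A-G, A-T, C-G, C-T, G-T); the rate matrix is scaled to one
#' expected substitution per unit branch length.
#'
#' @param kind `"JC"`, `"HKY"` or `"GTR"`.
#' @param rates six nonnegative exchangeabilities (GTR); ignored for JC.
#' @param base_freqs four base frequencies summing to 1 (order A,C,G,T).
#' @param kappa transition/transversion rate ratio (HKY shortcut).
#' @param gamma_shape shape of the discrete-Gamma mixture, or `NULL` for
#'   rate homogeneity.
#' @param n_categories number of discrete-Gamma categories (default 4).
#' @return object of class `subst_model` with the cached spectral
#'   decomposition used by [prob_matrix()].
#' @export
subst_model <- function(kind = c("JC", "HKY", "GTR"), rates = rep(1, 6),
                        base_freqs = rep(0.25, 4), kappa = NULL,
                        gamma_shape = NULL, n_categories = 4L) {
  kind <- match.arg(kind)
  if (kind == "JC") {
    rates <- rep(1, 6)
    base_freqs <- rep(0.25, 4)
  } else if (kind == "HKY") {
    if (is.null(kappa)) kappa <- 2
    rates <- c(1, kappa, 1, 1, kappa, 1)
  }
  if (length(rates) != 6L || any(rates < 0)) stop("need 6 nonnegative rates")
  if (length(base_freqs) != 4L || any(base_freqs <= 0) ||
      abs(sum(base_freqs) - 1) > 1e-9)
    stop("base_freqs must be 4 positive numbers summing to 1")
  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop("gamma_shape must be positive")
  pi <- base_freqs
  # symmetric exchangeability matrix in pair order AC,AG,AT,CG,CT,GT
  S <- matrix(0, 4, 4)
  pair <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    S[pair[k, 1], pair[k, 2]] <- rates[k]
    S[pair[k, 2], pair[k, 1]] <- rates[k]
  }
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # symmetrize for a stable eigendecomposition: B = D Q D^-1, D = diag(sqrt(pi))
  D <- sqrt(pi)
  B <- (Q * rep(D, times = 4)) / rep(D, each = 4)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  A <- eg$vectors / D          # rows divided by sqrt(pi)
  Ainv <- t(eg$vectors) * rep(D, each = 4)
  structure(list(kind = kind, rates = rates / rates[6], base_freqs = pi,
                 gamma_shape = gamma_shape, n_categories = as.integer(n_categories),
                 Q = Q, eigen_values = eg$values, A = A, Ainv = Ainv),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(x$kind, " model; base freqs ", paste(sprintf("%.3f", x$base_freqs), collapse = "/"),
      if (!is.null(x$gamma_shape))
        sprintf("; Gamma(%g) x %d categories", x$gamma_shape, x$n_categories)
      else "; rate-homogeneous",
      "\n", sep = "")
  invisible(x)
}

#' Transition probability matrix P(t)
#' @param model a [subst_model()].
#' @param t branch length (expected substitutions per site).
#' @param rate rate multiplier (discrete-Gamma category rate).
#' @return 4x4 row-stochastic matrix (rows = from-state).
#' @export
prob_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("negative branch length")
  P <- model$A %*% (exp(model$eigen_values * t * rate) * model$Ainv)
  P[P < 0] <- 0
  P
}

# Mean-per-quantile discretization of a mean-1 Gamma(shape, shape).
gamma_category_rates <- function(shape, k) {
  if (is.null(shape)) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = shape)
  p_up <- stats::pgamma(b[-1L], shape = shape + 1, rate = shape)
  p_lo <- stats::pgamma(b[-(k + 1L)], shape = shape + 1, rate = shape)
  k * (p_up - p_lo)
}

# 4 x n matrix of tip partial likelihoods for a character vector; gaps and
# ambiguities give partial likelihood 1 over their compatible states.
tip_partials <- function(chars) {
  bases <- c("A", "C", "G", "T")
  out <- matrix(0, 4, length(chars))
  for (i in seq_along(chars)) {
    ch <- chars[i]
    states <- if (ch %in% names(IUPAC)) IUPAC[[ch]] else bases
    out[match(states, bases), i] <- 1
  }
  out
}

compress_patterns <- function(mat) {
  keys <- apply(mat, 2L, paste, collapse = "")
  first <- !duplicated(keys)
  list(mat = mat[, first, drop = FALSE],
       weights = as.vector(table(match(keys, keys[first]))[as.character(seq_len(sum(first)))]))
}

#' Phylogenetic log-likelihood by postorder pruning
#'
#' Felsenstein pruning with an optional discrete-Gamma rate mixture.
#' Accepts rooted or unrooted trees (basal multifurcations included); under
#' a reversible model the result is invariant to root placement.
#'
#' @param tree `phylo` with branch lengths (>= 0).
#' @param aln a [multi_aln()] whose rows cover the tree's tip labels.
#' @param model a [subst_model()].
#' @return log-likelihood (sum over sites).
#' @export
tree_loglik <- function(tree, aln, model) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  miss <- setdiff(tree$tip.label, rownames(aln))
  if (length(miss)) stop("no sequence for leaf: ", paste(miss, collapse = ", "))
  cp <- compress_patterns(unclass(aln)[tree$tip.label, , drop = FALSE])
  sum(cp$weights * site_logliks(tree, cp$mat, model))
}

# log-likelihood per (compressed) site pattern; mat rows follow tree$tip.label
site_logliks <- function(tree, mat, model) {
  ntip <- length(tree$tip.label)
  npat <- ncol(mat)
  tree <- ape::reorder.phylo(tree, "postorder")
  rates <- gamma_category_rates(model$gamma_shape, model$n_categories)
  lik <- matrix(0, nrow = npat, ncol = length(rates))
  root <- tree$edge[nrow(tree$edge), 1L]
  tips <- lapply(seq_len(ntip), function(i) tip_partials(mat[i, ]))
  for (ci in seq_along(rates)) {
    partial <- vector("list", ntip + tree$Nnode)
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
      Lc <- if (ch <= ntip) tips[[ch]] else partial[[ch]]
      contrib <- prob_matrix(model, tree$edge.length[k], rates[ci]) %*% Lc
      partial[[p]] <- if (is.null(partial[[p]])) contrib else partial[[p]] * contrib
    }
    lik[, ci] <- as.vector(model$base_freqs %*% partial[[root]])
  }
  log(rowMeans(lik))
}

#' Estimate model parameters on a reference alignment
#'
#' Direct numerical maximization of [tree_loglik()] over the free model
#' parameters (exchangeabilities, base frequencies, Gamma shape), holding
#' the tree fixed. Parameters are estimated once on the reference data and
#' then fixed during query placement.
#'
#' @param tree reference `phylo` with branch lengths.
#' @param aln a [multi_aln()].
#' @param kind model family (see [subst_model()]).
#' @param gamma estimate a discrete-Gamma shape as well?
#' @param n_categories Gamma categories.
#' @return fitted [subst_model()] with attribute `loglik`.
#' @export
estimate_model <- function(tree, aln, kind = c("GTR", "HKY", "JC"),
                           gamma = TRUE, n_categories = 4L) {
  kind <- match.arg(kind)
  cp <- compress_patterns(unclass(aln)[tree$tip.label, , drop = FALSE])
  counts <- table(factor(cp$mat[cp$mat %in% c("A", "C", "G", "T")],
                         levels = c("A", "C", "G", "T")))
  emp_freqs <- (as.numeric(counts) + 1) / sum(as.numeric(counts) + 1)
  n_rate <- switch(kind, JC = 0L, HKY = 1L, GTR = 5L)
  build <- function(par) {
    i <- 0L
    rates <- rep(1, 6)
    if (kind == "HKY") { rates <- c(1, exp(par[1]), 1, 1, exp(par[1]), 1); i <- 1L }
    if (kind == "GTR") { rates <- c(exp(par[1:5]), 1); i <- 5L }
    freqs <- if (kind == "JC") rep(0.25, 4) else {
      z <- c(exp(par[i + 1:3]), 1); i <- i + 3L; z / sum(z)
    }
    shape <- if (gamma) exp(par[length(par)]) else NULL
    subst_model(kind, rates = rates, base_freqs = freqs,
                gamma_shape = shape, n_categories = n_categories)
  }
  n_freq <- if (kind == "JC") 0L else 3L
  par0 <- c(rep(0, n_rate),
            if (n_freq) log(emp_freqs[1:3] / emp_freqs[4]),
            if (gamma) log(1))
  objective <- function(par)
    -sum(cp$weights * site_logliks(tree, cp$mat, build(par)))
  if (length(par0) == 0L) {
    fit <- subst_model("JC")
    attr(fit, "loglik") <- -objective(numeric(0))
    return(fit)
  }
  opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                      control = list(reltol = 1e-6, maxit = 2000))
  fit <- build(opt$par)
  attr(fit, "loglik") <- -opt$value
  fit
}
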
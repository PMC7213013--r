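# Shared helpers: IUPAC tables, log-sum-exp, union-find.

# IUPAC nucleotide ambiguity codes -> base sets
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' IUPAC code for a set of bases
#'
#' @param bases character vector of bases from \{A,C,G,T\}.
#' @return single IUPAC code covering exactly that set.
#' @examples
#' iupac_code(c("A", "T"))  # "W"
#' @export
iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  keys <- vapply(IUPAC, function(b) paste(sort(b), collapse = ""), character(1))
  hit <- names(keys)[match(key, keys)]
  if (is.na(hit)) stop("no IUPAC code for state set {", key, "}")
  hit
}

BASE_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-", `?` = "?",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D"
)

#' Reverse complement of a character vector of bases
#' @param x character vector (one base per element).
#' @return reverse-complemented character vector.
#' @export
reverse_complement <- function(x) {
  out <- BASE_COMPLEMENT[toupper(x)]
  if (anyNA(out)) stop("cannot complement states: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  unname(rev(out))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Minimal union-find on an environment (path-halving).
uf_new <- function(n) {
  e <- new.env(parent = emptyenv())
  e$parent <- seq_len(n)
  e
}
uf_find <- function(uf, i) {
  p <- uf$parent
  while (p[i] != i) {
    p[i] <- p[p[i]]
    i <- p[i]
  }
  uf$parent <- p
  i
}
uf_union <- function(uf, i, j) {
  ri <- uf_find(uf, i)
  rj <- uf_find(uf, j)
  if (ri != rj) uf$parent[rj] <- ri
  invisible(ri != rj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
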
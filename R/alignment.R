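# Multiple sequence alignments: container, readers, per-region diagnostics,
# concatenation, genotype collapsing and consensus sequences.

#' Multiple sequence alignment
#'
#' A taxa-by-columns character matrix over \{A,C,G,T, IUPAC ambiguity,
#' '-', '?', 'N'\}, optionally carrying named region partitions. This is the
#' substrate of all downstream diagnostics, recoding and network inference.
#'
#' @param x character matrix (one character per cell) or a list/character
#'   vector of equal-length sequence strings; row/element names are the taxon
#'   labels.
#' @param partitions named list of length-2 integer vectors `c(start, end)`
#'   (1-based, inclusive) mapping region names to column ranges. Ranges must
#'   be disjoint and within the alignment.
#' @param region optional free-text name for the region the alignment covers.
#' @return object of class `multi_aln`: the uppercased character matrix with
#'   attributes `partitions` and `region`.
#' @export
multi_aln <- function(x, partitions = NULL, region = NULL) {
  if (!is.matrix(x)) {
    if (is.list(x)) x <- vapply(x, paste, character(1), collapse = "")
    if (!is.character(x)) stop("x must be a character matrix or sequences")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("alignment rows have unequal lengths (", paste(unique(lens), collapse = ", "), ")")
    nm <- names(x)
    x <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(x) <- nm
  }
  if (is.null(rownames(x))) stop("taxa labels required as row names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon label: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  mat <- toupper(x)
  if (ncol(mat) > 0 && any(nchar(mat) != 1L))
    stop("alignment cells must be single characters")
  attr(mat, "partitions") <- validate_partitions(partitions, ncol(mat))
  attr(mat, "region") <- region
  class(mat) <- c("multi_aln", "matrix")
  mat
}

validate_partitions <- function(partitions, n_col) {
  if (is.null(partitions) || length(partitions) == 0L) return(NULL)
  if (is.null(names(partitions)) || any(names(partitions) == ""))
    stop("partitions must be named")
  cov <- integer(0)
  for (nm in names(partitions)) {
    p <- as.integer(partitions[[nm]])
    if (length(p) != 2L || p[1] < 1L || p[2] > n_col || p[1] > p[2])
      stop("partition '", nm, "' out of bounds [1, ", n_col, "]")
    idx <- p[1]:p[2]
    if (any(idx %in% cov)) stop("partition '", nm, "' overlaps another partition")
    cov <- c(cov, idx)
    partitions[[nm]] <- p
  }
  partitions
}

#' @export
print.multi_aln <- function(x, ...) {
  cat("Multiple alignment: ", nrow(x), " taxa x ", ncol(x), " columns\n", sep = "")
  if (!is.null(attr(x, "region"))) cat("  region: ", attr(x, "region"), "\n", sep = "")
  p <- attr(x, "partitions")
  if (!is.null(p))
    cat("  partitions: ",
        paste(sprintf("%s [%d-%d]", names(p),
                      vapply(p, `[`, 1L, 1L), vapply(p, `[`, 1L, 2L)),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Readers for the three alignment formats in common use for marker data:
#' FASTA, relaxed PHYLIP (taxon names of arbitrary length, sequential or
#' interleaved) and the NEXUS data/characters block.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"phylip"`, `"nexus"`; default guessed
#'   from the file extension.
#' @param region region name recorded on the alignment; defaults to the
#'   file base name.
#' @return a [multi_aln()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip", "nexus"),
                           region = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      fa = , fas = , fasta = , fna = "fasta",
      phy = , phylip = "phylip",
      nex = , nxs = , nexus = "nexus",
      "fasta")
  }
  seqs <- switch(format,
    fasta = {
      x <- ape::read.FASTA(path)
      lapply(as.character(x), function(s) toupper(s))
    },
    phylip = read_phylip_relaxed(path),
    nexus = {
      x <- ape::read.nexus.data(path)
      lapply(x, toupper)
    })
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment rows have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon label: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  mat <- do.call(rbind, seqs)
  rownames(mat) <- names(seqs)
  multi_aln(mat, region = region %||% sub("\\.[^.]*$", "", basename(path)))
}

# Relaxed PHYLIP: header "ntax nchar", names are whitespace-delimited tokens
# of any length; sequential or interleaved (continuation blocks may repeat
# the names or be bare sequence lines in taxon order).
read_phylip_relaxed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  if (length(lines) < 2L) stop("not a PHYLIP file: ", path)
  hdr <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  if (length(hdr) < 2L || anyNA(hdr)) stop("bad PHYLIP header: ", lines[1])
  ntax <- hdr[1]; nchar_exp <- hdr[2]
  body <- lines[-1]
  if (length(body) < ntax) stop("PHYLIP file truncated")
  nm <- character(ntax); seqs <- vector("list", ntax)
  for (i in seq_len(ntax)) {
    tok <- strsplit(body[i], "\\s+")[[1]]
    nm[i] <- tok[1]
    seqs[[i]] <- paste(tok[-1], collapse = "")
  }
  extra <- body[-seq_len(ntax)]
  i <- 0L
  for (ln in extra) {
    i <- i %% ntax + 1L
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] %in% nm) {
      i <- match(tok[1], nm)
      tok <- tok[-1]
    }
    seqs[[i]] <- paste0(seqs[[i]], paste(tok, collapse = ""))
  }
  out <- strsplit(toupper(unlist(seqs)), "", fixed = TRUE)
  names(out) <- nm
  if (any(lengths(out) != nchar_exp))
    stop("PHYLIP sequence length disagrees with header (expected ",
         nchar_exp, ")")
  out
}

#' Read a partition table
#'
#' Plain-text lines of the form `name = start-end` with 1-based inclusive
#' column coordinates (lines starting with `#` are ignored).
#'
#' @param path file path.
#' @return named list of `c(start, end)` integer vectors.
#' @export
read_partitions <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^(.+?)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)$", ln))[[1]]
    if (length(m) != 4L) stop("cannot parse partition line: ", ln)
    out[[trimws(m[2])]] <- c(as.integer(m[3]), as.integer(m[4]))
  }
  out
}

#' Extract one region of a partitioned alignment
#' @param aln a [multi_aln()] with partitions.
#' @param name region name.
#' @return a [multi_aln()] restricted to that region's columns.
#' @export
aln_region <- function(aln, name) {
  p <- attr(aln, "partitions")
  if (is.null(p) || !(name %in% names(p))) stop("no partition named '", name, "'")
  r <- p[[name]]
  multi_aln(unclass(aln)[, r[1]:r[2], drop = FALSE], region = name)
}

#' Alignment diagnostics: duplicates, gappyness, distinct patterns
#'
#' Computes the three per-region summary statistics used to characterize
#' marker alignments: NLD, the number of literally duplicate (identical)
#' sequences; PUC, the proportion of undetermined matrix cells (gappyness);
#' and DAP, the number of distinct alignment patterns (distinct column
#' vectors, gap states included, unweighted).
#'
#' @param aln a [multi_aln()]; must be non-empty.
#' @param undetermined characters counted as undetermined cells. IUPAC
#'   partial ambiguities are determined and excluded by default.
#' @return object of class `aln_diagnostics`: list with `n_taxa`,
#'   `n_columns`, `nld`, `puc`, `dap`.
#' @export
diagnostics <- function(aln, undetermined = c("-", "?", "N")) {
  if (nrow(aln) == 0L || ncol(aln) == 0L) stop("empty alignment")
  mat <- unclass(aln)
  rows <- apply(mat, 1L, paste, collapse = "")
  cols <- apply(mat, 2L, paste, collapse = "")
  out <- list(
    n_taxa = nrow(mat),
    n_columns = ncol(mat),
    nld = nrow(mat) - length(unique(rows)),
    puc = mean(mat %in% undetermined),
    dap = length(unique(cols)),
    region = attr(aln, "region")
  )
  class(out) <- "aln_diagnostics"
  out
}

#' @export
print.aln_diagnostics <- function(x, ...) {
  cat(sprintf("%s%d x %d | NLD %d | PUC %.1f%% | DAP %d\n",
              if (is.null(x$region)) "" else paste0(x$region, ": "),
              x$n_taxa, x$n_columns, x$nld, 100 * x$puc, x$dap))
  invisible(x)
}

#' Diagnostics for every partition of an alignment
#'
#' @param aln a partitioned [multi_aln()].
#' @param undetermined see [diagnostics()].
#' @return data frame with one row per region (plus `concatenated` if the
#'   alignment has more than one partition).
#' @export
diagnostics_by_region <- function(aln, undetermined = c("-", "?", "N")) {
  p <- attr(aln, "partitions")
  regions <- if (is.null(p)) list(whole = aln) else
    stats::setNames(lapply(names(p), aln_region, aln = aln), names(p))
  rows <- lapply(names(regions), function(nm) {
    d <- diagnostics(regions[[nm]], undetermined)
    data.frame(region = nm, n_taxa = d$n_taxa, n_columns = d$n_columns,
               nld = d$nld, puc = d$puc, dap = d$dap)
  })
  out <- do.call(rbind, rows)
  if (length(regions) > 1L) {
    d <- diagnostics(aln, undetermined)
    out <- rbind(out, data.frame(region = "concatenated", n_taxa = d$n_taxa,
                                 n_columns = d$n_columns, nld = d$nld,
                                 puc = d$puc, dap = d$dap))
  }
  out
}

#' Concatenate region alignments into one partitioned matrix
#'
#' Taxon sets may differ between regions; taxa absent from a region are
#' padded with `missing_fill`. Column order is preserved within regions and
#' each input becomes a named partition of the result.
#'
#' @param alns list of [multi_aln()] objects; names (or their `region`
#'   attributes) become partition names.
#' @param missing_fill single character used for absent taxa (default `"?"`).
#' @return a partitioned [multi_aln()] over the union of taxa, in order of
#'   first appearance.
#' @export
concatenate <- function(alns, missing_fill = "?") {
  if (inherits(alns, "multi_aln")) alns <- list(alns)
  stopifnot(length(alns) >= 1L, nchar(missing_fill) == 1L)
  nms <- names(alns)
  if (is.null(nms)) nms <- rep("", length(alns))
  for (i in seq_along(alns)) {
    if (nms[i] == "")
      nms[i] <- attr(alns[[i]], "region") %||% paste0("region", i)
  }
  if (anyDuplicated(nms)) nms <- make.unique(nms, sep = "_")
  taxa <- unique(unlist(lapply(alns, rownames)))
  blocks <- vector("list", length(alns))
  partitions <- list()
  at <- 1L
  for (i in seq_along(alns)) {
    a <- unclass(alns[[i]])
    blk <- matrix(missing_fill, nrow = length(taxa), ncol = ncol(a),
                  dimnames = list(taxa, NULL))
    blk[rownames(a), ] <- a
    blocks[[i]] <- blk
    partitions[[nms[i]]] <- c(at, at + ncol(a) - 1L)
    at <- at + ncol(a)
  }
  multi_aln(do.call(cbind, blocks), partitions = partitions,
            region = paste(nms, collapse = "+"))
}

#' Collapse alignment rows into genotypes
#'
#' Accessions sharing the same substitution pattern are collected into one
#' genotype. With `ignore_indels = TRUE` (the default, matching how
#' statistical-parsimony networks treat plastid/ITS data) equality is
#' evaluated only on columns that are gap-free in every taxon; the remaining
#' (gap-bearing) columns are recorded per accession as an indel-pattern
#' fingerprint (`subtype_key`), so genotypes may collect several indel
#' subtypes.
#'
#' @param aln a non-empty [multi_aln()].
#' @param ignore_indels collapse across indel variation (see above).
#' @return object of class `genotype_set`: list with `states` (genotype x
#'   substitution-character matrix), `members` (list of accession vectors,
#'   in input order of first member), `frequency`, `subtype_key` (per-member
#'   fingerprints, only if `ignore_indels`) and `columns` (source columns of
#'   the state matrix).
#' @export
collapse_to_genotypes <- function(aln, ignore_indels = TRUE) {
  if (nrow(aln) == 0L) stop("empty alignment")
  mat <- unclass(aln)
  if (ignore_indels) {
    gap_free <- colSums(mat == "-") == 0L
    sub_cols <- which(gap_free)
  } else {
    sub_cols <- seq_len(ncol(mat))
  }
  states <- mat[, sub_cols, drop = FALSE]
  key <- apply(states, 1L, paste, collapse = "")
  first <- !duplicated(key)
  uniq <- key[first]
  idx <- match(key, uniq)
  members <- split(rownames(mat), idx)
  members <- members[order(as.integer(names(members)))]
  out <- list(
    ids = seq_along(uniq),
    states = states[first, , drop = FALSE],
    members = stats::setNames(unname(members), paste0("g", seq_along(uniq))),
    frequency = as.integer(lengths(members)),
    columns = sub_cols
  )
  rownames(out$states) <- paste0("g", seq_along(uniq))
  if (ignore_indels && length(sub_cols) < ncol(mat)) {
    rest <- mat[, setdiff(seq_len(ncol(mat)), sub_cols), drop = FALSE]
    out$subtype_key <- stats::setNames(
      apply(rest, 1L, function(r) paste(r[r != "-"], collapse = "")),
      rownames(mat))
  }
  class(out) <- "genotype_set"
  out
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("Genotype set: ", length(x$ids), " genotypes over ",
      ncol(x$states), " substitution characters (",
      sum(x$frequency), " accessions)\n", sep = "")
  invisible(x)
}

#' Majority-rule consensus sequence of a genotype set
#'
#' Per column, the strict-majority state over genotypes (each genotype
#' counted once, unweighted by frequency). Ties are resolved either by the
#' IUPAC ambiguity code of the tied bases or by the state of the earliest
#' genotype among the tied ones.
#'
#' @param genotypes a `genotype_set` or a character state matrix.
#' @param tie_rule `"ambiguity"` (default) or `"first"`.
#' @return character vector of consensus states, one per column.
#' @export
consensus_sequence <- function(genotypes, tie_rule = c("ambiguity", "first")) {
  tie_rule <- match.arg(tie_rule)
  states <- if (inherits(genotypes, "genotype_set")) genotypes$states else genotypes
  if (is.null(dim(states))) stop("need a state matrix")
  if (nrow(states) == 0L) stop("need at least one genotype")
  apply(states, 2L, function(col) {
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    if (tie_rule == "first") return(col[col %in% top][1L])
    bases <- top[top %in% names(IUPAC)]
    if (length(bases) == length(top)) iupac_code(unlist(IUPAC[bases])) else
      sort(top)[1L]
  })
}
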
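# Recoding of length-polymorphic alignments into reduced character matrices.
#
# Four sequence-pattern categories are distinguished at the intra-clade
# level: (i) SNPs, one character per variable column; (ii) indels, one
# presence/absence character per shared gap event; (iii) length-polymorphic
# tracts (LP), whose pure length variation is excluded and only internal
# point mutations emit characters; (iv) oligo-nucleotide motifs (ONM),
# linked mutations over a short window recoded as one multistate character
# (inversions are a special ONM). Hypervariable regions can be excluded
# outright (category EXCLUDE).

EVENT_CATEGORIES <- c("SNP", "INDEL", "LP", "ONM", "EXCLUDE")

#' Event annotation table
#'
#' @param category character vector over SNP/INDEL/LP/ONM/EXCLUDE.
#' @param start,end 1-based inclusive column coordinates.
#' @param note free text per event.
#' @param variants optional list (one element per event) of named character
#'   vectors mapping taxon -> state label, used for ONM/LP events whose
#'   variants are expert-annotated.
#' @return data frame of class `event_table` with a `variants` list column.
#' @export
event_table <- function(category = character(), start = integer(),
                        end = integer(), note = "", variants = NULL) {
  category <- toupper(as.character(category))
  if (!all(category %in% EVENT_CATEGORIES))
    stop("unknown event category: ",
         paste(setdiff(category, EVENT_CATEGORIES), collapse = ", "))
  n <- length(category)
  out <- data.frame(category = category, start = as.integer(start),
                    end = as.integer(end), note = rep_len(note, n),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("event start exceeds end")
  if (any(out$category == "SNP" & out$start != out$end))
    stop("SNP events must cover single columns")
  out$variants <- if (is.null(variants)) rep(list(NULL), n) else variants
  class(out) <- c("event_table", "data.frame")
  out
}

#' Read an event annotation table from TSV
#'
#' Columns `category`, `start`, `end` (1-based inclusive), optional `note`.
#' @param path file path.
#' @return an [event_table()].
#' @export
read_event_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  event_table(df$category, df$start, df$end,
              note = if (is.null(df$note)) "" else df$note)
}

# events overlapping check on non-SNP rows; returns stops on violation
check_events <- function(events, n_col) {
  if (is.null(events) || nrow(events) == 0L) return(invisible(NULL))
  if (any(events$start < 1L | events$end > n_col))
    stop("event outside alignment bounds [1, ", n_col, "]")
  spans <- events[events$category != "SNP", , drop = FALSE]
  if (nrow(spans) > 1L) {
    o <- order(spans$start)
    s <- spans$start[o]; e <- spans$end[o]
    if (any(s[-1L] <= e[-length(e)]))
      stop("overlapping events in annotation table")
  }
  if (any(events$category == "SNP" & events$start != events$end))
    stop("SNP events must cover single columns")
  invisible(NULL)
}

#' Detect shared indel (gap) events in an alignment
#'
#' Maximal gap runs that share identical start and end coordinates across
#' the taxa bearing them are grouped into one candidate INDEL event. When
#' candidate events overlap (nested or staggered runs), the best-supported
#' run is kept and the others are dropped, so the returned events are
#' pairwise disjoint; taxa gapped over a sub- or super-range of a kept event
#' receive a missing state at recoding time.
#'
#' @param aln a [multi_aln()].
#' @return an [event_table()] of INDEL events, sorted by start; attribute
#'   `taxa` holds, per event, the taxa whose gap run matches it exactly.
#' @export
detect_indel_events <- function(aln) {
  mat <- unclass(aln)
  runs <- list()
  for (tx in rownames(mat)) {
    g <- mat[tx, ] == "-"
    if (!any(g)) next
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      key <- paste(starts[k], ends[k], sep = ":")
      runs[[key]] <- c(runs[[key]], tx)
    }
  }
  if (length(runs) == 0L)
    return(structure(event_table(), taxa = list()))
  coords <- do.call(rbind, strsplit(names(runs), ":", fixed = TRUE))
  cand <- data.frame(start = as.integer(coords[, 1]),
                     end = as.integer(coords[, 2]),
                     support = lengths(runs))
  cand$taxa <- unname(runs)
  # greedy disjoint selection: support desc, then leftmost, then shortest
  cand <- cand[order(-cand$support, cand$start, cand$end), , drop = FALSE]
  keep <- logical(nrow(cand))
  occupied <- rep(FALSE, ncol(mat))
  for (i in seq_len(nrow(cand))) {
    idx <- cand$start[i]:cand$end[i]
    if (!any(occupied[idx])) {
      keep[i] <- TRUE
      occupied[idx] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  ev <- event_table(rep("INDEL", nrow(cand)), cand$start, cand$end)
  attr(ev, "taxa") <- cand$taxa
  ev
}

#' Detect length-polymorphic homopolymer tracts
#'
#' A tract is a maximal run of columns whose non-gap majority base is
#' constant (e.g. a multi-A motif), spanning at least `min_run` columns and
#' showing length variation (at least one gap cell). Pure length variation
#' inside a tract is not a character; recoding emits characters only for
#' point mutations internal to the tract.
#'
#' @param aln a [multi_aln()].
#' @param min_run minimum tract width in columns (default 5, a typical
#'   homopolymer-instability threshold).
#' @return an [event_table()] of LP events.
#' @export
detect_lp_motifs <- function(aln, min_run = 5L) {
  if (min_run < 3L) stop("min_run must be >= 3")
  mat <- unclass(aln)
  n_col <- ncol(mat)
  if (n_col == 0L) return(event_table())
  dominant <- character(n_col)
  for (j in seq_len(n_col)) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0L) { dominant[j] <- NA_character_; next }
    tab <- sort(table(col), decreasing = TRUE)
    # a column belongs to an X-tract when X is carried by >= half its bases
    dominant[j] <- if (tab[1L] * 2L >= length(col)) names(tab)[1L] else NA_character_
  }
  r <- rle(dominant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- !is.na(r$values) & r$lengths >= min_run
  starts <- starts[sel]; ends <- ends[sel]
  has_gap <- vapply(seq_along(starts), function(k)
    any(mat[, starts[k]:ends[k]] == "-"), logical(1))
  starts <- starts[has_gap]; ends <- ends[has_gap]
  event_table(rep("LP", length(starts)), starts, ends)
}

#' Recode an alignment into a reduced character matrix
#'
#' Applies an event annotation table: EXCLUDE columns are dropped; INDEL,
#' LP and ONM events each replace their columns by event-level characters
#' (INDEL: binary presence/absence; LP: one SNP-like character per internal
#' point mutation, pure length variation dropped; ONM: one multistate
#' character per event, states from `variants` or automatic labelling of
#' the distinct substrings). Remaining variable columns emit SNP characters;
#' constant columns are dropped; identical rows are collapsed into
#' haplotypes. Missing states (partial gap overlap, `N`, `?`) are `NA` and
#' never contribute to distances.
#'
#' @param aln a [multi_aln()].
#' @param events an [event_table()] or `NULL` (SNP-only recoding).
#' @return object of class `recoded_matrix`: haplotype x character state
#'   matrix (`NA` = missing) with attributes `categories`, `provenance`
#'   (source columns per character), `members` (haplotype -> accessions)
#'   and `weights` (all 1 by default).
#' @export
recode <- function(aln, events = NULL) {
  mat <- unclass(aln)
  check_events(events, ncol(mat))
  taken <- rep(FALSE, ncol(mat))          # columns consumed by events/EXCLUDE
  chars <- list()                         # per character: list(states, category, cols)
  if (!is.null(events) && nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      cat_i <- events$category[i]
      cols <- events$start[i]:events$end[i]
      if (cat_i == "SNP") next            # plain column, handled below
      taken[cols] <- TRUE
      if (cat_i == "EXCLUDE") next
      if (cat_i == "INDEL") {
        states <- apply(mat[, cols, drop = FALSE], 1L, function(r) {
          if (all(r == "-")) "0" else if (!any(r == "-")) "1" else NA_character_
        })
        chars[[length(chars) + 1L]] <- list(states = states, category = "INDEL",
                                            cols = cols, note = events$note[i])
      } else if (cat_i == "LP") {
        for (j in cols) {
          col <- mat[, j]
          det <- col[col %in% c("A", "C", "G", "T")]
          if (length(unique(det)) > 1L) {  # internal point mutation
            states <- ifelse(col %in% c("A", "C", "G", "T"), col, NA_character_)
            chars[[length(chars) + 1L]] <- list(states = states, category = "LP",
                                                cols = j, note = events$note[i])
          }
        }
      } else if (cat_i == "ONM") {
        vm <- events$variants[[i]]
        if (!is.null(vm)) {
          states <- unname(vm[rownames(mat)])
        } else {
          sub <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
          undet <- grepl("[N?]", sub)
          uniq <- unique(sub[!undet])
          states <- ifelse(undet, NA_character_,
                           paste0("v", match(sub, uniq)))
        }
        chars[[length(chars) + 1L]] <- list(states = states, category = "ONM",
                                            cols = cols, note = events$note[i])
      }
    }
  }
  # SNP characters from leftover variable columns
  for (j in which(!taken)) {
    col <- mat[, j]
    det <- col %in% c("A", "C", "G", "T")
    if (length(unique(col[det])) > 1L) {
      states <- ifelse(det, col, NA_character_)
      chars[[length(chars) + 1L]] <- list(states = states, category = "SNP",
                                          cols = j, note = "")
    }
  }
  smat <- if (length(chars)) do.call(cbind, lapply(chars, `[[`, "states")) else
    matrix(character(0), nrow = nrow(mat), ncol = 0L)
  rownames(smat) <- rownames(mat)
  # collapse identical rows (NA pattern included) into haplotypes
  key <- apply(smat, 1L, function(r) paste(ifelse(is.na(r), "\x01", r), collapse = "\x02"))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  members <- split(rownames(mat), idx)
  members <- members[order(as.integer(names(members)))]
  hmat <- smat[first, , drop = FALSE]
  rownames(hmat) <- paste0("h", seq_len(nrow(hmat)))
  if (ncol(hmat) > 0L)
    colnames(hmat) <- paste0("c", seq_len(ncol(hmat)))
  structure(hmat,
            categories = vapply(chars, `[[`, character(1), "category"),
            provenance = lapply(chars, function(ch) ch[c("category", "cols", "note")]),
            members = stats::setNames(unname(members), rownames(hmat)),
            weights = rep(1, length(chars)),
            class = c("recoded_matrix", "matrix"))
}

#' @export
print.recoded_matrix <- function(x, ...) {
  tab <- table(attr(x, "categories"))
  cat("Recoded matrix: ", nrow(x), " haplotypes x ", ncol(x), " characters",
      if (length(tab)) paste0(" (", paste(names(tab), tab, sep = ":", collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Convert a recoded SNP matrix back to an alignment view
#'
#' Useful for feeding an already-reduced matrix through alignment-level
#' tools; missing states become `?`.
#' @param x a `recoded_matrix`.
#' @return a [multi_aln()].
#' @export
as_multi_aln <- function(x) {
  m <- unclass(x)
  m[is.na(m)] <- "?"
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  multi_aln(m)
}

#' Write a recoded matrix as TSV plus a JSON provenance sidecar
#' @param x a `recoded_matrix`.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @export
write_recoded_matrix <- function(x, path) {
  m <- unclass(x)
  m[is.na(m)] <- "?"
  df <- data.frame(haplotype = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    categories = attr(x, "categories"),
    provenance = lapply(attr(x, "provenance"), function(p)
      list(category = p$category, columns = p$cols, note = p$note)),
    members = attr(x, "members")
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
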
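#' Multiple sequence alignments
#'
#' An `mt_aln` is a character matrix over `{A, C, G, T, -}` with one row per
#' sequence (unique rownames are the sequence IDs) and one column per
#' alignment position. Positions are 1-based throughout the package so that
#' coordinates match published variable-site tables directly.
#'
#' @param x character matrix of single characters, or a named character
#'   vector of equal-length sequence strings.
#' @return An object of class `mt_aln`.
#' @examples
#' aln <- as_mt_aln(c(s1 = "ACGT-", s2 = "ACGTT"))
#' n_sites(aln)
#' @export
as_mt_aln <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      abort("sequences must carry unique names")
    }
    if (length(unique(nchar(x))) != 1L) {
      abort("all sequences must have equal (aligned) length")
    }
    nm <- names(x)
    x <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(x) <- nm
  }
  m <- x
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    abort("alignment rows must carry unique sequence IDs")
  }
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "-"))
  if (length(bad) > 0) {
    abort(paste0(
      "illegal residue(s) in alignment: ",
      paste(bad, collapse = ", "),
      " (only A, C, G, T and '-' are accepted; ambiguity codes are rejected)"
    ))
  }
  if (ncol(m) < 1L) abort("alignment must have at least one column")
  structure(m, class = c("mt_aln", "matrix", "array"))
}

# internal fast-path constructor from a named vector of strings
strings_to_aln <- function(seqs) {
  m <- matrix("", nrow = length(seqs), ncol = nchar(seqs[[1]]),
              dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) m[i, ] <- strsplit(seqs[[i]], "")[[1]]
  as_mt_aln(m)
}

#' @export
print.mt_aln <- function(x, ...) {
  cat(sprintf("<mt_aln> %d sequences x %d columns\n", nrow(x), ncol(x)))
  show <- min(nrow(x), 12L)
  w <- min(ncol(x), 60L)
  for (i in seq_len(show)) {
    cat(sprintf("  %-28s %s%s\n", rownames(x)[i],
                paste(x[i, seq_len(w)], collapse = ""),
                if (ncol(x) > w) "..." else ""))
  }
  if (nrow(x) > show) cat(sprintf("  ... and %d more\n", nrow(x) - show))
  invisible(x)
}

#' @rdname as_mt_aln
#' @param aln an `mt_aln` alignment.
#' @export
n_sites <- function(aln) ncol(aln)

#' @rdname as_mt_aln
#' @export
seq_ids <- function(aln) rownames(aln)

# plain-matrix column subset that keeps the class
aln_cols <- function(aln, idx) {
  m <- unclass(aln)[, idx, drop = FALSE]
  structure(m, class = c("mt_aln", "matrix", "array"))
}

seq_chars <- function(aln, id) {
  if (!id %in% rownames(aln)) abort(paste0("sequence ID not found: ", id))
  unclass(aln)[id, ]
}

#' Read and write aligned FASTA
#'
#' `read_fasta()` parses a multi-FASTA file into an [as_mt_aln()] alignment,
#' upper-casing residues and failing hard (with the offending line number)
#' on ragged sequence lengths, duplicate IDs or illegal characters such as
#' IUPAC ambiguity codes. `write_fasta()` writes the alignment back; the
#' round trip is the identity on IDs, order and residues.
#'
#' @param path file path.
#' @return `read_fasta()` an `mt_aln`; `write_fasta()` the path, invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  ids <- character()
  seqs <- character()
  first_line <- integer()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, ">")) {
      cur <- trimws(sub("^>", "", ln))
      cur <- strsplit(cur, "[ \t]")[[1]][1]
      if (cur == "") abort(paste0("empty sequence ID at line ", i))
      if (cur %in% ids) abort(paste0("duplicate sequence ID '", cur, "' at line ", i))
      ids <- c(ids, cur)
      seqs <- c(seqs, "")
      first_line <- c(first_line, i)
    } else {
      if (is.null(cur)) abort(paste0("sequence data before any header at line ", i))
      chunk <- toupper(gsub("[ \t]", "", ln))
      if (grepl("[^ACGT-]", chunk)) {
        bad <- regmatches(chunk, regexpr("[^ACGT-]", chunk))
        abort(paste0("illegal character '", bad, "' at line ", i,
                     " (ambiguity codes are not accepted)"))
      }
      seqs[length(seqs)] <- paste0(seqs[length(seqs)], chunk)
    }
  }
  if (length(ids) == 0) abort(paste0("no sequences found in ", path))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1])[1]
    abort(paste0("ragged alignment: sequence '", ids[off], "' (starting line ",
                 first_line[off], ") has length ", lens[off],
                 " but '", ids[1], "' has length ", lens[1]))
  }
  strings_to_aln(setNames(seqs, ids))
}

#' @rdname read_fasta
#' @param aln an `mt_aln` alignment.
#' @param width residues per output line.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in rownames(aln)) {
    s <- paste(unclass(aln)[id, ], collapse = "")
    writeLines(paste0(">", id), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and write sequence-to-group assignments
#'
#' Groups are putative species hypotheses: a two-column TSV (`id`, `group`)
#' mapping each sequence ID to a group label.
#'
#' @param path file path.
#' @return a tibble with columns `id` and `group`.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) abort(paste0("no such groups file: ", path))
  df <- read.table(path, sep = "\t", header = FALSE, col.names = c("id", "group"),
                   colClasses = "character", quote = "")
  as_tibble(df)
}

#' @rdname read_groups
#' @param groups tibble/data.frame with columns `id` and `group`.
#' @export
write_groups <- function(groups, path) {
  write.table(groups[, c("id", "group")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# normalise a groups argument (tibble or named vector) into a named vector
# id -> group, checking coverage of `ids`
group_lookup <- function(groups, ids) {
  if (is.data.frame(groups)) {
    g <- setNames(as.character(groups$group), as.character(groups$id))
  } else {
    g <- groups
  }
  missing <- setdiff(ids, names(g))
  if (length(missing) > 0) {
    abort(paste0("sequence ID(s) with no group assignment: ",
                 paste(missing, collapse = ", ")))
  }
  g[ids]
}

#' Variable alignment columns
#'
#' Columns where more than one symbol occurs, a gap counting as a symbol
#' state, in ascending 1-based order.
#'
#' @param aln an `mt_aln` alignment.
#' @return integer vector of 1-based column indices.
#' @examples
#' variable_positions(as_mt_aln(c(a = "AC-", b = "ACT")))
#' @export
variable_positions <- function(aln) {
  if (nrow(aln) < 1L) abort("empty alignment")
  m <- unclass(aln)
  which(vapply(seq_len(ncol(m)), function(j) length(unique(m[, j])) > 1L,
               logical(1)))
}

#' Base composition per sequence
#'
#' Counts over non-gap residues and percentages over the ungapped length,
#' plus AT and GC content.
#'
#' @param aln an `mt_aln` alignment.
#' @param ids sequence IDs to profile (default: all).
#' @return tibble with one row per sequence: counts `A`,`C`,`G`,`T`,
#'   percentages `pct_*`, `at_content`, `gc_content` (percent) and
#'   `ungapped_length`.
#' @export
composition <- function(aln, ids = seq_ids(aln)) {
  purrr::map_dfr(ids, function(id) {
    s <- seq_chars(aln, id)
    s <- s[s != "-"]
    n <- length(s)
    cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(s == b), integer(1))
    tibble(
      id = id,
      A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
      pct_A = 100 * cnt[["A"]] / n, pct_C = 100 * cnt[["C"]] / n,
      pct_G = 100 * cnt[["G"]] / n, pct_T = 100 * cnt[["T"]] / n,
      at_content = 100 * (cnt[["A"]] + cnt[["T"]]) / n,
      gc_content = 100 * (cnt[["G"]] + cnt[["C"]]) / n,
      ungapped_length = n
    )
  })
}

#' Collapse sequences to haplotypes within groups
#'
#' Haplotypes are compared over the full gapped strings; multiplicities sum
#' to group sizes.
#'
#' @param aln an `mt_aln` alignment.
#' @param groups tibble (`id`, `group`) or named character vector.
#' @return tibble with columns `group`, `haplotype`, `n`, `ids` (list).
#' @export
collapse_haplotypes <- function(aln, groups) {
  g <- group_lookup(groups, seq_ids(aln))
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  purrr::map_dfr(unique(unname(g)), function(grp) {
    ids <- names(g)[g == grp]
    if (length(ids) == 0) {
      return(tibble(group = character(), haplotype = character(),
                    n = integer(), ids = list()))
    }
    sp <- split(ids, seqs[ids])
    tibble(
      group = grp,
      haplotype = names(sp),
      n = unname(lengths(sp)),
      ids = unname(sp)
    )
  })
}

#' Gap-aware pairwise site differences
#'
#' Counts, for one sequence pair, transitions (A<->G, C<->T), transversions
#' (all other base mismatches), indel events (maximal runs of columns gapped
#' in exactly one of the two sequences) and `compared_sites` (columns where
#' neither sequence has a gap). A gap-vs-base column is an indel, never a
#' nucleotide difference.
#'
#' @param aln an `mt_aln` alignment.
#' @param id1,id2 sequence IDs.
#' @return object of class `site_diff`: list with `transitions`,
#'   `transversions`, `indel_events`, `compared_sites`.
#' @examples
#' aln <- as_mt_aln(c(a = "AAGT", b = "AGG-"))
#' pairwise_site_diffs(aln, "a", "b")
#' @export
pairwise_site_diffs <- function(aln, id1, id2) {
  x <- seq_chars(aln, id1)
  y <- seq_chars(aln, id2)
  gx <- x == "-"
  gy <- y == "-"
  keep <- !gx & !gy
  xs <- x[keep]
  ys <- y[keep]
  mism <- xs != ys
  ts <- sum(mism & ((xs == "A" & ys == "G") | (xs == "G" & ys == "A") |
                      (xs == "C" & ys == "T") | (xs == "T" & ys == "C")))
  tv <- sum(mism) - ts
  one_gap <- xor(gx, gy)
  r <- rle(one_gap)
  indels <- sum(r$values)
  site_diff(ts, tv, indels, sum(keep))
}

#' @rdname pairwise_site_diffs
#' @param transitions,transversions,indel_events,compared_sites counts.
#' @export
site_diff <- function(transitions, transversions, indel_events = 0L,
                      compared_sites = 0L) {
  out <- list(transitions = as.integer(transitions),
              transversions = as.integer(transversions),
              indel_events = as.integer(indel_events),
              compared_sites = as.integer(compared_sites))
  if (any(unlist(out) < 0)) abort("site_diff counts must be non-negative")
  if (out$transitions + out$transversions > out$compared_sites) {
    abort("transitions + transversions cannot exceed compared_sites")
  }
  structure(out, class = "site_diff")
}

#' @export
print.site_diff <- function(x, ...) {
  cat(sprintf(
    "<site_diff> ts=%d tv=%d indel_events=%d compared_sites=%d\n",
    x$transitions, x$transversions, x$indel_events, x$compared_sites))
  invisible(x)
}
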
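#' Parse a dot-bracket secondary structure
#'
#' Vienna convention: `(` and `)` are paired columns, `.` unpaired, `-`
#' positions without structural assignment (e.g. alignment gap columns).
#' Brackets must balance and nest properly.
#'
#' @param text dot-bracket string.
#' @param aln_length if given, the annotation length must match it.
#' @return list of class `dot_bracket`: `annotation` (string) and
#'   `pair_table` (integer vector, 0 for unpaired, else 1-based partner).
#' @examples
#' parse_dot_bracket("((..))")$pair_table
#' @export
parse_dot_bracket <- function(text, aln_length = NULL) {
  chars <- strsplit(text, "")[[1]]
  bad <- setdiff(unique(chars), c("(", ")", ".", "-"))
  if (length(bad) > 0) {
    abort(paste0("illegal dot-bracket character(s): ", paste(bad, collapse = " ")))
  }
  if (!is.null(aln_length) && length(chars) != aln_length) {
    abort(sprintf("structure length %d does not match alignment length %d",
                  length(chars), aln_length))
  }
  pair <- integer(length(chars))
  stack <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) {
        abort(paste0("unbalanced ')' at position ", i))
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair[i] <- j
      pair[j] <- i
    }
  }
  if (length(stack) > 0) {
    abort(paste0("unbalanced '(' at position ", stack[length(stack)]))
  }
  structure(list(annotation = text, pair_table = pair), class = "dot_bracket")
}

#' @export
print.dot_bracket <- function(x, ...) {
  cat(sprintf("<dot_bracket> %d columns, %d base pairs\n",
              nchar(x$annotation), sum(x$pair_table > 0) / 2))
  invisible(x)
}

CANONICAL_PAIRS <- c("AT", "TA", "GC", "CG", "GT", "TG")  # T read as U; GU wobble allowed

#' Classify variable sites against a secondary structure
#'
#' For every sequence pair and every column where the pair differs:
#' unpaired columns are `"unpaired"`; a paired column is
#' `"stem_preserving"` if **both** sequences form a canonical pair
#' (Watson-Crick or GU wobble, T read as U) with the partner column, else
#' `"stem_breaking"`. A gap at a paired column is `"stem_breaking"` with an
#' `"indel-in-stem"` note. Invariant columns are never classified.
#'
#' @param aln an `mt_aln` alignment.
#' @param structure a [parse_dot_bracket()] result of matching length.
#' @param pairs optional 2-column matrix/list of ID pairs (default: all
#'   unordered pairs).
#' @return tibble with columns `site`, `partner` (0 if unpaired), `id1`,
#'   `id2`, `class`, `note`.
#' @export
classify_variable_sites <- function(aln, structure, pairs = NULL) {
  if (nchar(structure$annotation) != ncol(aln)) {
    abort("structure length does not match alignment length")
  }
  ids <- seq_ids(aln)
  if (is.null(pairs)) pairs <- combn(ids, 2L, simplify = FALSE)
  pt <- structure$pair_table
  m <- unclass(aln)
  canonical <- function(b1, b2) paste0(b1, b2) %in% CANONICAL_PAIRS
  purrr::map_dfr(pairs, function(p) {
    x <- m[p[1], ]; y <- m[p[2], ]
    diff_cols <- which(x != y)
    purrr::map_dfr(diff_cols, function(col) {
      partner <- pt[col]
      if (partner == 0L) {
        cls <- "unpaired"; note <- ""
      } else if (x[col] == "-" || y[col] == "-" ||
                 x[partner] == "-" || y[partner] == "-") {
        cls <- "stem_breaking"; note <- "indel-in-stem"
      } else if (canonical(x[col], x[partner]) && canonical(y[col], y[partner])) {
        cls <- "stem_preserving"; note <- ""
      } else {
        cls <- "stem_breaking"; note <- ""
      }
      tibble(site = col, partner = partner, id1 = p[1], id2 = p[2],
             class = cls, note = note)
    })
  })
}

#' Read a dot-bracket file
#'
#' First non-empty, non-`>` line of the file is taken as the annotation.
#'
#' @param path file path.
#' @param aln_length optional expected length.
#' @export
read_dot_bracket <- function(path, aln_length = NULL) {
  if (!file.exists(path)) abort(paste0("no such structure file: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  if (length(lines) == 0) abort(paste0("no structure line found in ", path))
  parse_dot_bracket(lines[[1]], aln_length)
}
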
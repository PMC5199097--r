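#' Neighbour-joining tree
#'
#' Saitou–Nei agglomeration: iteratively join the pair minimising the
#' rate-corrected criterion
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`,
#' with branch lengths from the standard two-point formulas and the final
#' three clusters resolved by the three-point formulas. Ties in Q are
#' broken by the lexicographically smallest (sorted) pair of cluster
#' labels, making runs reproducible. Negative branch lengths are clamped
#' to zero with the deficit moved to the adjacent (sister) branch; raw
#' values are kept in the `raw_lengths` attribute.
#'
#' @param dm a [distance_matrix()] (or plain symmetric matrix with
#'   dimnames) over at least 3 IDs.
#' @return an unrooted `ape::phylo` tree.
#' @examples
#' aln <- build_study_alignment(study_fixture_spec())
#' tr <- nj_tree(distance_matrix(aln, "k2p"))
#' @export
nj_tree <- function(dm) {
  d <- dm_values(dm)
  if (is.null(rownames(d))) abort("distance matrix needs IDs as dimnames")
  if (any(!is.finite(d))) {
    abort("distance matrix contains non-finite entries (saturated pairs?)")
  }
  n <- nrow(d)
  if (n < 3L) abort("neighbour joining needs at least 3 taxa")
  labels <- rownames(d)       # current cluster labels (Newick fragments keyed separately)
  newick <- setNames(labels, labels)
  raw <- character()

  fmt <- function(x) sprintf("%.10g", x)

  while (nrow(d) > 3L) {
    m <- nrow(d)
    rs <- rowSums(d)
    best <- NULL
    best_q <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        q <- (m - 2) * d[i, j] - rs[i] - rs[j]
        key <- sort(c(rownames(d)[i], rownames(d)[j]))
        if (q < best_q - 1e-12 ||
            (abs(q - best_q) <= 1e-12 && !is.null(best) &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best_q <- q
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    bi <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    raw <- c(raw, sprintf("%s:%s %s:%s", rownames(d)[i], fmt(bi),
                          rownames(d)[j], fmt(bj)))
    # clamp negatives, moving the deficit to the sister branch
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- abs(max(bi, 0)); bj <- abs(max(bj, 0))  # abs() drops IEEE -0

    li <- rownames(d)[i]; lj <- rownames(d)[j]
    new_label <- paste0("(", li, ",", lj, ")")
    new_newick <- paste0("(", newick[[li]], ":", fmt(bi), ",",
                         newick[[lj]], ":", fmt(bj), ")")
    dk <- (d[i, -c(i, j), drop = TRUE] + d[j, -c(i, j), drop = TRUE] - d[i, j]) / 2
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, dk), c(dk, 0))
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- new_label
    newick <- newick[setdiff(names(newick), c(li, lj))]
    newick[[new_label]] <- new_newick
  }

  # resolve the last three clusters by the three-point formulas
  l <- rownames(d)
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  raw <- c(raw, sprintf("%s:%s %s:%s %s:%s", l[1], fmt(b1), l[2], fmt(b2),
                        l[3], fmt(b3)))
  b <- abs(pmax(c(b1, b2, b3), 0))
  txt <- paste0("(", newick[[l[1]]], ":", fmt(b[1]), ",",
                newick[[l[2]]], ":", fmt(b[2]), ",",
                newick[[l[3]]], ":", fmt(b[3]), ");")
  tree <- ape::read.tree(text = txt)
  attr(tree, "raw_lengths") <- raw
  tree
}

# canonical keys for the non-trivial bipartitions (splits) of an unrooted
# phylo: each key is the sorted leaf set of the split side NOT containing
# the alphabetically first leaf, "|"-joined.
tree_splits <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  n_tip <- length(tips)
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(n_tip)) desc[[i]] <- tips[i]
  for (e in rev(seq_len(nrow(tree$edge)))) {   # edges in pruningwise-ish order
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  keys <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n_tip) next                   # trivial split
    side <- desc[[child]]
    if (length(side) <= 1L || length(side) >= n_tip - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Neighbour-joining tree with column-bootstrap support
#'
#' Builds the NJ tree on the full alignment, then resamples alignment
#' columns with replacement `replicates` times; the support of an internal
#' split is the percentage of replicate NJ trees containing it, attached
#' as integer node labels.
#'
#' @param aln an `mt_aln` alignment.
#' @param model distance model passed to [distance_matrix()].
#' @param replicates bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param deletion deletion mode for [distance_matrix()].
#' @return an `ape::phylo` with `node.label` giving percent support (empty
#'   for the root/trivial nodes).
#' @export
bootstrap_support <- function(aln, model = "k2p", replicates = 1000L, seed,
                              deletion = "pairwise") {
  if (replicates < 1L) abort("replicates must be >= 1")
  if (missing(seed) || is.null(seed)) abort("a seed is required for bootstrapping")
  main <- nj_tree(distance_matrix(aln, model, deletion))
  main_splits <- tree_splits(main)
  counts <- setNames(numeric(length(main_splits)), main_splits)
  L <- ncol(aln)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      rep_aln <- aln_cols(aln, sample.int(L, L, replace = TRUE))
      rep_tree <- try(nj_tree(distance_matrix(rep_aln, model, deletion)),
                      silent = TRUE)
      if (inherits(rep_tree, "try-error")) next
      hits <- intersect(main_splits, tree_splits(rep_tree))
      counts[hits] <- counts[hits] + 1
    }
  })
  support <- 100 * counts / replicates
  annotate_splits(main, support)
}

# support value attached to the internal node realising split `key`
# (canonical form as produced by tree_splits); NA when absent
split_support_of <- function(tree, key) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  n_tip <- length(tips)
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(n_tip)) desc[[i]] <- tips[i]
  for (e in rev(seq_len(nrow(tree$edge)))) {
    desc[[tree$edge[e, 1]]] <- c(desc[[tree$edge[e, 1]]], desc[[tree$edge[e, 2]]])
  }
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    side <- desc[[node]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (identical(paste(sort(side), collapse = "|"), key)) {
      lab <- tree$node.label[node - n_tip]
      return(if (nzchar(lab)) as.numeric(lab) else NA_real_)
    }
  }
  NA_real_
}

# write split supports onto the internal node labels of `tree`
annotate_splits <- function(tree, support) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  n_tip <- length(tips)
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(n_tip)) desc[[i]] <- tips[i]
  for (e in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  labels <- rep("", tree$Nnode)
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    side <- desc[[node]]
    if (length(side) <= 1L || length(side) >= n_tip - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      labels[node - n_tip] <- as.character(round(support[[key]]))
    }
  }
  tree$node.label <- labels
  tree
}

#' Newick round trip
#'
#' Thin wrappers over `ape::read.tree()`/`ape::write.tree()` that fail
#' loudly on malformed input. Branch lengths survive the round trip to 10
#' significant digits; internal node labels carry bootstrap support.
#'
#' @param text,path Newick string / file path.
#' @param tree an `ape::phylo`.
#' @return `from_newick()` an `ape::phylo`; `to_newick()` a Newick string.
#' @export
from_newick <- function(text = NULL, path = NULL) {
  src <- if (!is.null(text)) text else {
    if (is.null(path) || !file.exists(path)) abort("no Newick text or readable file given")
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  if (!nzchar(trimws(src))) abort("empty Newick input")
  tree <- tryCatch(ape::read.tree(text = src),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) {
    abort(paste0("malformed Newick near character ",
                 regexpr("[^();,: [:alnum:]._-]|$", src)[1], ": ", src))
  }
  tree
}

#' @rdname from_newick
#' @export
to_newick <- function(tree, path = NULL, digits = 10L) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) writeLines(txt, path)
  txt
}
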
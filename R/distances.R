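#' p and Kimura two-parameter distances
#'
#' `p_distance()` is the raw proportion of differing sites among compared
#' (mutually ungapped) sites. `k2p_distance()` corrects for multiple hits
#' distinguishing transitions from transversions:
#' \deqn{d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q)}
#' with `P` and `Q` the transition and transversion proportions. Saturated
#' pairs (a non-positive logarithm argument) yield `NaN` with a warning.
#'
#' @param summary a [site_diff()] (or anything with `transitions`,
#'   `transversions`, `compared_sites`).
#' @return a single distance (substitutions/site).
#' @examples
#' k2p_distance(site_diff(9, 0, 0, 233))
#' @export
p_distance <- function(summary) {
  if (summary$compared_sites <= 0) abort("no compared sites: p-distance undefined")
  (summary$transitions + summary$transversions) / summary$compared_sites
}

#' @rdname p_distance
#' @export
k2p_distance <- function(summary) {
  if (summary$compared_sites <= 0) abort("no compared sites: K2P distance undefined")
  P <- summary$transitions / summary$compared_sites
  Q <- summary$transversions / summary$compared_sites
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    warn(sprintf(
      "saturated pair (P=%.4f, Q=%.4f): K2P distance is not finite", P, Q))
    return(NaN)
  }
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Pairwise distance matrix
#'
#' All unordered pairs via [pairwise_site_diffs()] and the chosen model.
#' Under `deletion = "complete"` every column containing any gap is removed
#' before counting; under `"pairwise"` (the default, and the study's
#' setting) each pair uses its own mutually ungapped columns.
#'
#' @param aln an `mt_aln` alignment with at least 2 sequences.
#' @param model `"k2p"` or `"p"`.
#' @param deletion `"pairwise"` or `"complete"`.
#' @return a symmetric numeric matrix of class `dist_mat` with `model` and
#'   `deletion` attributes and sequence IDs as dimnames.
#' @export
distance_matrix <- function(aln, model = c("k2p", "p"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (nrow(aln) < 2L) abort("need at least two sequences")
  if (deletion == "complete") {
    gapless <- which(colSums(unclass(aln) == "-") == 0L)
    if (length(gapless) == 0L) abort("complete deletion removed every column")
    aln <- aln_cols(aln, gapless)
  }
  ids <- seq_ids(aln)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  f <- if (model == "k2p") k2p_distance else p_distance
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d[i, j] <- d[j, i] <- f(pairwise_site_diffs(aln, ids[i], ids[j]))
    }
  }
  structure(d, model = model, deletion = deletion,
            class = c("dist_mat", "matrix", "array"))
}

dm_values <- function(dm) {
  m <- unclass(dm)
  attr(m, "model") <- NULL
  attr(m, "deletion") <- NULL
  m
}

#' @export
print.dist_mat <- function(x, ...) {
  cat(sprintf("<dist_mat> %d x %d, model=%s, deletion=%s\n", nrow(x), ncol(x),
              attr(x, "model") %||% "?", attr(x, "deletion") %||% "?"))
  print(round(dm_values(x), 6))
  invisible(x)
}

mean_cross <- function(dm, ids_x, ids_y) {
  mean(dm_values(dm)[ids_x, ids_y, drop = FALSE])
}

mean_within <- function(dm, ids) {
  if (length(ids) < 2L) return(NA_real_)
  m <- dm_values(dm)[ids, ids, drop = FALSE]
  mean(m[upper.tri(m)])
}

#' Within/between-group distance summary and net divergence
#'
#' Means over unordered sequence pairs: `d_within` per group (undefined,
#' `NA`, for singletons), `d_between` per group pair, and the net
#' divergence `Da = dXY - (dX + dY)/2`. The within-term of a singleton
#' group enters Da as 0 under the default `"singleton_zero"` policy, or as
#' the other group's within-mean under `"borrow_sister"`.
#'
#' @param dm a [distance_matrix()].
#' @param groups tibble (`id`, `group`) or named vector covering the matrix
#'   IDs.
#' @param singleton_policy `"singleton_zero"` or `"borrow_sister"`.
#' @return list of class `group_dist_summary` with tibbles `within`
#'   (`group`, `n`, `d_within`) and `between`
#'   (`group_x`, `group_y`, `d_between`, `Da`).
#' @export
group_summary <- function(dm, groups,
                          singleton_policy = c("singleton_zero", "borrow_sister")) {
  singleton_policy <- match.arg(singleton_policy)
  g <- group_lookup(groups, rownames(dm))
  grp_ids <- split(names(g), unname(g))
  within <- purrr::map_dfr(names(grp_ids), function(grp) {
    tibble(group = grp, n = length(grp_ids[[grp]]),
           d_within = mean_within(dm, grp_ids[[grp]]))
  })
  wi <- setNames(within$d_within, within$group)
  effective_within <- function(a, b) {
    da <- wi[[a]]
    if (is.na(da)) {
      da <- switch(singleton_policy,
        singleton_zero = 0,
        borrow_sister = {
          other <- wi[[b]]
          if (is.na(other)) 0 else other
        })
    }
    da
  }
  pairs <- if (length(grp_ids) >= 2L) {
    combn(sort(names(grp_ids)), 2L, simplify = FALSE)
  } else list()
  between <- purrr::map_dfr(pairs, function(p) {
    dxy <- mean_cross(dm, grp_ids[[p[1]]], grp_ids[[p[2]]])
    da <- dxy - (effective_within(p[1], p[2]) + effective_within(p[2], p[1])) / 2
    tibble(group_x = p[1], group_y = p[2], d_between = dxy, Da = da)
  })
  if (length(pairs) == 0L) {
    between <- tibble(group_x = character(), group_y = character(),
                      d_between = double(), Da = double())
  }
  structure(list(within = within, between = between,
                 singleton_policy = singleton_policy),
            class = "group_dist_summary")
}

#' @export
print.group_dist_summary <- function(x, ...) {
  cat("<group_dist_summary> (singleton policy:", x$singleton_policy, ")\n")
  cat("within:\n"); print(x$within)
  cat("between:\n"); print(x$between)
  invisible(x)
}

#' Column-bootstrap standard error of an alignment statistic
#'
#' Resamples alignment columns with replacement (same column count),
#' recomputes `statistic` on each replicate alignment, and returns the
#' standard deviation across replicates.
#'
#' @param aln an `mt_aln` alignment.
#' @param statistic function taking an `mt_aln` and returning one number.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed (mandatory for reproducibility).
#' @return list of class `boot_se`: `se`, `replicates` (numeric vector),
#'   `seed`.
#' @export
bootstrap_se <- function(aln, statistic, replicates = 1000L, seed) {
  if (replicates < 1L) abort("replicates must be >= 1")
  if (missing(seed) || is.null(seed)) abort("a seed is required for bootstrapping")
  L <- ncol(aln)
  vals <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      statistic(aln_cols(aln, sample.int(L, L, replace = TRUE)))
    }, numeric(1))
  })
  structure(list(se = stats::sd(vals), replicates = vals, seed = as.integer(seed)),
            class = "boot_se")
}

#' Write a distance matrix as TSV or PHYLIP
#'
#' @param dm a [distance_matrix()].
#' @param path output path.
#' @param format `"tsv"` (square, header row/column) or `"phylip"` (square).
#' @param digits decimals used at report time (internal values stay full
#'   precision).
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip"),
                                  digits = 6L) {
  format <- match.arg(format)
  m <- round(dm_values(dm), digits)
  if (format == "tsv") {
    fmt <- matrix(formatC(m, format = "f", digits = digits), nrow = nrow(m),
                  dimnames = dimnames(m))
    df <- data.frame(id = rownames(m), fmt, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(sprintf("%-10s", rownames(m)[i]),
                         sprintf("%.6f", m[i, ])), collapse = "  "), con)
    }
  }
  invisible(path)
}
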
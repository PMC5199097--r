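#' Barcode-gap partitioning configuration
#'
#' Geometric ladder of prior maximum intraspecific divergences from
#' `p_min` to `p_max` (`steps` points, inclusive), and the relative gap
#' width `X`: scanning the sorted distinct pairwise distances at or above
#' a prior, the first consecutive pair `(d_i, d_{i+1})` with
#' `d_{i+1} - d_i > X * d_i` marks the barcode gap, and `d_i` becomes the
#' clustering threshold (falling back to the prior itself when no such gap
#' exists). Groups are the connected components of the graph joining pairs
#' at or below the threshold, re-partitioned recursively until stable.
#' This is a deliberately simplified, fully specified variant of the
#' published ABGD partitioner; on trimodal barcode-like data it behaves
#' like the original defaults.
#'
#' @param p_min,p_max prior floor and ceiling (defaults 0.001 and 0.1).
#' @param steps ladder size (default 10).
#' @param X relative gap width multiplier (default 1.5).
#' @return list of class `abgd_config`.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, steps = 10L, X = 1.5) {
  if (!(p_min > 0 && p_min < p_max)) abort("need 0 < p_min < p_max")
  if (steps < 2L) abort("steps must be >= 2")
  if (X <= 0) abort("X must be positive")
  structure(list(p_min = p_min, p_max = p_max, steps = as.integer(steps), X = X),
            class = "abgd_config")
}

#' @rdname abgd_config
#' @param cfg an `abgd_config`.
#' @return `abgd_prior_ladder()`: numeric vector of priors.
#' @examples
#' abgd_prior_ladder(abgd_config())
#' @export
abgd_prior_ladder <- function(cfg = abgd_config()) {
  exp(seq(log(cfg$p_min), log(cfg$p_max), length.out = cfg$steps))
}

# threshold for one scan: first significant relative gap among sorted
# distinct distances >= prior, else the prior itself
abgd_threshold <- function(distances, prior, X) {
  ds <- sort(unique(distances))
  ds <- ds[ds >= prior]
  if (length(ds) >= 2L) {
    for (i in seq_len(length(ds) - 1L)) {
      if (ds[i + 1L] - ds[i] > X * ds[i]) return(ds[i])
    }
  }
  prior
}

# connected components of the graph joining pairs with distance <= thr
components_below <- function(d, thr) {
  n <- nrow(d)
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (d[i, j] <= thr && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  unname(split(rownames(d), comp))
}

#' Partition sequences by the barcode gap
#'
#' @param dm a [distance_matrix()] (finite entries).
#' @param prior prior maximum intraspecific divergence `P`.
#' @param X relative gap width (see [abgd_config()]).
#' @return list of class `abgd_partition`: `prior`, `threshold`, `groups`
#'   (list of ID character vectors, ordered by first member).
#' @examples
#' aln <- build_study_alignment(study_fixture_spec())
#' abgd_partition(distance_matrix(aln, "k2p"), prior = 0.001)
#' @export
abgd_partition <- function(dm, prior, X = 1.5) {
  d <- dm_values(dm)
  if (any(!is.finite(d))) abort("distance matrix must be finite for partitioning")
  if (prior <= 0) abort("prior must be positive")
  recurse <- function(ids) {
    if (length(ids) <= 1L) return(list(ids))
    sub <- d[ids, ids, drop = FALSE]
    off <- sub[upper.tri(sub)]
    thr <- abgd_threshold(off, prior, X)
    groups <- components_below(sub, thr)
    if (length(groups) == 1L) return(groups)
    unlist(lapply(groups, recurse), recursive = FALSE)
  }
  groups <- recurse(rownames(d))
  groups <- groups[order(vapply(groups, function(g) min(match(g, rownames(d))),
                                numeric(1)))]
  thr <- abgd_threshold(d[upper.tri(d)], prior, X)
  structure(list(prior = prior, threshold = thr, groups = groups),
            class = "abgd_partition")
}

#' @export
print.abgd_partition <- function(x, ...) {
  cat(sprintf("<abgd_partition> prior=%.6f threshold=%.6f -> %d group(s)\n",
              x$prior, x$threshold, length(x$groups)))
  for (g in x$groups) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' Scan the full prior ladder
#'
#' One [abgd_partition()] per ladder value, a stability summary (how many
#' priors yield each group count) and the ranked pairwise-distance data
#' behind the barcode-gap histogram.
#'
#' @param dm a [distance_matrix()].
#' @param cfg an [abgd_config()].
#' @return list of class `abgd_scan`: `partitions` tibble (`partition`,
#'   `prior`, `n_groups`, `groups` list-column), `distances` tibble of all
#'   unordered pairwise distances, `cfg`.
#' @export
abgd_scan <- function(dm, cfg = abgd_config()) {
  priors <- abgd_prior_ladder(cfg)
  parts <- lapply(priors, function(p) abgd_partition(dm, p, cfg$X))
  partitions <- tibble(
    partition = seq_along(priors),
    prior = priors,
    n_groups = vapply(parts, function(p) length(p$groups), integer(1)),
    groups = lapply(parts, function(p) p$groups)
  )
  d <- dm_values(dm)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  distances <- tibble(
    id1 = rownames(d)[idx[, 1]],
    id2 = colnames(d)[idx[, 2]],
    distance = d[upper.tri(d)]
  )
  structure(list(partitions = partitions, distances = distances, cfg = cfg),
            class = "abgd_scan")
}

#' @export
print.abgd_scan <- function(x, ...) {
  cat("<abgd_scan>\n")
  print(x$partitions[, c("partition", "prior", "n_groups")])
  invisible(x)
}

#' K/theta evolutionary-genetic-species test
#'
#' Under the evolutionary genetic species concept, two sister clades are
#' distinct species (with probability >= 0.95) when the ratio of the mean
#' between-clade distance `K` to the within-clade diversity `theta` is at
#' least 4. `theta` policies: `"max_within"` (the larger of the two
#' within-clade mean pairwise distances), `"supplied"` (an explicit
#' value, e.g. taken from another locus), or `"watterson_upper"` (an upper
#' bound `3 / (a_n * L)` with `a_n = sum(1/i, i < n)` for clades showing no
#' variation, using the larger clade's `n`).
#'
#' @param dm a [distance_matrix()] over both clades.
#' @param clade_a,clade_b disjoint character vectors of sequence IDs.
#' @param theta_policy one of `"max_within"`, `"supplied"`,
#'   `"watterson_upper"`, or `"auto"` (`"max_within"` where that is
#'   positive, falling back to `"watterson_upper"` for monomorphic
#'   clades; the policy actually applied is reported in the result).
#' @param theta explicit theta (required for `"supplied"`).
#' @param L sequence length (required for `"watterson_upper"`).
#' @param label optional comparison label.
#' @return list of class `ktheta`: `theta`, `K`, `ratio`, `n1`, `n2`,
#'   `decision` (TRUE = distinct species), `theta_policy`, `label`.
#' @examples
#' aln <- build_study_alignment(study_fixture_spec())
#' dm <- distance_matrix(aln, "k2p")
#' grp <- study_groups()
#' ktheta_test(dm, grp$id[grp$group == "chloroticum"],
#'             grp$id[grp$group == "brunneum"],
#'             theta_policy = "supplied", theta = 0.0043165)
#' @export
ktheta_test <- function(dm, clade_a, clade_b,
                        theta_policy = c("max_within", "supplied",
                                         "watterson_upper", "auto"),
                        theta = NULL, L = NULL, label = NULL) {
  theta_policy <- match.arg(theta_policy)
  if (length(intersect(clade_a, clade_b)) > 0) abort("clades must be disjoint")
  K <- mean_cross(dm, clade_a, clade_b)
  if (theta_policy == "auto") {
    w <- c(mean_within(dm, clade_a), mean_within(dm, clade_b))
    w <- w[!is.na(w)]
    theta_policy <- if (length(w) > 0 && max(w) > 0) "max_within" else "watterson_upper"
  }
  th <- switch(theta_policy,
    supplied = {
      if (is.null(theta)) abort("theta_policy 'supplied' needs an explicit theta")
      theta
    },
    max_within = {
      w <- c(mean_within(dm, clade_a), mean_within(dm, clade_b))
      w <- w[!is.na(w)]
      if (length(w) == 0) abort("theta unresolved: both clades are singletons")
      max(w)
    },
    watterson_upper = {
      if (is.null(L)) abort("theta_policy 'watterson_upper' needs the sequence length L")
      n <- max(length(clade_a), length(clade_b))
      if (n < 2) abort("theta unresolved: watterson_upper needs a clade with n >= 2")
      a_n <- sum(1 / seq_len(n - 1L))
      3 / (a_n * L)
    })
  if (!is.finite(th) || th <= 0) abort("theta unresolved: non-positive theta")
  ratio <- K / th
  structure(list(theta = th, K = K, ratio = ratio,
                 n1 = length(clade_a), n2 = length(clade_b),
                 decision = ratio >= 4, theta_policy = theta_policy,
                 label = label %||% "A/B"),
            class = "ktheta")
}

#' @export
print.ktheta <- function(x, ...) {
  cat(sprintf(
    "<ktheta> %s  theta=%.7f (%s)  K=%.7f  K/theta=%.2f  n=(%d, %d)  -> %s\n",
    x$label, x$theta, x$theta_policy, x$K, x$ratio, x$n1, x$n2,
    if (x$decision) "distinct species" else "not distinct"))
  invisible(x)
}
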
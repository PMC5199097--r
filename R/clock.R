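#' Tajima's relative rate test
#'
#' Non-parametric test of clock-like evolution for two ingroup taxa against
#' an outgroup. Over columns where none of the three sequences has a gap,
#' `m1` counts sites where taxon 1 carries the unique state (taxon 2 agrees
#' with the outgroup) and `m2` the symmetric count. Under a clock,
#' `E[m1] = E[m2]`, and `(m1 - m2)^2 / (m1 + m2)` is compared to a 1-df
#' chi-square (upper tail, no continuity correction).
#'
#' @param aln an `mt_aln` alignment.
#' @param taxon1,taxon2 ingroup sequence IDs.
#' @param outgroup outgroup sequence ID.
#' @return list of class `rrt`: `m1`, `m2`, `chi_square`, `p_value`, plus
#'   the taxa used.
#' @examples
#' aln <- simulate_clock_alignment(clock_sim_spec(length = 500, seed = 3))
#' tajima_rrt(aln, "A", "B", "C")
#' @export
tajima_rrt <- function(aln, taxon1, taxon2, outgroup) {
  x <- seq_chars(aln, taxon1)
  y <- seq_chars(aln, taxon2)
  o <- seq_chars(aln, outgroup)
  keep <- x != "-" & y != "-" & o != "-"
  x <- x[keep]; y <- y[keep]; o <- o[keep]
  m1 <- sum(x != y & y == o)
  m2 <- sum(y != x & x == o)
  chi <- if (m1 + m2 > 0) (m1 - m2)^2 / (m1 + m2) else 0
  p <- pchisq(chi, df = 1L, lower.tail = FALSE)
  structure(list(m1 = m1, m2 = m2, chi_square = chi, p_value = p,
                 taxon1 = taxon1, taxon2 = taxon2, outgroup = outgroup),
            class = "rrt")
}

#' @export
print.rrt <- function(x, ...) {
  cat(sprintf(
    "Tajima relative rate test: %s vs %s (outgroup %s)\n  m1=%d m2=%d chi^2=%.4f p=%.4g\n",
    x$taxon1, x$taxon2, x$outgroup, x$m1, x$m2, x$chi_square, x$p_value))
  invisible(x)
}

#' Net-divergence dating of a group pair
#'
#' Estimates the divergence time `T = Da / rate_2mu` where `Da` is the net
#' nucleotide divergence between the two groups (K2P, pairwise deletion)
#' and `rate_2mu` the divergence rate in substitutions/site/Myr. The
#' standard error of `Da` comes from a column bootstrap of the alignment,
#' and the 95% interval is `(Da +/- 1.96 SE) / rate_2mu`.
#'
#' @param aln an `mt_aln` alignment.
#' @param group_x,group_y disjoint, non-empty character vectors of
#'   sequence IDs.
#' @param rate_2mu divergence rate (substitutions/site/Myr); the study
#'   value is 0.006.
#' @param replicates bootstrap replicates; 0 skips the bootstrap (SE and
#'   CI become `NA`).
#' @param seed integer seed (required when `replicates > 0`).
#' @param singleton_policy passed to [group_summary()].
#' @param label optional name for the split.
#' @return list of class `dating_estimate`: `Da`, `SE`, `rate_2mu`, `T`,
#'   `ci_low`, `ci_high`, `label`, `n_x`, `n_y`.
#' @export
net_divergence_time <- function(aln, group_x, group_y, rate_2mu = 0.006,
                                replicates = 1000L, seed = NULL,
                                singleton_policy = "singleton_zero",
                                label = NULL) {
  if (length(group_x) == 0 || length(group_y) == 0) abort("groups must be non-empty")
  if (length(intersect(group_x, group_y)) > 0) abort("groups must be disjoint")
  if (rate_2mu <= 0) abort("rate_2mu must be positive")
  ids <- c(group_x, group_y)
  sub <- as_mt_aln(unclass(aln)[ids, , drop = FALSE])
  grp <- setNames(c(rep("X", length(group_x)), rep("Y", length(group_y))), ids)
  da_of <- function(a) {
    dm <- distance_matrix(a, "k2p", "pairwise")
    group_summary(dm, grp, singleton_policy)$between$Da[1]
  }
  Da <- da_of(sub)
  se <- NA_real_
  if (replicates > 0L) {
    se <- bootstrap_se(sub, da_of, replicates, seed)$se
  }
  structure(list(
    Da = Da, SE = se, rate_2mu = rate_2mu, T = Da / rate_2mu,
    ci_low = if (is.na(se)) NA_real_ else (Da - 1.96 * se) / rate_2mu,
    ci_high = if (is.na(se)) NA_real_ else (Da + 1.96 * se) / rate_2mu,
    label = label %||% "X/Y", n_x = length(group_x), n_y = length(group_y)
  ), class = "dating_estimate")
}

#' @export
print.dating_estimate <- function(x, ...) {
  cat(sprintf(
    "<dating_estimate> %s\n  Da=%.7f SE=%s rate=%g/Myr  T=%.3f Myr  95%% CI [%s, %s]\n",
    x$label, x$Da,
    if (is.na(x$SE)) "NA" else sprintf("%.7f", x$SE), x$rate_2mu, x$T,
    if (is.na(x$ci_low)) "NA" else sprintf("%.3f", x$ci_low),
    if (is.na(x$ci_high)) "NA" else sprintf("%.3f", x$ci_high)))
  invisible(x)
}

# tip sets of the two child clades under every binary internal node of a
# rooted guide tree whose tips are GROUP names
guide_tree_splits <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(n_tip)) desc[[i]] <- tree$tip.label[i]
  for (e in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  out <- list()
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(children) != 2L) {
      # root trifurcation on an unrooted guide tree: pair the smallest
      # child clade (the outlying group) against the union of the rest
      sets <- lapply(children, function(ch) desc[[ch]])
      ord <- order(lengths(sets))
      out[[length(out) + 1L]] <- list(x = sets[[ord[1]]],
                                      y = unlist(sets[ord[-1]]))
    } else {
      out[[length(out) + 1L]] <- list(x = desc[[children[1]]],
                                      y = desc[[children[2]]])
    }
  }
  out
}

#' Date every split of a guide tree
#'
#' One [net_divergence_time()] estimate per internal node of a rooted
#' guide tree over group names: the two sides of each split are the unions
#' of the member groups' sequences.
#'
#' @param aln an `mt_aln` alignment.
#' @param groups tibble (`id`, `group`) or named vector.
#' @param guide_tree `ape::phylo` whose tip labels are group names, or a
#'   Newick string.
#' @param rate_2mu,replicates,seed,singleton_policy as in
#'   [net_divergence_time()].
#' @return tibble with one row per split: `node`, `groups_x`, `groups_y`,
#'   `Da`, `SE`, `T`, `ci_low`, `ci_high`.
#' @export
date_all_splits <- function(aln, groups, guide_tree, rate_2mu = 0.006,
                            replicates = 1000L, seed = NULL,
                            singleton_policy = "singleton_zero") {
  if (is.character(guide_tree)) guide_tree <- from_newick(guide_tree)
  g <- group_lookup(groups, seq_ids(aln))
  grp_ids <- split(names(g), unname(g))
  missing <- setdiff(guide_tree$tip.label, names(grp_ids))
  if (length(missing) > 0) {
    abort(paste0("guide tree group(s) not in the alignment: ",
                 paste(missing, collapse = ", ")))
  }
  splits <- guide_tree_splits(guide_tree)
  rows <- purrr::imap(splits, function(sp, k) {
    est <- net_divergence_time(
      aln,
      group_x = unlist(grp_ids[sp$x], use.names = FALSE),
      group_y = unlist(grp_ids[sp$y], use.names = FALSE),
      rate_2mu = rate_2mu, replicates = replicates,
      seed = if (is.null(seed)) NULL else seed + k,
      singleton_policy = singleton_policy,
      label = paste(paste(sp$x, collapse = "+"), "/",
                    paste(sp$y, collapse = "+"))
    )
    tibble(node = est$label,
           groups_x = paste(sp$x, collapse = "+"),
           groups_y = paste(sp$y, collapse = "+"),
           Da = est$Da, SE = est$SE, T = est$T,
           ci_low = est$ci_low, ci_high = est$ci_high)
  })
  dplyr::bind_rows(rows)
}
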
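#' Tidiers and plots for result objects
#'
#' broom-style `tidy()`/`glance()` methods returning tibbles, and an
#' `autoplot()` for the barcode-gap histogram.
#'
#' @param x a result object.
#' @param ... unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy site_diff
#' @export
tidy.site_diff <- function(x, ...) {
  tibble(transitions = x$transitions, transversions = x$transversions,
         indel_events = x$indel_events, compared_sites = x$compared_sites)
}

#' @rdname tidiers
#' @method tidy rrt
#' @export
tidy.rrt <- function(x, ...) {
  tibble(taxon1 = x$taxon1, taxon2 = x$taxon2, outgroup = x$outgroup,
         m1 = x$m1, m2 = x$m2, chi_square = x$chi_square, p_value = x$p_value)
}

#' @rdname tidiers
#' @method glance rrt
#' @export
glance.rrt <- function(x, ...) {
  tibble(chi_square = x$chi_square, p_value = x$p_value,
         clock_rejected = x$p_value < 0.05)
}

#' @rdname tidiers
#' @method tidy dating_estimate
#' @export
tidy.dating_estimate <- function(x, ...) {
  tibble(node = x$label, Da = x$Da, SE = x$SE, rate_2mu = x$rate_2mu,
         T = x$T, ci_low = x$ci_low, ci_high = x$ci_high,
         n_x = x$n_x, n_y = x$n_y)
}

#' @rdname tidiers
#' @method tidy ktheta
#' @export
tidy.ktheta <- function(x, ...) {
  tibble(comparison = x$label, theta = x$theta, K = x$K, ratio = x$ratio,
         n1 = x$n1, n2 = x$n2, distinct = x$decision,
         theta_policy = x$theta_policy)
}

#' @rdname tidiers
#' @method tidy abgd_partition
#' @export
tidy.abgd_partition <- function(x, ...) {
  tibble(prior = x$prior, threshold = x$threshold,
         group = seq_along(x$groups),
         ids = vapply(x$groups, paste, character(1), collapse = ","))
}

#' @rdname tidiers
#' @method tidy abgd_scan
#' @export
tidy.abgd_scan <- function(x, ...) {
  dplyr::mutate(
    x$partitions[, c("partition", "prior", "n_groups")],
    groups = vapply(x$partitions$groups, function(gs) {
      paste(vapply(gs, paste, character(1), collapse = ","), collapse = " | ")
    }, character(1)))
}

#' @rdname tidiers
#' @method glance abgd_scan
#' @export
glance.abgd_scan <- function(x, ...) {
  counts <- table(x$partitions$n_groups)
  modal <- as.integer(names(counts)[which.max(counts)])
  tibble(n_priors = nrow(x$partitions),
         modal_n_groups = modal,
         n_priors_at_mode = as.integer(max(counts)),
         max_stable_prior = max(x$partitions$prior[x$partitions$n_groups == modal]))
}

#' @rdname tidiers
#' @method tidy group_dist_summary
#' @export
tidy.group_dist_summary <- function(x, ...) {
  dplyr::full_join(
    dplyr::rename(x$between, group = "group_x", other = "group_y"),
    dplyr::rename(x$within, group = "group"),
    by = "group")
}

#' @rdname tidiers
#' @method tidy boot_se
#' @export
tidy.boot_se <- function(x, ...) {
  tibble(replicate = seq_along(x$replicates), value = x$replicates)
}

#' @rdname tidiers
#' @method glance boot_se
#' @export
glance.boot_se <- function(x, ...) {
  tibble(se = x$se, n_replicates = length(x$replicates), seed = x$seed)
}

#' @rdname tidiers
#' @param object an `abgd_scan`.
#' @param binwidth histogram bin width (distance units).
#' @return `autoplot.abgd_scan()`: a ggplot of the pairwise-distance
#'   histogram, the classic visual of the barcode gap.
#' @method autoplot abgd_scan
#' @export
autoplot.abgd_scan <- function(object, binwidth = 0.0025, ...) {
  ggplot2::ggplot(object$distances, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(x = "pairwise K2P distance", y = "number of pairs",
                  title = "Pairwise distance distribution (barcode gap)") +
    ggplot2::theme_minimal()
}
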
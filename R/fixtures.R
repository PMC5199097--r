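#' Specification of the printed-study alignment
#'
#' The study alignment (11 ingroup sequences, 234 columns of the third
#' domain of the 12S mt rRNA) is fully determined, up to the arrangement of
#' its invariant columns, by three printed facts: the 13 polymorphic
#' columns with their per-species states, the per-species base totals, and
#' the per-species sample sizes (1 *A. stigmaticum*, 3 *A. brunneum*,
#' 7 *A. chloroticum*). `study_fixture_spec()` bundles those facts;
#' [build_study_alignment()] solves for the invariant-column base multiset
#' (verifying it is consistent across species and non-negative) and emits
#' the alignment with the invariant columns shuffled by `seed`. All
#' in-scope statistics depend only on column multisets, so any seed yields
#' identical distances, trees and delimitations.
#'
#' @param seed integer seed controlling the arrangement of invariant
#'   columns.
#' @return a list of class `study_fixture_spec` with elements `n_columns`,
#'   `polymorphic` (tibble: `column`, `stigmaticum`, `brunneum`,
#'   `chloroticum`), `species_counts`, `composition` (per-species base
#'   totals), `accessions`, `seed`.
#' @export
study_fixture_spec <- function(seed = 1L) {
  polymorphic <- tibble(
    column       = c(27L, 28L, 42L, 67L, 68L, 102L, 104L, 123L, 163L, 164L, 177L, 214L, 225L),
    stigmaticum  = c("C", "A", "A", "T", "G", "C", "G", "C", "C", "C", "A", "G", "-"),
    brunneum     = c("C", "G", "A", "C", "A", "T", "G", "T", "T", "T", "G", "A", "-"),
    chloroticum  = c("T", "G", "G", "T", "G", "T", "A", "T", "T", "T", "G", "A", "T")
  )
  spec <- structure(list(
    n_columns = 234L,
    polymorphic = polymorphic,
    species_counts = c(stigmaticum = 1L, brunneum = 3L, chloroticum = 7L),
    composition = list(
      stigmaticum = c(A = 81L, C = 33L, G = 39L, T = 80L),
      brunneum    = c(A = 81L, C = 30L, G = 39L, T = 83L),
      chloroticum = c(A = 80L, C = 28L, G = 40L, T = 86L)
    ),
    accessions = list(
      stigmaticum = "KU168372",
      brunneum    = c("KU168373", "KU168374", "KU168375"),
      chloroticum = c("KU168376", "KU168377", "KU168378", "KU168379",
                      "KU168380", "KU168381", "KU168382")
    ),
    seed = as.integer(seed)
  ), class = "study_fixture_spec")
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  p <- spec$polymorphic
  if (nrow(p) != 13L) abort("exactly 13 polymorphic columns are required")
  if (anyDuplicated(p$column)) abort("polymorphic columns must be distinct")
  if (any(p$column < 1L | p$column > spec$n_columns)) {
    abort("polymorphic columns must lie within the alignment")
  }
  invisible(spec)
}

# Solve for the base multiset of the invariant columns: per species it is
# the printed totals minus that species' non-gap states at polymorphic
# columns. All species must agree on the same non-negative solution.
solve_background <- function(spec) {
  sols <- lapply(names(spec$species_counts), function(sp) {
    states <- spec$polymorphic[[sp]]
    states <- states[states != "-"]
    poly <- vapply(c("A", "C", "G", "T"), function(b) sum(states == b), integer(1))
    bg <- spec$composition[[sp]] - poly
    if (any(bg < 0)) {
      abort(paste0("inconsistent fixture spec: negative invariant-column ",
                   "count for species '", sp, "'"))
    }
    bg
  })
  names(sols) <- names(spec$species_counts)
  ref <- sols[[1]]
  for (sp in names(sols)[-1]) {
    if (!identical(unname(sols[[sp]]), unname(ref))) {
      abort(paste0("inconsistent fixture spec: invariant-column composition ",
                   "implied by species '", sp, "' disagrees with '",
                   names(sols)[1], "'"))
    }
  }
  n_invariant <- spec$n_columns - nrow(spec$polymorphic)
  if (sum(ref) != n_invariant) {
    abort(paste0("inconsistent fixture spec: invariant-column counts sum to ",
                 sum(ref), ", expected ", n_invariant))
  }
  ref
}

#' Build the study alignment from its printed tables
#'
#' @param spec a [study_fixture_spec()].
#' @return an [as_mt_aln()] alignment of 11 sequences x 234 columns with
#'   IDs `species_accession` (e.g. `stigmaticum_KU168372`). Within each
#'   species all sequences are identical; invariant columns are identical
#'   across species; the gap at column 225 is carried by *A. stigmaticum*
#'   and *A. brunneum*, so ungapped lengths are 233/233/234.
#' @examples
#' aln <- build_study_alignment(study_fixture_spec(seed = 42))
#' variable_positions(aln)
#' @export
build_study_alignment <- function(spec = study_fixture_spec()) {
  validate_fixture_spec(spec)
  bg <- solve_background(spec)
  background <- rep(c("A", "C", "G", "T"), times = bg)
  background <- with_seed(spec$seed, sample(background))
  invariant_cols <- setdiff(seq_len(spec$n_columns), spec$polymorphic$column)

  seqs <- character()
  for (sp in names(spec$species_counts)) {
    s <- character(spec$n_columns)
    s[invariant_cols] <- background
    s[spec$polymorphic$column] <- spec$polymorphic[[sp]]
    ids <- paste(sp, spec$accessions[[sp]], sep = "_")
    if (length(ids) != spec$species_counts[[sp]]) {
      abort(paste0("accession count for '", sp, "' does not match its N"))
    }
    for (id in ids) seqs[id] <- paste(s, collapse = "")
  }
  strings_to_aln(seqs)
}

#' Species groups for the study alignment
#'
#' @param spec a [study_fixture_spec()].
#' @return tibble (`id`, `group`) assigning each fixture sequence to its
#'   species.
#' @export
study_groups <- function(spec = study_fixture_spec()) {
  purrr::map_dfr(names(spec$species_counts), function(sp) {
    tibble(id = paste(sp, spec$accessions[[sp]], sep = "_"), group = sp)
  })
}

#' Specification of a clock-like three-taxon simulation
#'
#' Sequences evolve on the rooted clock tree `((A,B):inner, C):outer` under
#' a Kimura two-parameter process calibrated so that the expected K2P
#' distance between tips split `t` Myr ago is `rate_2mu * t`. Defaults are
#' the study's conditions: splits at 6.57 and 3.75 Myr, a divergence rate
#' of 0.6% per Myr, a 234-column fragment, and a transition-biased process
#' (every observed difference in the study data is a transition).
#'
#' @param inner,outer node ages in Myr; `outer >= inner > 0` (zero allowed
#'   for degenerate tests).
#' @param rate_2mu divergence rate in substitutions/site/Myr.
#' @param length number of alignment columns.
#' @param ts_tv_ratio expected transition/transversion rate ratio.
#' @param seqs_per_tip named integer vector: identical copies per tip.
#' @param tip_names names for the three tips (A and B are the inner pair).
#' @param seed integer seed.
#' @return list of class `clock_sim_spec`.
#' @export
clock_sim_spec <- function(inner = 3.75, outer = 6.57, rate_2mu = 0.006,
                           length = 234L, ts_tv_ratio = 10,
                           seqs_per_tip = c(1L, 1L, 1L),
                           tip_names = c("A", "B", "C"), seed = 1L) {
  if (!(outer >= inner && inner >= 0)) abort("need outer >= inner >= 0")
  if (rate_2mu <= 0) abort("rate_2mu must be positive")
  if (length < 1) abort("length must be positive")
  if (ts_tv_ratio <= 0) abort("ts_tv_ratio must be positive")
  if (length(seqs_per_tip) != 3L || any(seqs_per_tip < 1)) {
    abort("seqs_per_tip must be three positive counts")
  }
  structure(list(inner = inner, outer = outer, rate_2mu = rate_2mu,
                 length = as.integer(length), ts_tv_ratio = ts_tv_ratio,
                 seqs_per_tip = as.integer(seqs_per_tip),
                 tip_names = tip_names, seed = as.integer(seed)),
            class = "clock_sim_spec")
}

# K2P substitution probabilities after time t for per-lineage rates
# alpha (transition) and beta (each transversion): returns c(same, ts, tv)
# where tv is the probability of EACH of the two transversion targets.
k2p_branch_probs <- function(alpha, beta, t) {
  e4b <- exp(-4 * beta * t)
  e2ab <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e4b + 0.5 * e2ab,
    ts   = 0.25 + 0.25 * e4b - 0.5 * e2ab,
    tv   = 0.25 - 0.25 * e4b)
}

BASES <- c("A", "C", "G", "T")
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

evolve_branch <- function(seq, alpha, beta, t) {
  if (t <= 0) return(seq)
  p <- k2p_branch_probs(alpha, beta, t)
  u <- runif(length(seq))
  out <- seq
  ts_idx <- u >= p[["same"]] & u < p[["same"]] + p[["ts"]]
  tv1_idx <- u >= p[["same"]] + p[["ts"]] & u < p[["same"]] + p[["ts"]] + p[["tv"]]
  tv2_idx <- u >= p[["same"]] + p[["ts"]] + p[["tv"]]
  out[ts_idx] <- TS_PARTNER[seq[ts_idx]]
  out[tv1_idx] <- vapply(seq[tv1_idx], function(b) TV_PARTNERS[[b]][1], character(1))
  out[tv2_idx] <- vapply(seq[tv2_idx], function(b) TV_PARTNERS[[b]][2], character(1))
  out
}

#' Simulate a clock-like alignment
#'
#' @param spec a [clock_sim_spec()].
#' @return an [as_mt_aln()] alignment; tips carrying more than one sequence
#'   get suffixed IDs (`A_1`, `A_2`, ...). Byte-identical for equal specs.
#' @examples
#' aln <- simulate_clock_alignment(clock_sim_spec(length = 100, seed = 7))
#' @export
simulate_clock_alignment <- function(spec = clock_sim_spec()) {
  stopifnot(inherits(spec, "clock_sim_spec"))
  mu <- spec$rate_2mu / 2          # per-lineage substitutions/site/Myr
  R <- spec$ts_tv_ratio
  alpha <- mu * R / (R + 1)
  beta <- mu / (2 * (R + 1))
  with_seed(spec$seed, {
    root <- sample(BASES, spec$length, replace = TRUE)
    anc_ab <- evolve_branch(root, alpha, beta, spec$outer - spec$inner)
    tipseqs <- list(
      evolve_branch(anc_ab, alpha, beta, spec$inner),
      evolve_branch(anc_ab, alpha, beta, spec$inner),
      evolve_branch(root, alpha, beta, spec$outer)
    )
    seqs <- character()
    for (k in 1:3) {
      n <- spec$seqs_per_tip[[k]]
      ids <- if (n == 1L) spec$tip_names[[k]] else
        paste(spec$tip_names[[k]], seq_len(n), sep = "_")
      for (id in ids) seqs[id] <- paste(tipseqs[[k]], collapse = "")
    }
    strings_to_aln(seqs)
  })
}
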
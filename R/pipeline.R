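#' Run the full analysis pipeline
#'
#' Orchestrates alignment profiling, distance estimation, NJ tree with
#' bootstrap support, relative-rate clock checks, barcode-gap and K/theta
#' species delimitation, and net-divergence dating from a single config,
#' writing one TSV per analysis table plus the tree and a run log. Output
#' is byte-identical for identical config and seed; any stage failure
#' aborts with the stage name and removes partial outputs.
#'
#' @param config named list or path to a YAML file. Recognised keys
#'   (defaults in parentheses mirror the study's settings):
#'   `alignment` (path; omit to use the built-in study fixture), `groups`
#'   (path; required with `alignment`), `structure` (optional dot-bracket
#'   path), `guide_tree` (optional rooted Newick over group names;
#'   otherwise derived by average-linkage clustering of group distances),
#'   `model` ("k2p"), `deletion` ("pairwise"), `abgd_pmin` (0.001),
#'   `abgd_pmax` (0.1), `abgd_steps` (10), `abgd_X` (1.5), `theta_policy`
#'   ("auto": within-clade diversity where positive, else a Watterson-style
#'   upper bound), `theta` (named list "A|B" = value, for "supplied"),
#'   `rate_2mu` (0.006), `replicates` (1000), `seed` (required), `outdir`
#'   (required).
#' @return invisibly, a list with the result objects and the written file
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    model = "k2p", deletion = "pairwise",
    abgd_pmin = 0.001, abgd_pmax = 0.1, abgd_steps = 10L, abgd_X = 1.5,
    theta_policy = "auto", theta = NULL,
    rate_2mu = 0.006, replicates = 1000L,
    structure = NULL, guide_tree = NULL, alignment = NULL, groups = NULL
  ), config)
  if (is.null(cfg$outdir)) abort("config must set 'outdir'")
  if (is.null(cfg$seed)) abort("config must set 'seed' (stochastic stages are enabled)")

  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(cfg$outdir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    # --- input stage -----------------------------------------------------
    stage <- "input"
    if (is.null(cfg$alignment)) {
      aln <- build_study_alignment(study_fixture_spec(seed = cfg$seed))
      groups <- study_groups()
    } else {
      aln <- read_fasta(cfg$alignment)
      if (is.null(cfg$groups)) abort("config must set 'groups' alongside 'alignment'")
      groups <- read_groups(cfg$groups)
    }

    # --- profile stage ---------------------------------------------------
    stage <- "profile"
    vp <- variable_positions(aln)
    m <- unclass(aln)
    profile_tab <- tibble(column = vp)
    for (id in seq_ids(aln)) profile_tab[[id]] <- m[id, vp]
    emit(profile_tab, "variable_sites.tsv")
    emit(composition(aln), "composition.tsv")
    hap <- collapse_haplotypes(aln, groups)
    emit(dplyr::mutate(hap, ids = vapply(.data$ids, paste, character(1),
                                         collapse = ",")), "haplotypes.tsv")

    # --- distance stage --------------------------------------------------
    stage <- "distances"
    dm <- distance_matrix(aln, cfg$model, cfg$deletion)
    path_dm <- file.path(cfg$outdir, "distances.tsv")
    write_distance_matrix(dm, path_dm)
    written <- c(written, path_dm)
    gsum <- group_summary(dm, groups)
    emit(tidy(gsum), "group_distances.tsv")

    # --- tree stage ------------------------------------------------------
    stage <- "tree"
    tree <- bootstrap_support(aln, cfg$model, cfg$replicates, seed = cfg$seed,
                              deletion = cfg$deletion)
    path_tree <- file.path(cfg$outdir, "tree.nwk")
    to_newick(tree, path_tree)
    written <- c(written, path_tree)

    # --- structure stage (optional) --------------------------------------
    struct_tab <- NULL
    if (!is.null(cfg$structure)) {
      stage <- "structure"
      db <- read_dot_bracket(cfg$structure, n_sites(aln))
      struct_tab <- classify_variable_sites(aln, db)
      emit(struct_tab, "structure_classes.tsv")
    }

    # --- delimitation stage ----------------------------------------------
    stage <- "delimitation"
    scan <- abgd_scan(dm, abgd_config(cfg$abgd_pmin, cfg$abgd_pmax,
                                      cfg$abgd_steps, cfg$abgd_X))
    emit(tidy(scan), "partitions.tsv")
    emit(scan$distances, "distance_histogram.tsv")

    grp_ids <- split(groups$id, groups$group)
    pair_names <- if (length(grp_ids) >= 2L) {
      combn(sort(names(grp_ids)), 2L, simplify = FALSE)
    } else list()
    kt <- purrr::map(pair_names, function(p) {
      key <- paste(p, collapse = "|")
      supplied <- if (!is.null(cfg$theta)) cfg$theta[[key]] else NULL
      policy <- if (!is.null(supplied)) "supplied" else cfg$theta_policy
      th <- ktheta_test(dm, grp_ids[[p[1]]], grp_ids[[p[2]]],
                        theta_policy = policy, theta = supplied,
                        L = n_sites(aln), label = paste(p, collapse = "-"))
      tidy(th)
    })
    if (length(kt) > 0) emit(dplyr::bind_rows(kt), "ktheta.tsv")

    # --- clock stage ------------------------------------------------------
    stage <- "clock"
    guide <- if (!is.null(cfg$guide_tree)) {
      if (file.exists(cfg$guide_tree)) from_newick(path = cfg$guide_tree)
      else from_newick(cfg$guide_tree)
    } else {
      group_guide_tree(dm, groups)
    }
    rrt_tab <- NULL
    if (length(grp_ids) >= 3L) {
      splits <- guide_tree_splits(guide)
      inner <- splits[[which.max(vapply(splits, function(s)
        -length(c(s$x, s$y)), numeric(1)))]]
      # relative rate test on one representative per group of the innermost
      # split, using a representative of an outside group as outgroup
      inner_groups <- c(inner$x[1], inner$y[1])
      out_group <- setdiff(names(grp_ids), c(inner$x, inner$y))[1]
      if (!is.na(out_group)) {
        r <- tajima_rrt(aln, grp_ids[[inner_groups[1]]][1],
                        grp_ids[[inner_groups[2]]][1], grp_ids[[out_group]][1])
        rrt_tab <- tidy(r)
        emit(rrt_tab, "rrt.tsv")
      }
    }

    # --- dating stage ----------------------------------------------------
    stage <- "dating"
    dating <- date_all_splits(aln, groups, guide, rate_2mu = cfg$rate_2mu,
                              replicates = cfg$replicates, seed = cfg$seed)
    emit(dating, "dating.tsv")

    # --- log -------------------------------------------------------------
    stage <- "log"
    log_path <- file.path(cfg$outdir, "run_log.txt")
    writeLines(c(
      paste0("aylacostoma pipeline, package version ",
             as.character(utils::packageVersion("aylacostoma"))),
      paste0("seed: ", cfg$seed),
      # hash over the analysis settings only, so the same analysis in a
      # different output directory logs the same provenance
      paste0("config hash: ", rlang::hash(cfg[setdiff(names(cfg), "outdir")])),
      paste0("model: ", cfg$model, " / deletion: ", cfg$deletion),
      paste0("rate_2mu: ", cfg$rate_2mu, " subs/site/Myr"),
      paste0("bootstrap replicates: ", cfg$replicates),
      paste0("theta policy: ", cfg$theta_policy),
      paste0("outputs: ", paste(basename(written), collapse = ", "))
    ), log_path)
    written <- c(written, log_path)

    list(alignment = aln, groups = groups, dm = dm, tree = tree,
         group_summary = gsum, abgd = scan, ktheta = kt,
         structure = struct_tab, rrt = rrt_tab, dating = dating,
         files = written)
  }, error = function(e) {
    unlink(written)
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  invisible(result)
}

# rooted guide tree over group names by average-linkage clustering of the
# between-group mean distances (deterministic; no branch-length semantics
# beyond nesting order)
group_guide_tree <- function(dm, groups) {
  g <- group_lookup(groups, rownames(dm))
  grp_ids <- split(names(g), unname(g))
  grps <- sort(names(grp_ids))
  if (length(grps) < 2L) abort("guide tree needs at least two groups")
  n <- length(grps)
  gd <- matrix(0, n, n, dimnames = list(grps, grps))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      gd[i, j] <- gd[j, i] <- mean_cross(dm, grp_ids[[grps[i]]], grp_ids[[grps[j]]])
    }
  }
  hc <- stats::hclust(stats::as.dist(gd), method = "average")
  ape::as.phylo(hc)
}
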
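test_that("p and K2P distances reproduce the printed study values", {
  expect_equal(round(p_distance(site_diff(9, 0, 0, 233)), 6), 0.038627)
  expect_equal(round(p_distance(site_diff(10, 0, 1, 233)), 6), 0.042918)
  expect_equal(round(p_distance(site_diff(5, 0, 1, 233)), 6), 0.021459)
  expect_equal(round(k2p_distance(site_diff(9, 0, 0, 233)), 6), 0.040200)
  expect_equal(round(k2p_distance(site_diff(10, 0, 1, 233)), 6), 0.044873)
  expect_equal(round(k2p_distance(site_diff(5, 0, 1, 233)), 6), 0.021933)
  expect_equal(p_distance(site_diff(0, 0, 0, 100)), 0)
  expect_equal(k2p_distance(site_diff(0, 0, 0, 100)), 0)
})

test_that("K2P agrees with ape's K80 implementation", {
  # constructed pair: 3 transitions + 2 transversions over 100 sites
  x <- strrep("A", 100)
  y <- paste0(strrep("A", 95), "GGGCC")
  aln <- as_mt_aln(c(x = x, y = y))
  ours <- k2p_distance(pairwise_site_diffs(aln, "x", "y"))
  bin <- ape::as.DNAbin(list(x = strsplit(tolower(x), "")[[1]],
                             y = strsplit(tolower(y), "")[[1]]))
  ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
  expect_equal(ours, ref, tolerance = 1e-12)

  # random related alignments (one ancestor, scattered substitutions),
  # pairwise deletion, whole matrix
  set.seed(77)
  for (rep in 1:3) {
    anc <- sample(c("a", "c", "g", "t"), 400, replace = TRUE)
    mat <- do.call(rbind, lapply(1:5, function(i) {
      s <- anc
      idx <- sample(400, 30)
      s[idx] <- sample(c("a", "c", "g", "t"), 30, replace = TRUE)
      s
    }))
    rownames(mat) <- paste0("s", 1:5)
    bin <- ape::as.DNAbin(mat)
    ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
    ours <- distance_matrix(as_mt_aln(toupper(mat)), "k2p", "pairwise")
    expect_equal(unname(unclass(ours)), unname(ref[rownames(ours), colnames(ours)]),
                 tolerance = 1e-10, ignore_attr = TRUE)
    refp <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
    oursp <- distance_matrix(as_mt_aln(toupper(mat)), "p", "pairwise")
    expect_equal(unname(unclass(oursp)), unname(refp[rownames(oursp), colnames(oursp)]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("K2P dominates p, equality only at zero, and Q=0 has closed form", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(50:400, 1)
    ts <- sample(0:10, 1)
    tv <- sample(0:10, 1)
    if (2 * ts + tv >= n || 2 * tv >= n) next
    d_p <- p_distance(site_diff(ts, tv, 0, n))
    d_k <- k2p_distance(site_diff(ts, tv, 0, n))
    if (ts + tv == 0) expect_identical(d_k, d_p) else expect_gt(d_k, d_p)
    if (tv == 0) {
      expect_equal(d_k, -0.5 * log(1 - 2 * ts / n), tolerance = 1e-14)
    }
  }
})

test_that("saturation is flagged as a non-finite distance", {
  expect_warning(d <- k2p_distance(site_diff(60, 0, 0, 100)), "saturated")
  expect_true(is.nan(d))
  expect_warning(d2 <- k2p_distance(site_diff(0, 50, 0, 100)), "saturated")
  expect_true(is.nan(d2))
})

test_that("distance matrices are symmetric, zero-diagonal and deletion-stable", {
  dm <- fixture_dm
  expect_true(isSymmetric(unclass(dm)))
  expect_true(all(diag(unclass(dm)) == 0))
  expect_equal(sort(unique(round(as.vector(unclass(dm)), 6))),
               c(0, 0.021933, 0.040200, 0.044873))
  # only gap column 225 is removed under complete deletion: identical values
  dm_c <- distance_matrix(fixture_aln, "k2p", "complete")
  expect_equal(unclass(dm_c)[rownames(dm), colnames(dm)], unclass(dm),
               ignore_attr = TRUE)
})

test_that("distances are invariant under column permutation and row reorder", {
  set.seed(4)
  perm <- sample(n_sites(fixture_aln))
  aln_p <- as_mt_aln(unclass(fixture_aln)[, perm])
  expect_equal(unclass(distance_matrix(aln_p, "k2p")), unclass(fixture_dm),
               ignore_attr = TRUE)
  rows <- sample(seq_ids(fixture_aln))
  aln_r <- as_mt_aln(unclass(fixture_aln)[rows, ])
  dm_r <- distance_matrix(aln_r, "k2p")
  expect_equal(unclass(dm_r)[rownames(fixture_dm), colnames(fixture_dm)],
               unclass(fixture_dm), ignore_attr = TRUE)
})

test_that("group summary reproduces the within/between/net structure", {
  gs <- group_summary(fixture_dm, fixture_groups)
  within <- setNames(gs$within$d_within, gs$within$group)
  expect_equal(within[["brunneum"]], 0)
  expect_equal(within[["chloroticum"]], 0)
  expect_true(is.na(within[["stigmaticum"]]))  # singleton: undefined, not 0

  btw <- gs$between
  row_chbr <- btw[btw$group_x == "brunneum" & btw$group_y == "chloroticum", ]
  expect_equal(round(row_chbr$d_between, 6), 0.021933)
  expect_equal(row_chbr$Da, row_chbr$d_between)

  # stigmaticum vs the union of the other two: printed-table brute force
  ids_y <- c(id_br, id_ch)
  grp <- setNames(c("X", rep("Y", 10)), c(id_st, ids_y))
  gs2 <- group_summary(fixture_dm, grp)
  expect_equal(gs2$between$d_between, 0.0434711, tolerance = 1e-5)
  expect_equal(setNames(gs2$within$d_within, gs2$within$group)[["Y"]],
               0.0102355, tolerance = 1e-5)
  expect_equal(gs2$between$Da, 0.0383533, tolerance = 1e-5)

  # one group containing everything: between is empty
  gs3 <- group_summary(fixture_dm, setNames(rep("all", 11), rownames(fixture_dm)))
  expect_equal(nrow(gs3$between), 0L)
})

test_that("Da identity holds and Da is non-negative for clean clusters", {
  gs <- group_summary(fixture_dm, fixture_groups)
  w <- setNames(gs$within$d_within, gs$within$group)
  for (k in seq_len(nrow(gs$between))) {
    r <- gs$between[k, ]
    wx <- w[[r$group_x]]; wy <- w[[r$group_y]]
    if (!is.na(wx) && !is.na(wy)) {
      expect_equal(r$Da, r$d_between - (wx + wy) / 2)
    }
    expect_gte(r$Da, 0)
  }
})

test_that("bootstrap SE behaves like sampling theory says it should", {
  # constant statistic: SE exactly 0
  b0 <- bootstrap_se(fixture_aln, function(a) 42, replicates = 50, seed = 1)
  expect_equal(b0$se, 0)

  stat <- function(a) k2p_distance(pairwise_site_diffs(a, id_st, id_br[1]))
  b <- bootstrap_se(fixture_aln, stat, replicates = 1000, seed = 7)
  # delta-method oracle for 9 substitutions over 233 sites (Q = 0):
  # SE = sqrt(P(1-P)/n) / (1-2P)
  P <- 9 / 233
  se_delta <- sqrt(P * (1 - P) / 233) / (1 - 2 * P)
  expect_equal(b$se, se_delta, tolerance = 0.15)

  # doubling the columns shrinks the SE by ~ 1/sqrt(2)
  doubled <- as_mt_aln(cbind(unclass(fixture_aln), unclass(fixture_aln)))
  b2 <- bootstrap_se(doubled, stat, replicates = 1000, seed = 7)
  expect_equal(b2$se / b$se, 1 / sqrt(2), tolerance = 0.12)

  # same seed, same replicates: reproducible
  b_again <- bootstrap_se(fixture_aln, stat, replicates = 200, seed = 3)
  b_again2 <- bootstrap_se(fixture_aln, stat, replicates = 200, seed = 3)
  expect_identical(b_again$replicates, b_again2$replicates)
  expect_error(bootstrap_se(fixture_aln, stat, replicates = 10), "seed")
})

test_that("distance matrix writers round-trip through their formats", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(fixture_dm, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE)
  expect_equal(as.matrix(back), round(unclass(fixture_dm), 6),
               ignore_attr = TRUE)
  phy <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(fixture_dm, phy, format = "phylip")
  first <- readLines(phy, n = 1)
  expect_match(first, "^\\s*11$")
})
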
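test_that("the prior ladder is the inclusive geometric series", {
  ladder <- abgd_prior_ladder(abgd_config())
  expect_equal(round(ladder, 6),
               c(0.001, 0.001668, 0.002783, 0.004642, 0.007743,
                 0.012915, 0.021544, 0.035938, 0.059948, 0.1))
  expect_equal(abgd_prior_ladder(abgd_config(steps = 2)), c(0.001, 0.1))
  expect_error(abgd_config(p_min = 0.01, p_max = 0.01), "p_min < p_max")
  expect_error(abgd_config(steps = 1), "steps")
})

test_that("barcode-gap partitioning matches the study's group counts by prior", {
  p1 <- abgd_partition(fixture_dm, prior = 0.001)
  expect_length(p1$groups, 3L)
  sets <- lapply(p1$groups, sort)
  expect_true(any(vapply(sets, identical, logical(1), sort(id_ch))))
  expect_true(any(vapply(sets, identical, logical(1), sort(id_br))))
  expect_true(any(vapply(sets, identical, logical(1), sort(id_st))))

  # at prior 0.035938 chloroticum and brunneum merge (the 0.0402 -> 0.0449
  # step has relative width ~0.12 < 1.5, so the threshold falls back to
  # the prior, which exceeds their 0.0219 distance)
  p8 <- abgd_partition(fixture_dm, prior = 0.035938)
  expect_length(p8$groups, 2L)
  merged <- p8$groups[[which.max(lengths(p8$groups))]]
  expect_setequal(merged, c(id_ch, id_br))

  # identical sequences: one group at every prior
  z <- as_mt_aln(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  dmz <- distance_matrix(z, "p")
  for (p in abgd_prior_ladder(abgd_config())) {
    expect_length(abgd_partition(dmz, p)$groups, 1L)
  }
})

test_that("the ladder scan reproduces the 7-partition stability and trimodal histogram", {
  scan <- abgd_scan(fixture_dm, abgd_config())
  # 3 groups at exactly the seven priors up to 0.021544 (the printed value
  # of the seventh ladder entry), never beyond
  expect_equal(which(scan$partitions$n_groups == 3L), 1:7)
  expect_equal(round(scan$partitions$prior[7], 6), 0.021544)
  expect_equal(glance(scan)$modal_n_groups, 3L)

  d <- scan$distances$distance
  expect_length(d, 55L)
  expect_equal(sum(d < 0.01), 24L)                  # intraspecific mode
  expect_equal(sum(d > 0.015 & d < 0.03), 21L)      # chloroticum-brunneum mode
  expect_equal(sum(d > 0.035 & d < 0.05), 10L)      # stigmaticum mode
})

test_that("single-cluster simulated data never splits across the ladder", {
  aln <- simulate_clock_alignment(clock_sim_spec(
    inner = 0.05, outer = 0.05, rate_2mu = 0.006, length = 234,
    seqs_per_tip = c(4L, 4L, 4L), seed = 21))
  scan <- abgd_scan(distance_matrix(aln, "k2p"), abgd_config())
  expect_true(all(scan$partitions$n_groups == 1L))
})

test_that("group counts are monotone non-increasing in the prior", {
  set.seed(404)
  for (rep in 1:50) {
    n <- sample(6:12, 1)
    # random two-level matrices: within-cluster small, between large-ish
    k <- sample(2:4, 1)
    assign_to <- sample(k, n, replace = TRUE)
    d <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
    centers <- runif(k, 0.02, 0.2)
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        base <- if (assign_to[i] == assign_to[j]) runif(1, 0, 0.01) else
          abs(centers[assign_to[i]] - centers[assign_to[j]]) + runif(1, 0, 0.02)
        d[i, j] <- d[j, i] <- base
      }
    }
    counts <- abgd_scan(d, abgd_config())$partitions$n_groups
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("partitioning is invariant to id order and common rescaling", {
  set.seed(9)
  d <- unclass(fixture_dm)
  perm <- sample(rownames(d))
  p_ref <- abgd_partition(fixture_dm, 0.005)
  p_perm <- abgd_partition(d[perm, perm], 0.005)
  expect_setequal(lapply(p_ref$groups, sort), lapply(p_perm$groups, sort))
  p_scaled <- abgd_partition(d * 3, 0.005 * 3)
  expect_setequal(lapply(p_ref$groups, sort), lapply(p_scaled$groups, sort))
})

test_that("K/theta reproduces the printed ratios and its invariances", {
  kt1 <- ktheta_test(fixture_dm, id_ch, id_br, "supplied", theta = 0.0043165)
  expect_equal(round(kt1$ratio, 2), 5.08)
  expect_true(kt1$decision)
  expect_equal(kt1$K, 0.0219333, tolerance = 1e-5)

  kt2 <- ktheta_test(fixture_dm, id_br, id_st, "supplied", theta = 0.0043165)
  expect_equal(round(kt2$ratio, 2), 9.31)
  expect_true(kt2$decision)

  kt3 <- ktheta_test(fixture_dm, id_ch, id_st, "supplied", theta = 0.0014333)
  expect_equal(round(kt3$ratio, 2), 31.31)
  expect_true(kt3$decision)
  expect_equal(c(kt3$n1, kt3$n2), c(7L, 1L))

  # theta = K: ratio 1, not distinct
  kt_eq <- ktheta_test(fixture_dm, id_ch, id_br, "supplied", theta = kt1$K)
  expect_equal(kt_eq$ratio, 1)
  expect_false(kt_eq$decision)

  # ratio invariant under multiplicative rescaling with max_within policy
  aln2 <- simulate_clock_alignment(clock_sim_spec(
    inner = 2, outer = 8, rate_2mu = 0.006, length = 1000,
    seqs_per_tip = c(3L, 3L, 3L), seed = 17))
  # add within-clade variation by pooling tips A and B as one clade
  dm2 <- distance_matrix(aln2, "k2p")
  cl_a <- c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3")
  cl_b <- c("C_1", "C_2", "C_3")
  r1 <- ktheta_test(dm2, cl_a, cl_b, "max_within")
  r2 <- ktheta_test(unclass(dm2) * 2.5, cl_a, cl_b, "max_within")
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)

  # watterson upper bound: 3 / (a_n * L), larger clade's n
  kw <- ktheta_test(fixture_dm, id_ch, id_st, "watterson_upper", L = 234)
  a_7 <- sum(1 / 1:6)
  expect_equal(kw$theta, 3 / (a_7 * 234))
  expect_error(ktheta_test(fixture_dm, id_st, id_br[1], "watterson_upper", L = 234),
               "theta unresolved")
  expect_error(ktheta_test(fixture_dm, id_st, id_br[1], "max_within"),
               "theta unresolved")
})

test_that("two clades built with K/theta >= 4 are almost always called distinct", {
  calls <- vapply(1:40, function(k) {
    aln <- simulate_clock_alignment(clock_sim_spec(
      inner = 1, outer = 10, rate_2mu = 0.006, length = 2000,
      seqs_per_tip = c(3L, 3L, 2L), seed = 3000 + k))
    dm <- distance_matrix(aln, "k2p")
    # clade 1 = A tips + B tips (theta ~ mean within incl. 0.006 A-B pairs);
    # clade 2 = C tips; K ~ 0.06 => K/theta ~ 17 by construction
    kt <- ktheta_test(dm, c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3"),
                      c("C_1", "C_2"), "max_within")
    kt$decision
  }, logical(1))
  expect_gte(mean(calls), 0.95)
})
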
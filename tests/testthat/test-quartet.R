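test_that("degenerate quartets have the expected pattern probabilities", {
  # all branch lengths zero: tips identical, no informative pattern
  tr0 <- quartet_tree(0, 0, 0, 0, 0, lam = 1)
  pp0 <- pattern_probabilities(tr0)
  expect_equal(c(pp0$y, pp0$x1, pp0$x2), c(0, 0, 0))
  expect_equal(pp0$no_change, 1)
  expect_equal(pp0$pi_true, 0)

  # star tree: zero internode, equal subtending branches
  star <- quartet_tree(0, 0.2, 0.2, 0.2, 0.2, lam = 1)
  pps <- pattern_probabilities(star)
  expect_equal(pps$y, pps$x1, tolerance = 1e-12)
  expect_equal(pps$y, pps$x2, tolerance = 1e-12)
  expect_equal(pps$signal, 0)
  expect_equal(pps$pi_true, 0)

  # saturation: all expected lengths large, tips i.i.d. uniform;
  # each AABB pattern then has probability 4*3*(1/4)^4 = 3/64
  sat <- quartet_tree(50, 50, 50, 50, 50, lam = 1)
  ppl <- pattern_probabilities(sat)
  expect_equal(c(ppl$y, ppl$x1, ppl$x2), rep(3 / 64, 3), tolerance = 1e-6)
})

test_that("contraction equals the literal six-index summation", {
  tr <- quartet_tree(0.1, 0.25, 0.25, 0.25, 0.25, lam = 1)
  pp <- pattern_probabilities(tr)
  or <- enumerate_oracle(tr)
  expect_equal(pp$y, or$y, tolerance = 1e-12)
  expect_equal(pp$x1, or$x1, tolerance = 1e-12)
  expect_equal(pp$x2, or$x2, tolerance = 1e-12)
  expect_equal(pp$signal, or$signal, tolerance = 1e-12)
  expect_equal(or$total, 1, tolerance = 1e-10)

  set.seed(23)
  for (rep in 1:20) {
    tr <- random_quartet()
    pp <- pattern_probabilities(tr)
    or <- enumerate_oracle(tr)
    expect_equal(pp$y, or$y, tolerance = 1e-12)
    expect_equal(pp$x1, or$x1, tolerance = 1e-12)
    expect_equal(pp$x2, or$x2, tolerance = 1e-12)
    expect_equal(or$total, 1, tolerance = 1e-10)
  }
})

test_that("signal, no-change and true-synapomorphy follow their closed forms", {
  tr <- quartet_tree(0.1, 0.25, 0.25, 0.25, 0.25, lam = 1)
  expect_equal(signal_probability(tr), (3 / 4) * (1 - exp(-4 * 0.1 / 3)),
               tolerance = 1e-12)
  expect_equal(no_change_probability(tr), exp(-1), tolerance = 1e-12)
  expect_equal(true_synapomorphy(tr),
               signal_probability(tr) * no_change_probability(tr))

  # zero internode gives zero signal; saturated internode approaches 3/4
  expect_equal(signal_probability(quartet_tree(0, 1, 1, 1, 1, lam = 1)), 0)
  expect_equal(signal_probability(quartet_tree(100, 1, 1, 1, 1, lam = 1)),
               0.75, tolerance = 1e-10)

  # zero subtending branches: Pi reduces to the signal probability alone
  bare <- quartet_tree(0.1, 0, 0, 0, 0, lam = 1)
  expect_equal(true_synapomorphy(bare), signal_probability(bare))
  expect_equal(true_synapomorphy(bare), 0.09362, tolerance = 1e-4)

  # no-change is strictly decreasing in any subtending expected length
  expect_lt(no_change_probability(quartet_tree(0.1, 0.3, 0.25, 0.25, 0.25, lam = 1)),
            no_change_probability(tr))
})

test_that("probability structure holds on random quartets", {
  set.seed(31)
  for (rep in 1:40) {
    tr <- random_quartet()
    pp <- pattern_probabilities(tr)
    v <- c(pp$y, pp$x1, pp$x2, pp$signal, pp$no_change, pp$pi_true)
    expect_true(all(v >= 0 & v <= 1))
    expect_lte(pp$y + pp$x1 + pp$x2, 1 + 1e-12)
    expect_identical(pp$pi_true, pp$signal * pp$no_change)
    expect_lte(pp$pi_true, pp$y + 1e-12)
    expect_gte(pp$apparent, -1e-12)
  }
})

test_that("pattern probabilities respect the quartet label symmetries", {
  set.seed(47)
  for (rep in 1:10) {
    tr <- random_quartet()
    pp <- pattern_probabilities(tr)
    # swapping both within-cherry pairs leaves everything invariant
    pp_sw <- pattern_probabilities(swap_branches(swap_branches(tr, 1, 2), 3, 4))
    expect_equal(pp_sw$y, pp$y, tolerance = 1e-12)
    expect_equal(pp_sw$x1, pp$x1, tolerance = 1e-12)
    expect_equal(pp_sw$x2, pp$x2, tolerance = 1e-12)
    # swapping one cherry only exchanges the two homoplasious patterns
    pp_1 <- pattern_probabilities(swap_branches(tr, 1, 2))
    expect_equal(pp_1$y, pp$y, tolerance = 1e-12)
    expect_equal(pp_1$x1, pp$x2, tolerance = 1e-12)
    expect_equal(pp_1$x2, pp$x1, tolerance = 1e-12)
  }
})

test_that("utility statistics and ratio sentinels behave as defined", {
  star <- quartet_tree(0, 0.2, 0.2, 0.2, 0.2, lam = 1)
  expect_equal(quartet_utility(star)$u_parsimony, 0, tolerance = 1e-15)

  set.seed(59)
  for (rep in 1:20) {
    u <- quartet_utility(random_quartet())
    expect_lte(u$u_conservative, u$u_parsimony + 1e-12)
  }

  # all-zero quartet: 0/0 ratios are NaN
  u0 <- quartet_utility(quartet_tree(0, 0, 0, 0, 0, lam = 1))
  expect_true(is.nan(u0$ratio_y_max))
  # positive signal over zero homoplasy: +Inf sentinel
  uinf <- quartet_utility(quartet_tree(0.1, 0, 0, 0, 0, lam = 1))
  expect_identical(uinf$ratio_y_max, Inf)
  expect_identical(uinf$ratio_pi_max, Inf)
  expect_equal(uinf$ratio_pi_y, 1)
})

test_that("classic zone points have the predicted utility signs", {
  # Felsenstein-zone point of the Huelsenbeck-Hillis tree
  hh <- expand_zone_tree("hh", pa = 0.05, pb = 0.60)
  u_hh <- quartet_utility(hh)
  expect_lt(u_hh$u_parsimony, 0)
  # sign confirmed by the enumeration oracle
  or <- enumerate_oracle(hh)
  expect_lt(or$y - max(or$x1, or$x2), 0)

  # the same p-lengths on the Siddall tree: long branches are sisters
  sid <- expand_zone_tree("siddall", pa = 0.05, pb = 0.60)
  u_sid <- quartet_utility(sid)
  expect_gt(u_sid$u_parsimony, 0)
  or2 <- enumerate_oracle(sid)
  expect_gt(or2$y - max(or2$x1, or2$x2), 0)
})
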
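test_that("model families enforce their defining constraints", {
  jc <- substitution_model("JC")
  expect_equal(unique(jc$R[upper.tri(jc$R)]), 1)
  expect_equal(unname(jc$pi), rep(0.25, 4))

  gtr <- substitution_model("GTR",
    exchangeabilities = c(TC = 9.082, TA = 1.967, TG = 1,
                          CA = 1.078, CG = 0.907, AG = 2.902),
    frequencies = c(0.265, 0.225, 0.286, 0.224))
  expect_identical(gtr$states, c("T", "C", "A", "G"))
  expect_equal(gtr$R["T", "C"], 9.082)
  expect_equal(gtr$R["A", "G"], 2.902)
  expect_equal(gtr$R, t(gtr$R))
  expect_equal(sum(gtr$pi), 1)

  # HKY forces a single transversion class
  expect_error(
    substitution_model("HKY",
      exchangeabilities = c(TC = 4.5, TA = 2, TG = 1, CA = 1, CG = 1, AG = 4.5),
      frequencies = c(0.3, 0.3, 0.2, 0.2)),
    "transversion")
  # frequency validation
  expect_error(substitution_model("GTR", exchangeabilities = rep(1, 6),
                                  frequencies = c(0.5, 0.3, 0.3, 0.1)),
               "sum to 1")
  expect_error(substitution_model("GTR", exchangeabilities = rep(1, 6),
                                  frequencies = c(0.7, 0.3, 0.2, -0.2)),
               "positive")
})

test_that("the ACT1 presets carry the published parameter values", {
  k2p <- model_preset("act1-k2p")
  expect_equal(k2p$R["T", "C"], 4.493)
  expect_equal(k2p$R["A", "G"], 4.493)
  expect_equal(k2p$R["T", "A"], 1)
  expect_equal(unname(k2p$pi), rep(0.25, 4))

  hky <- model_preset("act1-hky")
  expect_equal(hky$R["T", "C"], 4.522)
  expect_equal(unname(hky$pi), c(0.336, 0.274, 0.235, 0.155))

  gtr <- model_preset("act1-gtr")
  expect_equal(gtr$R["T", "G"], 1)
  expect_equal(unname(gtr$pi), c(0.265, 0.225, 0.286, 0.224))
})

test_that("rate matrices satisfy normalization, reversibility and row sums", {
  # JC at lam = 1: every off-diagonal must be 1/3
  Qjc <- rate_matrix(substitution_model("JC"), 1)
  expect_equal(unique(Qjc$Q[upper.tri(Qjc$Q)]), 1 / 3)
  expect_equal(unname(diag(Qjc$Q)), rep(-1, 4))

  # lam = 0 gives the zero matrix
  expect_equal(max(abs(rate_matrix(model_preset("act1-gtr"), 0)$Q)), 0)
  expect_error(rate_matrix(substitution_model("JC"), -1), "nonnegative")

  # GTR of the ACT1 preset at lam = 1: recompute the normalization constant
  # independently by direct summation over q_ij = s r_ij pi_j
  m <- model_preset("act1-gtr")
  s_indep <- 1 / sum(m$pi * (m$R %*% m$pi))
  Q <- rate_matrix(m, 1)
  expect_equal(Q$Q["T", "C"], s_indep * 9.082 * m$pi[["C"]], tolerance = 1e-12)
  expect_equal(max(abs(rowSums(Q$Q))), 0, tolerance = 1e-12)
  expect_equal(sum(m$pi * (rowSums(Q$Q) - diag(Q$Q))), 1, tolerance = 1e-10)
  expect_lt(max(abs(m$pi * Q$Q - t(m$pi * Q$Q))), 1e-10)
})

test_that("transition matrices match the JC closed form and the stationary limit", {
  Q <- rate_matrix(substitution_model("JC"), 1)
  expect_equal(transition_matrix(Q, 0)$P, diag(4), ignore_attr = TRUE)
  expect_equal(max(abs(transition_matrix(Q, 50)$P - 0.25)), 0, tolerance = 1e-10)
  for (lt in c(0, 0.01, 0.1, 1, 5, 50)) {
    expect_equal(transition_matrix(Q, lt)$P, jc_closed_form(1, lt)$P,
                 tolerance = 1e-12)
  }
  # explicit closed-form values at lam*t = 0.1
  P <- transition_matrix(Q, 0.1)$P
  expect_equal(P[1, 1], 1 / 4 + (3 / 4) * exp(-0.4 / 3), tolerance = 1e-12)
  expect_equal(P[1, 2], 1 / 4 - (1 / 4) * exp(-0.4 / 3), tolerance = 1e-12)
  expect_error(transition_matrix(Q, -0.1), "nonnegative")
})

test_that("random GTR transition matrices satisfy the Markov-chain identities", {
  set.seed(11)
  for (rep in 1:25) {
    m <- random_gtr_model()
    lam <- stats::runif(1, 0.05, 2)
    t1 <- stats::runif(1, 0, 5 / lam)
    t2 <- stats::runif(1, 0, 5 / lam)
    Q <- rate_matrix(m, lam)
    P1 <- transition_matrix(Q, t1)$P
    P2 <- transition_matrix(Q, t2)$P
    P12 <- transition_matrix(Q, t1 + t2)$P
    expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
    expect_lt(max(abs(m$pi %*% P1 - m$pi)), 1e-10)                 # stationarity
    expect_lt(max(abs(m$pi * P1 - t(m$pi * P1))), 1e-10)           # detailed balance
    expect_lt(max(abs(P1 %*% P2 - P12)), 1e-9)                     # Chapman-Kolmogorov
    expect_true(all(P1 >= 0 & P1 <= 1))
  }
})

test_that("the k-state symmetric model generalizes JC", {
  mk4 <- substitution_model("MK_K", k = 4)
  Q4 <- rate_matrix(mk4, 1)
  expect_equal(unname(Q4$Q), unname(rate_matrix(substitution_model("JC"), 1)$Q))
  P <- transition_matrix(Q4, 0.3)$P
  expect_equal(unname(P), unname(jc_closed_form(1, 0.3)$P), tolerance = 1e-12)

  mk2 <- substitution_model("MK_K", k = 2)
  P2 <- transition_matrix(rate_matrix(mk2, 1), 0.5)$P
  # two-state symmetric closed form: p_ii = 1/2 + 1/2 e^{-2 lam t}
  expect_equal(P2[1, 1], 0.5 + 0.5 * exp(-2 * 0.5), tolerance = 1e-12)
  expect_error(substitution_model("MK_K", k = 1), "at least 2")
})

test_that("custom models round-trip through the plain-text file format", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a b c",
               "1.5 0.5",
               "2.0",
               "0.2 0.3 0.5"), path)
  m <- read_model_file(path)
  expect_identical(m$states, c("a", "b", "c"))
  expect_equal(m$R["a", "b"], 1.5)
  expect_equal(m$R["a", "c"], 0.5)
  expect_equal(m$R["b", "c"], 2.0)
  expect_equal(unname(m$pi), c(0.2, 0.3, 0.5))
  Q <- rate_matrix(m, 1)
  expect_equal(sum(m$pi * (rowSums(Q$Q) - diag(Q$Q))), 1, tolerance = 1e-10)

  writeLines(c("a b c", "1.5", "2.0", "0.2 0.3 0.5"), path)
  expect_error(read_model_file(path), "lengths")
})

test_that("p-length conversion is the exact JC inverse pair", {
  expect_equal(p_from_lt(1, 0), 0)
  expect_equal(p_from_lt(0, 5), 0)
  expect_equal(p_from_lt(1, 0.3831), 0.3, tolerance = 1e-4)
  # approach to the 0.75 supremum (saturates to it in double precision)
  expect_lt(p_from_lt(1, 25), 0.75)
  expect_gt(p_from_lt(1, 25), 0.75 - 1e-12)
  expect_lte(p_from_lt(1, 100), 0.75)

  expect_equal(lt_from_p(0), 0)
  expect_error(lt_from_p(0.75), "0.75")
  expect_error(lt_from_p(-0.1), "0.75")
  for (p in c(0.1, 0.3, 0.6, 0.749)) {
    expect_equal(p_from_lt(1, lt_from_p(p)), p, tolerance = 1e-12)
  }
  # strictly increasing in lam*t
  lts <- seq(0, 10, length.out = 50)
  expect_true(all(diff(p_from_lt(1, lts)) > 0))
})
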
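test_that("BN selection probabilities follow the product rule and sum to 1", {
  m <- fixture_p53_mdm2()
  expect_equal(bn_selection_probability(m, c(1, 1)), 0.25)
  expect_equal(bn_selection_probability(m, c(2, 3)), 0.4 * 0.09)
  expect_error(bn_selection_probability(m, c(5, 1)), "invalid choice")

  # every l(i) = 1: the empty product of certainties
  expect_equal(bn_selection_probability(deterministic_model(), c(1, 1)), 1)

  # exhaustive enumeration: selection probabilities form a distribution
  set.seed(5)
  m3 <- generate_random_pbn(3, seed = 17)
  l <- vapply(m3$functions, length, integer(1))
  grid <- as.matrix(expand.grid(lapply(l, seq_len)))
  total <- sum(apply(grid, 1, function(ch) bn_selection_probability(m3, ch)))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("evaluate_bn applies the selected truth-table columns", {
  m <- fixture_p53_mdm2()
  # state 00, first function of both genes: f1^1 = 1, f1^2 = 0
  expect_equal(evaluate_bn(m, c(1, 1), c(0, 0)), c(1L, 0L))
  # fourth functions at 00: f4^1 = 0, f4^2 = 1
  expect_equal(evaluate_bn(m, c(4, 4), c(0, 0)), c(0L, 1L))

  # a network of self-buffers is the identity
  mb <- pbn_model(c("x", "y"), list(
    x = list(pbn_function("x", gate = "BUFFER", prob = 1)),
    y = list(pbn_function("y", gate = "BUFFER", prob = 1))))
  for (s in 0:3) {
    bits <- decode_state(s, 2)
    expect_equal(evaluate_bn(mb, c(1, 1), bits), bits)
  }

  # random 4-gene model vs the independent table-lookup oracle
  m4 <- generate_random_pbn(4, seed = 23)
  l <- vapply(m4$functions, length, integer(1))
  set.seed(31)
  for (rep in 1:20) {
    choice <- vapply(l, function(li) sample.int(li, 1L), integer(1))
    bits <- sample(0:1, 4, replace = TRUE)
    want <- vapply(seq_len(4), function(i)
      oracle_eval_fn(m4$functions[[i]][[choice[i]]], bits, m4$genes),
      integer(1))
    expect_equal(evaluate_bn(m4, choice, bits), want)
  }
})

test_that("the exact transition matrix matches both the printed example and enumeration", {
  m <- fixture_p53_mdm2()
  A <- transition_matrix_exact(m)
  expect_equal(unname(A["01", ]), c(0.09, 0.01, 0.81, 0.09),
               tolerance = 1e-12)
  expect_equal(round(unclass(A), 4), p53_exact, ignore_attr = TRUE)
  expect_equal(A["00", "10"], 0.9801, tolerance = 1e-12)

  # deterministic model: a 0/1 matrix with one 1 per row
  Ad <- transition_matrix_exact(deterministic_model())
  expect_true(all(Ad %in% c(0, 1)))
  expect_equal(unname(rowSums(Ad)), rep(1, 4))

  # marginal products equal the brute-force sum over all N networks
  for (seed in c(3, 7, 19)) {
    m3 <- generate_random_pbn(3, seed = seed)
    expect_equal(unclass(transition_matrix_exact(m3)),
                 oracle_transition_matrix(m3),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }

  # perturbed models are rejected with a pointer
  mp <- fixture_p53_mdm2(perturbation = 0.01)
  expect_error(transition_matrix_exact(mp), "perturbed_transition_matrix")
})

test_that("perturbation produces the printed matrix and keeps rows stochastic", {
  A <- transition_matrix_exact(fixture_p53_mdm2())
  At <- perturbed_transition_matrix(A, 0.01)
  expect_lt(max(abs(unclass(At) - p53_perturbed)), 5e-5)
  expect_equal(At["00", "10"], 0.97049601, tolerance = 1e-10)

  # p = 0 is the identity operation
  expect_equal(perturbed_transition_matrix(A, 0), A)

  # diagonal scaling is exact: Atilde[s,s] = (1-p)^n A[s,s]
  for (p in c(0.01, 0.2, 0.7)) {
    Ap <- perturbed_transition_matrix(A, p)
    expect_equal(unname(diag(Ap)), unname((1 - p)^2 * diag(A)),
                 tolerance = 1e-14)
    expect_equal(unname(rowSums(Ap)), rep(1, 4), tolerance = 1e-12)
  }

  # row sums stay 1 for random models and perturbation rates
  m3 <- generate_random_pbn(3, seed = 41)
  A3 <- transition_matrix_exact(m3)
  for (p in c(1e-4, 0.05, 0.5, 0.9)) {
    expect_equal(unname(rowSums(perturbed_transition_matrix(A3, p))),
                 rep(1, 8), tolerance = 1e-12)
  }
  expect_error(perturbed_transition_matrix(A, 1), "\\[0, 1\\)")
})

test_that("DA-PBN simulation honours updating periods", {
  m <- fixture_p53_mdm2()

  # single gene, period 3, NOT of itself: toggles only at t = 3, 6, 9
  m1 <- pbn_model("x", list(x = list(pbn_function("x", gate = "NOT",
                                                  prob = 1))),
                  periods = 3L)
  traj <- simulate_da_pbn(m1, 0L, horizon = 9, seed = 1)
  expect_equal(as.integer(traj[, 1]),
               c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L))

  # missing periods is a configuration error
  expect_error(simulate_da_pbn(m, c(0, 0), 5), "periods")

  # unit periods: one-step transitions match the synchronous matrix
  # (chi-squared over the pooled transition counts of a long chain)
  ms <- pbn_model(m$genes, m$functions, periods = c(1L, 1L))
  A <- transition_matrix_exact(m)
  traj <- simulate_da_pbn(ms, c(0, 1), horizon = 10000, seed = 99)
  from <- traj[-nrow(traj), , drop = FALSE] %*% c(2, 1)
  to <- traj[-1, , drop = FALSE] %*% c(2, 1)
  chi2 <- 0; df <- 0
  for (s in 0:3) {
    rows <- which(from == s)
    if (length(rows) < 50) next
    obs <- tabulate(to[rows] + 1, nbins = 4)
    exp_ <- length(rows) * A[s + 1, ]
    keep <- exp_ > 1e-9
    chi2 <- chi2 + sum((obs[keep] - exp_[keep])^2 / exp_[keep])
    df <- df + sum(keep) - 1
  }
  expect_gt(stats::pchisq(chi2, df, lower.tail = FALSE), 0.01)

  # periods (1,2): empirical two-step distribution equals the composed
  # analytic stage matrices
  ma <- pbn_model(m$genes, m$functions, periods = c(1L, 2L))
  S1 <- transition_matrix_exact(stage_model(m, 1))
  S2 <- transition_matrix_exact(stage_model(m, c(1, 2)))
  M2 <- unclass(S1) %*% unclass(S2)
  set.seed(7)
  counts <- numeric(4)
  n_rep <- 4000
  for (r in seq_len(n_rep)) {
    tr <- simulate_da_pbn(ma, c(0, 1), horizon = 2)
    s <- sum(tr[3, ] * c(2, 1))
    counts[s + 1] <- counts[s + 1] + 1
  }
  p_hat <- counts / n_rep
  expected <- M2[2, ]  # row of input state 01
  expect_lt(max(abs(p_hat - expected) /
                  pmax(binomial_se(expected, n_rep), 1e-9)), 4)
})
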
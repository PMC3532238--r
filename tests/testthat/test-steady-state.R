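test_that("distribution iteration follows d_t = d_0 A^t", {
  I4 <- diag(4); rownames(I4) <- colnames(I4) <- state_labels(2)
  d0 <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(unname(iterate_distribution(I4, d0, 17)), d0,
               ignore_attr = TRUE)

  A <- perturbed_transition_matrix(
    transition_matrix_exact(fixture_p53_mdm2()), 0.01)
  d <- iterate_distribution(A, rep(0.25, 4), 500)
  expect_equal(unname(d), unname(stationary_distribution(A)),
               tolerance = 1e-6)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_error(iterate_distribution(A, c(1, 1, 0, 0), 1), "distribution")
})

test_that("attractor detection finds cycles and stationary points", {
  # deterministic 2-cycle: permutation of two states
  P <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("0", "1"), c("0", "1")))
  rep2 <- detect_attractors(P, init = 0, threshold = 1e-9, burn_in = 2)
  expect_true(rep2$converged)
  expect_equal(rep2$period, 2)
  expect_setequal(rep2$states, c(0, 1))

  # ergodic chain with a positive spectrum (lazy walk on the perturbed
  # p53 chain): monotone convergence, period 1, top state of the
  # stationary law
  A <- perturbed_transition_matrix(
    transition_matrix_exact(fixture_p53_mdm2()), 0.01)
  A_lazy <- 0.5 * diag(4) + 0.5 * unclass(A)
  dimnames(A_lazy) <- dimnames(A)
  rep1 <- detect_attractors(A_lazy, init = 0, threshold = 1e-9)
  expect_equal(rep1$period, 1)
  expect_equal(rep1$labels, "10")
  # the damped oscillation of the perturbed chain itself is reported
  # with the period of its transient
  rep_damped <- detect_attractors(A, init = 0, threshold = 1e-9)
  expect_true(rep_damped$converged)
  expect_equal(rep_damped$period, 2)
  expect_lt(max(abs(rep_damped$distribution -
                      stationary_distribution(A))), 1e-6)

  # unperturbed p53 from one-hot 00: transient oscillation between the
  # two high-probability states 10 and 01 (independent direct iteration
  # confirms the argmax alternation at the detection point)
  A0 <- transition_matrix_exact(fixture_p53_mdm2())
  rep0 <- detect_attractors(A0, init = 0, threshold = 0.02)
  expect_true(rep0$converged)
  expect_equal(rep0$period, 2)
  d <- c(1, 0, 0, 0)
  argmax <- integer(rep0$frames)
  for (t in seq_len(rep0$frames)) {
    d <- as.numeric(d %*% unclass(A0)); argmax[t] <- which.max(d) - 1L
  }
  expect_setequal(rep0$states, argmax[(rep0$frames - 1):rep0$frames])
  expect_setequal(rep0$states, c(1, 2))  # states 01 and 10

  # no cycle within the window is a report, not an exception
  drift <- matrix(0, 3, 3)  # 3-cycle hidden from a window of 2
  drift[cbind(1:3, c(2, 3, 1))] <- 1
  repn <- detect_attractors(rbind(diag(3)[1, ], diag(3)[2, ], diag(3)[3, ],
                                  diag(3)[1, ], diag(3)[2, ], diag(3)[3, ],
                                  diag(3)[1, ], diag(3)[2, ], diag(3)[3, ]),
                            cycle_window = 2, threshold = 1e-9,
                            burn_in = 2)
  expect_false(repn$converged)
  expect_true(is.na(repn$period))
})

test_that("a 12-gene network with a designed 3-cycle is recovered at T-cell scale", {
  # deterministic 12-gene synthetic network: genes 1 and 2 rotate through
  # (0,0) -> (0,1) -> (1,0) -> (0,0) (a 3-state orbit), all other genes
  # hold their value; from a one-hot start the distribution orbit has
  # period 3, mirroring the attractor analysis of the published T-cell
  # matrix without requiring its (supplementary) truth tables.
  genes <- sprintf("g%02d", 1:12)
  fs <- list(
    # g1' = !g1 & !g2 ... using a truth table over (g1, g2)
    list(pbn_function(genes[1:2], table = c(0, 1, 0, 0), prob = 1)),
    list(pbn_function(genes[1:2], table = c(1, 0, 0, 0), prob = 1)))
  for (i in 3:12)
    fs[[i]] <- list(pbn_function(genes[i], gate = "BUFFER", prob = 1))
  names(fs) <- genes
  m12 <- pbn_model(genes, fs)
  A12 <- transition_matrix_exact(m12)
  expect_equal(dim(A12), c(4096, 4096))

  start <- rep(0L, 12); start[12] <- 1L   # an arbitrary held tail bit
  rep3 <- detect_attractors(A12, init = encode_state(start),
                            threshold = 1e-9, burn_in = 3)
  expect_true(rep3$converged)
  expect_equal(rep3$period, 3)
  orbit_bits <- lapply(rep3$states, decode_state, n = 12)
  pairs <- t(vapply(orbit_bits, function(b) b[1:2], integer(2)))
  expect_setequal(apply(pairs, 1, paste, collapse = ""),
                  c("00", "01", "10"))
  expect_true(all(vapply(orbit_bits, function(b) all(b[3:12] == start[3:12]),
                         logical(1))))
})

test_that("time-frame expansion matches the analytic steady state", {
  m <- fixture_p53_mdm2()
  At <- perturbed_transition_matrix(transition_matrix_exact(m), 0.01)
  pi_ <- stationary_distribution(At)

  sbn <- build_sbn(m, perturbation = 0.01)
  cfg <- convergence_config(threshold = 1e-3, L = 1e5, max_frames = 100)
  res <- time_frame_expansion(sbn, c(0, 0), cfg, seed = 21)
  expect_true(res$converged)
  expect_lt(max(abs(res$distribution - pi_)), 0.01)
  # stationarity of the returned distribution under the analytic matrix
  expect_lt(max(abs(as.numeric(res$distribution %*% unclass(At)) -
                      res$distribution)), 2 * cfg$threshold)

  # a distribution-valued initial condition is accepted and converges too
  res_u <- time_frame_expansion(sbn, rep(0.25, 4), cfg, seed = 22)
  expect_lt(max(abs(res_u$distribution - pi_)), 0.01)

  # deterministic fixed point: convergence within two frames, one-hot
  m_fix <- pbn_model(c("a", "b"), list(
    a = list(pbn_function("a", table = c(1, 1), prob = 1)),
    b = list(pbn_function("b", table = c(1, 1), prob = 1))))
  cfg_f <- suppressWarnings(convergence_config(threshold = 1e-6, L = 1000))
  res_f <- time_frame_expansion(build_sbn(m_fix), c(0, 0), cfg_f, seed = 23)
  expect_true(res_f$converged)
  expect_lte(res_f$frames, 3)
  expect_equal(unname(res_f$distribution), c(0, 0, 0, 1),
               ignore_attr = TRUE)

  # expectation agreement with matrix iteration: mean over 50 seeds of
  # the frame-3 distribution vs d_0 A^3 at L = 1000, n = 2
  A <- transition_matrix_exact(m)
  d3 <- iterate_distribution(At, c(1, 0, 0, 0), 3)
  set.seed(31)
  traj3 <- replicate(50, {
    cfg3 <- suppressWarnings(convergence_config(threshold = 1e-9, L = 1000,
                                                max_frames = 3,
                                                cycle_window = 1))
    r <- time_frame_expansion(sbn, c(0, 0), cfg3)
    r$trajectory[4, ]
  })
  m3 <- rowMeans(traj3)
  se3 <- apply(traj3, 1, stats::sd) / sqrt(50)
  expect_lt(max(abs(m3 - d3) / pmax(se3, 1e-5)), 4)

  # exceeding max_frames yields a diagnosable non-converged result
  cfg_n <- suppressWarnings(convergence_config(threshold = 1e-9, L = 1000,
                                               max_frames = 5))
  res_n <- time_frame_expansion(sbn, c(0, 0), cfg_n, seed = 24)
  expect_false(res_n$converged)
  expect_equal(res_n$frames, 5)
})

test_that("the resolution rule L >= 100/threshold warns but does not stop", {
  expect_warning(convergence_config(threshold = 1e-3, L = 1000),
                 "resolution")
  expect_silent(convergence_config(threshold = 1e-3, L = 1e5))
})

test_that("pseudo-attractor reports annotate nearest attractors by Hamming distance", {
  # one-hot on an attractor: empty report
  d <- c(0, 0, 0, 1)
  expect_equal(nrow(pseudo_attractor_report(d, attractors = 3)), 0)

  # synthetic 3-gene case vs hand enumeration
  d3 <- c(0.50, 0.20, 0.05, 0.05, 0.15, 0.02, 0.02, 0.01)
  rep3 <- pseudo_attractor_report(d3, attractors = c(0, 4), min_prob = 0.05)
  # candidates: states 1 (0.20), 2 (0.05), 3 (0.05); state 4 is an attractor
  expect_equal(rep3$state, c(1, 2, 3))
  # 001 differs from 000 by the third gene only
  expect_equal(rep3$hamming[1], 1)
  expect_equal(rep3$genes_differing[1], "g(3)")
  expect_equal(rep3$nearest_attractor[1], "000")
  # 011 is equidistant (2) from 000 and 100 is not: check 010
  expect_equal(rep3$genes_differing[2], "g(2)")
  # ties are all reported: 011 at distance 2 from 000 and distance 3
  # from 100 -> nearest is 000 only
  expect_equal(rep3$nearest_attractor[3], "000")

  # genuine tie: attractors 000 and 011, candidate 001
  d_t <- c(0.5, 0.3, 0, 0.2, 0, 0, 0, 0)
  rep_t <- pseudo_attractor_report(d_t, attractors = c(0, 3),
                                   min_prob = 0.25)
  expect_match(rep_t$nearest_attractor[1], "\\|")

  # the printed T-cell arithmetic: state numbers 1768 and 1736 (LSB-first,
  # 1-based) differ exactly in gene 6
  b1 <- decode_state(1768, 12, "eq10")
  b2 <- decode_state(1736, 12, "eq10")
  expect_equal(which(b1 != b2), 6L)
})
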
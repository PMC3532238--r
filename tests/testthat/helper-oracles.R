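# Printed reference matrices for the two-gene p53-Mdm2 example
# (rows/cols in state order 00, 01, 10, 11).

p53_exact <- matrix(c(
  0.0099, 0.0001, 0.9801, 0.0099,
  0.0900, 0.0100, 0.8100, 0.0900,
  0.0900, 0.8100, 0.0100, 0.0900,
  0.2500, 0.2500, 0.2500, 0.2500), 4, 4, byrow = TRUE,
  dimnames = list(state_labels(2), state_labels(2)))

# one bitstream realization at L = 10000 of the same matrix
p53_sbn_realization <- matrix(c(
  0.0097, 0.0003, 0.9803, 0.0097,
  0.0899, 0.0101, 0.8101, 0.0899,
  0.0904, 0.8096, 0.0096, 0.0904,
  0.2511, 0.2489, 0.2489, 0.2511), 4, 4, byrow = TRUE,
  dimnames = list(state_labels(2), state_labels(2)))

# analytic matrix with perturbation p = 0.01 (4-decimal rounding)
p53_perturbed <- matrix(c(
  0.0097, 0.0100, 0.9705, 0.0098,
  0.0981, 0.0098, 0.7940, 0.0981,
  0.0981, 0.7940, 0.0098, 0.0981,
  0.2451, 0.2549, 0.2549, 0.2450), 4, 4, byrow = TRUE,
  dimnames = list(state_labels(2), state_labels(2)))

# ---- independent oracles (deliberately reimplemented, not package code) ----

# truth-table lookup by Horner's scheme (package code uses powers of two)
oracle_eval_fn <- function(fn, bits, genes) {
  pos <- match(fn$inputs, genes)
  r <- 0L
  for (p in pos) r <- r * 2L + bits[p]
  fn$table[r + 1L]
}

oracle_state_bits <- function(s, n) {
  bits <- integer(n)
  for (i in n:1) { bits[i] <- s %% 2L; s <- s %/% 2L }
  bits
}

# brute-force transition matrix: enumerate all N constituent BNs,
# A = sum_j P_j A_j
oracle_transition_matrix <- function(model) {
  n <- length(model$genes)
  M <- 2L^n
  l <- vapply(model$functions, length, integer(1))
  grid <- as.matrix(expand.grid(lapply(l, seq_len)))
  A <- matrix(0, M, M)
  for (j in seq_len(nrow(grid))) {
    choice <- grid[j, ]
    Pj <- prod(vapply(seq_len(n), function(i)
      model$functions[[i]][[choice[i]]]$prob, numeric(1)))
    for (s in 0:(M - 1L)) {
      bits <- oracle_state_bits(s, n)
      nxt <- vapply(seq_len(n), function(i)
        oracle_eval_fn(model$functions[[i]][[choice[i]]], bits,
                       model$genes), integer(1))
      t <- sum(nxt * 2L^((n - 1L):0L))
      A[s + 1L, t + 1L] <- A[s + 1L, t + 1L] + Pj
    }
  }
  A
}

# replace the functions of genes not in `due` by a self-buffer; used to
# build the analytic matrix of one asynchronous stage
stage_model <- function(model, due) {
  fs <- lapply(seq_along(model$genes), function(i) {
    if (i %in% due) model$functions[[i]]
    else list(pbn_function(model$genes[i], gate = "BUFFER", prob = 1))
  })
  names(fs) <- model$genes
  pbn_model(model$genes, fs)
}

# largest-remainder apportionment, reimplemented
oracle_apportion <- function(probs, L) {
  x <- probs * L
  cnt <- floor(x)
  need <- L - sum(cnt)
  if (need > 0) {
    ord <- order(x - cnt, decreasing = TRUE)
    cnt[ord[seq_len(need)]] <- cnt[ord[seq_len(need)]] + 1
  }
  cnt
}

binomial_se <- function(q, L) sqrt(q * (1 - q) / L)

# a deterministic single-BN model (all l(i) = 1): 2-gene swap-and-invert
deterministic_model <- function() {
  pbn_model(c("a", "b"), list(
    a = list(pbn_function("b", gate = "NOT", prob = 1)),
    b = list(pbn_function("a", gate = "BUFFER", prob = 1))))
}
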
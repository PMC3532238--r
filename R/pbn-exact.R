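#' Exact state transition matrix of a PBN
#'
#' Computes the `2^n x 2^n` row-stochastic state transition matrix of an
#' independent PBN analytically. Because function selection is independent
#' across genes, each row factorizes into per-gene marginals: for input
#' state `s`, gene `i` takes value 1 with probability
#' \eqn{\sum_{j: f_j^i(s)=1} c_j^i}, and the row is the product of these
#' marginals over genes (an `O(n 2^n)` per-row computation). This equals
#' the brute-force mixture \eqn{A = \sum_j P_j A_j} over all
#' `N = prod(l(i))` constituent Boolean networks.
#'
#' @param model A [pbn_model()] with `perturbation == 0`; perturbation is
#'   applied separately by [perturbed_transition_matrix()].
#' @return A `2^n x 2^n` matrix with binary state labels as dimnames
#'   (`"matrix"` index convention: first gene = most significant bit).
#' @examples
#' A <- transition_matrix_exact(fixture_p53_mdm2())
#' A["01", ]  # 0.09 0.01 0.81 0.09
#' @export
transition_matrix_exact <- function(model) {
  stopifnot(inherits(model, "pbn"))
  if (model$perturbation != 0)
    stop("model has perturbation > 0; compute the unperturbed matrix and ",
         "apply perturbed_transition_matrix()")
  n <- n_genes(model)
  states <- .state_bit_matrix(n)
  M <- 2L^n
  A <- matrix(0, M, M)
  probs <- lapply(model$functions, function(fs)
    vapply(fs, `[[`, numeric(1), "prob"))
  for (s in seq_len(M)) {
    bits <- states[s, ]
    ## per-gene marginal P(x_i' = 1 | s)
    p1 <- vapply(seq_len(n), function(i) {
      vals <- vapply(model$functions[[i]],
                     function(fn) .eval_function(fn, bits, model$genes),
                     integer(1))
      sum(probs[[i]][vals == 1L])
    }, numeric(1))
    ## row as the Kronecker product over genes (gene 1 most significant)
    A[s, ] <- Reduce(kronecker, lapply(p1, function(p) c(1 - p, p)))
  }
  dimnames(A) <- list(state_labels(n), state_labels(n))
  .check_transition_matrix(A)
  .tag_convention(A)
}

#' Apply random gene perturbation to a transition matrix
#'
#' Under random gene perturbation, every gene independently flips its value
#' with probability `p` at each transition; when at least one gene flips
#' (probability \eqn{1-(1-p)^n}) the flip replaces the Boolean update,
#' otherwise a constituent network acts as usual. With perturbation bits
#' i.i.d. Bernoulli(`p`), the perturbed matrix has the closed form
#' \deqn{\tilde A[s,s'] = (1-p)^n A[s,s'] +
#'       [s' \neq s]\, p^{H(s,s')} (1-p)^{n-H(s,s')},}
#' where `H` is the Hamming distance between states; rows sum to 1
#' analytically.
#'
#' @param A An unperturbed transition matrix (e.g. from
#'   [transition_matrix_exact()]).
#' @param p Perturbation probability in `[0, 1)`.
#' @param n Number of genes; defaults to `log2(nrow(A))`.
#' @return The perturbed transition matrix, same shape and labels as `A`.
#' @examples
#' A <- transition_matrix_exact(fixture_p53_mdm2())
#' perturbed_transition_matrix(A, 0.01)["00", "10"]  # 0.97049601
#' @export
perturbed_transition_matrix <- function(A, p, n = round(log2(nrow(A)))) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 1)
    stop("`p` must lie in [0, 1)")
  .check_transition_matrix(A)
  if (nrow(A) != 2^n) stop("`n` inconsistent with the matrix order")
  if (p == 0) return(A)
  H <- .hamming_matrix(n)
  P <- p^H * (1 - p)^(n - H)
  diag(P) <- 0
  At <- (1 - p)^n * A + P
  .check_transition_matrix(At, tol = 1e-9)
  .tag_convention(At)
}

#' Simulate a deterministic-asynchronous PBN trajectory
#'
#' In a DA-PBN each gene has a fixed updating period; at time `t` gene `i`
#' updates if and only if `t` is a multiple of its period, in which case a
#' function is drawn according to the selection probabilities and applied
#' to the full pre-update state (genes due at the same time update
#' synchronously within the event); non-updated genes hold their value.
#'
#' @param model A [pbn_model()] with `periods` set.
#' @param initial Integer 0/1 vector: the state at `t = 0`.
#' @param horizon Number of time steps to simulate (`>= 1`).
#' @param seed Optional integer seed for reproducibility.
#' @return An integer matrix of dimension `(horizon + 1) x n`; row `t + 1`
#'   is the state at time `t`, with gene names as column names.
#' @export
simulate_da_pbn <- function(model, initial, horizon, seed = NULL) {
  stopifnot(inherits(model, "pbn"))
  if (is.null(model$periods))
    stop("model has no updating periods; set `periods` in pbn_model() ",
         "for deterministic-asynchronous simulation")
  if (!is.numeric(horizon) || horizon < 1)
    stop("`horizon` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- n_genes(model)
  state <- as.integer(initial)
  if (length(state) != n || !all(state %in% c(0L, 1L)))
    stop("`initial` must be a 0/1 vector over the model's genes")
  out <- matrix(0L, horizon + 1L, n,
                dimnames = list(0:horizon, model$genes))
  out[1L, ] <- state
  probs <- lapply(model$functions, function(fs)
    vapply(fs, `[[`, numeric(1), "prob"))
  for (t in seq_len(horizon)) {
    due <- which(t %% model$periods == 0L)
    if (length(due)) {
      prev <- state
      for (i in due) {
        j <- sample.int(length(probs[[i]]), 1L, prob = probs[[i]])
        state[i] <- .eval_function(model$functions[[i]][[j]], prev,
                                   model$genes)
      }
    }
    out[t + 1L, ] <- state
  }
  out
}
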
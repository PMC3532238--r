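#' Compile a PBN into a stochastic Boolean network
#'
#' An SBN realizes a PBN as a logic network on random bitstreams: each
#' gene's candidate Boolean functions become subcircuits evaluated
#' position-wise on the present-state streams, and an `l(i)`-input
#' stochastic multiplexer, driven by a selector stream with the selection
#' probabilities `c_j^i`, picks the applied function per bit position.
#' Fanned-out streams are shared physically, so signal correlations are
#' preserved exactly.
#'
#' @param model A [pbn_model()] object.
#' @param perturbation Perturbation probability wrapped around the network
#'   (see [wrap_perturbation()]); defaults to the model's own value.
#' @return An object of class `sbn`.
#' @export
build_sbn <- function(model, perturbation = model$perturbation) {
  stopifnot(inherits(model, "pbn"))
  if (!is.numeric(perturbation) || perturbation < 0 || perturbation >= 1)
    stop("`perturbation` must lie in [0, 1)")
  structure(list(model = model, perturbation = perturbation,
                 stages = NULL),
            class = "sbn")
}

#' Add a random-gene-perturbation wrapper to an SBN
#'
#' Adds `n` independent perturbation bitstream sources at probability `p`,
#' XORs each with the corresponding present-state stream, and feeds the
#' `n`-input OR of the perturbation streams into a bus multiplexer that
#' selects, position-wise, the flipped state (when any perturbation bit is
#' 1) or the unperturbed SBN output.
#'
#' @param sbn An [build_sbn()] object.
#' @param p Perturbation probability in `[0, 1)`.
#' @return The wrapped `sbn`.
#' @export
wrap_perturbation <- function(sbn, p) {
  stopifnot(inherits(sbn, "sbn"))
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 1)
    stop("`p` must lie in [0, 1)")
  if (!is.null(sbn$stages) && p > 0)
    stop("perturbation of a staged (asynchronous) SBN is not defined")
  sbn$perturbation <- p
  sbn
}

#' Compile a DA-PBN into a staged (asynchronous) SBN
#'
#' Genes are scheduled by their updating periods: one macro period spans
#' `lcm(periods)` time steps, and each step becomes a stage in which only
#' the gene(s) due at that time carry their function subcircuits and
#' multiplexer while all other genes pass through buffers. A gene with a
#' period `r` times shorter than the macro period therefore appears `r`
#' times along the staged network.
#'
#' @param model A [pbn_model()] with `periods` set and `perturbation = 0`.
#' @return An object of class `sbn` whose `stages` field lists, per stage,
#'   the indices of the genes updated there.
#' @export
build_asynchronous_sbn <- function(model) {
  stopifnot(inherits(model, "pbn"))
  if (is.null(model$periods))
    stop("model has no updating periods; asynchronous construction ",
         "requires `periods`")
  if (model$perturbation != 0)
    stop("perturbation of a staged (asynchronous) SBN is not defined")
  macro <- Reduce(.lcm, as.numeric(model$periods))
  stages <- lapply(seq_len(macro),
                   function(t) unname(which(t %% model$periods == 0L)))
  stages <- stages[lengths(stages) > 0L]
  structure(list(model = model, perturbation = 0, stages = stages,
                 macro_period = macro),
            class = "sbn")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
.lcm <- function(a, b) a / .gcd(a, b) * b

#' @export
print.sbn <- function(x, ...) {
  n <- n_genes(x$model)
  cat(sprintf("Stochastic Boolean network: %d gene(s), %d multiplexer(s)\n",
              n, n))
  if (x$perturbation > 0)
    cat(sprintf("  perturbation wrapper: p = %g\n", x$perturbation))
  if (!is.null(x$stages))
    cat(sprintf("  asynchronous: %d stage(s) per macro period of %d\n",
                length(x$stages), x$macro_period))
  invisible(x)
}

## Vectorized truth-table lookup of one function over an L x n bit matrix
.eval_function_bits <- function(fn, B, genes) {
  pos <- match(fn$inputs, genes)
  k <- length(pos)
  idx <- rep.int(1L, nrow(B))
  for (j in seq_len(k)) idx <- idx + B[, pos[j]] * 2L^(k - j)
  fn$table[idx]
}

## One stage update: genes in `due` go through their mux, others buffer.
.sbn_stage <- function(model, B, due) {
  L <- nrow(B)
  out <- B
  for (i in due) {
    fs <- model$functions[[i]]
    if (length(fs) == 1L) {  # mux degenerates to a wire
      out[, i] <- .eval_function_bits(fs[[1L]], B, model$genes)
    } else {
      cand <- vapply(fs, .eval_function_bits, integer(L),
                     B = B, genes = model$genes)
      sel <- make_selector_stream(vapply(fs, `[[`, numeric(1), "prob"), L)
      out[, i] <- cand[cbind(seq_len(L), as.integer(sel) + 1L)]
    }
  }
  out
}

## One full SBN transition on an L x n bit matrix: all stages, then the
## perturbation wrapper. Fresh selector and perturbation streams are drawn
## on every call (fresh per row and per time frame).
.sbn_step <- function(sbn, B) {
  model <- sbn$model
  n <- n_genes(model)
  L <- nrow(B)
  stages <- if (is.null(sbn$stages)) list(seq_len(n)) else sbn$stages
  out <- B
  for (due in stages) out <- .sbn_stage(model, out, due)
  p <- sbn$perturbation
  if (p > 0) {
    gamma <- vapply(seq_len(n), function(i)
      .as_bits(make_bitstream(p, L)), integer(L))
    ctrl <- rowSums(gamma) > 0L          # n-input OR of the gamma streams
    if (any(ctrl)) {
      pert <- bitwXor(B, gamma)          # flip of the *present* state
      dim(pert) <- dim(B)
      out[ctrl, ] <- pert[ctrl, ]
    }
  }
  out
}

## Constant input streams (all-0 / all-1 columns) for a definite state
.state_to_stream_matrix <- function(state, L) {
  matrix(rep(as.integer(state), each = L), nrow = L)
}

#' Estimate one transition-matrix row with an SBN
#'
#' Drives the SBN with constant input streams encoding `input_state`
#' (all-0 / all-1 per gene), draws fresh selector and perturbation streams,
#' propagates the bitstreams through the network and decodes the output
#' state frequencies. The expected value of each decoded entry equals the
#' analytic transition probability.
#'
#' @param sbn An `sbn` object.
#' @param input_state Integer 0/1 vector over the model's genes.
#' @param L Sequence length (`>= 1`).
#' @param seed Optional integer seed.
#' @return A probability vector over the `2^n` states (sums to 1).
#' @export
sbn_transition_row <- function(sbn, input_state, L, seed = NULL) {
  stopifnot(inherits(sbn, "sbn"))
  if (!is.null(seed)) set.seed(seed)
  n <- n_genes(sbn$model)
  input_state <- as.integer(input_state)
  if (length(input_state) != n || !all(input_state %in% c(0L, 1L)))
    stop("`input_state` must be a 0/1 vector over the model's genes")
  B <- .state_to_stream_matrix(input_state, L)
  decode_state_frequencies(.sbn_step(sbn, B))
}

#' Estimate the full state transition matrix with an SBN
#'
#' Runs [sbn_transition_row()] for each of the `2^n` input states with
#' independent streams per state and stacks the rows; the result is
#' row-stochastic by construction. Complexity is `O(n L 2^n)`, independent
#' of the number `N` of constituent Boolean networks.
#'
#' @inheritParams sbn_transition_row
#' @return A `2^n x 2^n` matrix with binary state labels.
#' @examples
#' sbn <- build_sbn(fixture_p53_mdm2())
#' A_hat <- sbn_transition_matrix(sbn, L = 1000, seed = 1)
#' @export
sbn_transition_matrix <- function(sbn, L, seed = NULL) {
  stopifnot(inherits(sbn, "sbn"))
  if (!is.null(seed)) set.seed(seed)
  n <- n_genes(sbn$model)
  states <- .state_bit_matrix(n)
  A <- t(vapply(seq_len(nrow(states)), function(s)
    sbn_transition_row(sbn, states[s, ], L), numeric(2L^n)))
  dimnames(A) <- list(state_labels(n), state_labels(n))
  .tag_convention(A)
}
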
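#' Matrix difference norms
#'
#' Norms of `A - B` in the Matlab conventions used to compare transition
#' matrices: norm 1 is the maximum absolute column sum, norm infinity the
#' maximum absolute row sum, and norm 2 the largest singular value
#' (spectral norm) of the difference.
#'
#' @param A,B Matrices of equal shape.
#' @return A single non-negative number.
#' @examples
#' A <- transition_matrix_exact(fixture_p53_mdm2())
#' B <- sbn_transition_matrix(build_sbn(fixture_p53_mdm2()), 10000, seed = 1)
#' c(norm1_diff(A, B), norm2_diff(A, B), norminf_diff(A, B))
#' @export
norm1_diff <- function(A, B) .norm_diff(A, B, "O")

#' @rdname norm1_diff
#' @export
norm2_diff <- function(A, B) .norm_diff(A, B, "2")

#' @rdname norm1_diff
#' @export
norminf_diff <- function(A, B) .norm_diff(A, B, "I")

.norm_diff <- function(A, B, type) {
  if (!all(dim(A) == dim(B)))
    stop("matrices must have the same shape")
  norm(unclass(A) - unclass(B), type = type)
}

#' Generate a random PBN
#'
#' Reproduces the random-network protocol used for benchmarking: per gene
#' the number of Boolean functions is drawn uniformly from
#' `1:max_functions`, each function is a gate drawn uniformly from
#' `gate_set` with input genes drawn uniformly without replacement, and
#' the selection probabilities are drawn from a symmetric Dirichlet(1)
#' (uniform on the simplex).
#'
#' @param n_genes Number of genes (`>= 1`; `>= 2` if any two-input gate is
#'   in `gate_set`).
#' @param max_functions Maximum functions per gene (default 4, the typical
#'   upper bound for real regulatory networks).
#' @param gate_set Character subset of [gate_names()].
#' @param seed Optional integer seed; the same seed reproduces the same
#'   model.
#' @return A [pbn_model()] object.
#' @export
generate_random_pbn <- function(n_genes, max_functions = 4L,
                                gate_set = gate_names(), seed = NULL) {
  if (n_genes < 1L) stop("`n_genes` must be >= 1")
  if (max_functions < 1L) stop("`max_functions` must be >= 1")
  gate_set <- match.arg(gate_set, gate_names(), several.ok = TRUE)
  arity <- ifelse(gate_set %in% c("BUFFER", "NOT"), 1L, 2L)
  if (max(arity) > n_genes)
    stop("gate arity exceeds the number of genes; restrict `gate_set` ",
         "to BUFFER/NOT or use more genes")
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%d", seq_len(n_genes))
  functions <- lapply(genes, function(g) {
    l <- sample.int(max_functions, 1L)
    probs <- stats::rexp(l)
    probs <- probs / sum(probs)
    lapply(seq_len(l), function(j) {
      gi <- sample.int(length(gate_set), 1L)
      ins <- genes[sample.int(n_genes, arity[gi])]
      pbn_function(ins, gate = gate_set[gi], prob = probs[j])
    })
  })
  names(functions) <- genes
  pbn_model(genes, functions)
}

#' Minimum sequence length for a target matrix accuracy
#'
#' Searches the step-`step` grid of sequence lengths from below for the
#' smallest `L` at which the median (over `reps` repetitions) of the
#' chosen norm of `A_SBN(L) - A_exact` is at most `accuracy`.
#'
#' @param model A [pbn_model()] (unperturbed).
#' @param accuracy Target norm value (`> 0`).
#' @param norm One of `"1"`, `"2"`, `"inf"`.
#' @param reps Repetitions per grid point (default 5).
#' @param step Grid step (default 10; grid is `step, 2*step, ...`).
#' @param max_length Cap on the search; if the accuracy is not reached the
#'   cap is returned with `achieved = FALSE`.
#' @param seed Optional integer seed.
#' @return A list with `L`, `achieved`, `median_error` (at the returned
#'   `L`) and `trace` (data frame of the grid points visited).
#' @export
min_sequence_length <- function(model, accuracy, norm = c("2", "1", "inf"),
                                reps = 5L, step = 10L, max_length = 20000L,
                                seed = NULL) {
  norm <- match.arg(norm)
  if (accuracy <= 0) stop("`accuracy` must be positive")
  if (!is.null(seed)) set.seed(seed)
  nf <- switch(norm, "1" = norm1_diff, "2" = norm2_diff,
               "inf" = norminf_diff)
  A <- transition_matrix_exact(model)
  sbn <- build_sbn(model)
  grid <- seq(step, max_length, by = step)
  trace <- data.frame(L = numeric(0), median_error = numeric(0))
  for (L in grid) {
    errs <- vapply(seq_len(reps), function(r)
      nf(A, sbn_transition_matrix(sbn, L)), numeric(1))
    med <- stats::median(errs)
    trace <- rbind(trace, data.frame(L = L, median_error = med))
    if (med <= accuracy)
      return(list(L = L, achieved = TRUE, median_error = med,
                  trace = trace))
  }
  list(L = max_length, achieved = FALSE,
       median_error = trace$median_error[nrow(trace)], trace = trace)
}
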
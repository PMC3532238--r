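#' Truth tables of the named logic gates
#'
#' Row order: the inputs are enumerated in binary with the first-listed
#' input varying slowest, i.e. for a two-input gate the rows correspond to
#' input patterns 00, 01, 10, 11.
#' @keywords internal
.gate_tables <- list(
  BUFFER = c(0L, 1L),
  NOT    = c(1L, 0L),
  AND    = c(0L, 0L, 0L, 1L),
  NAND   = c(1L, 1L, 1L, 0L),
  OR     = c(0L, 1L, 1L, 1L),
  NOR    = c(1L, 0L, 0L, 0L),
  XOR    = c(0L, 1L, 1L, 0L),
  XNOR   = c(1L, 0L, 0L, 1L)
)

#' Names of the supported logic gates
#'
#' @return Character vector of gate names usable in [pbn_function()] and
#'   [generate_random_pbn()].
#' @export
gate_names <- function() names(.gate_tables)

#' Define one Boolean predictor function of a PBN gene
#'
#' A gene of a probabilistic Boolean network (PBN) is updated by one of
#' several Boolean functions, each selected with a given probability.
#' A function is specified either by an explicit truth table or by a named
#' logic gate over its input genes.
#'
#' @param inputs Character vector of input gene names, in order. The truth
#'   table rows enumerate the inputs in binary with the first-listed input
#'   varying slowest (for inputs `c("a","b")` the rows are ab = 00,01,10,11).
#' @param table Integer/numeric vector of 0/1 of length `2^length(inputs)`:
#'   the output column of the truth table. Exactly one of `table` and
#'   `gate` must be given.
#' @param gate Name of a logic gate (see [gate_names()]); `BUFFER` and `NOT`
#'   take one input, all other gates take two.
#' @param prob Selection probability of this function (the \eqn{c_j^i} of
#'   the PBN); the probabilities of all functions of a gene must sum to 1.
#' @return An object of class `pbn_function`.
#' @examples
#' pbn_function("p53", gate = "NOT", prob = 1)
#' pbn_function(c("p53", "Mdm2"), table = c(1, 1, 0, 0), prob = 0.5)
#' @export
pbn_function <- function(inputs, table = NULL, gate = NULL, prob) {
  if (!is.character(inputs) || length(inputs) < 1L)
    stop("`inputs` must be a non-empty character vector of gene names")
  if (is.null(table) == is.null(gate))
    stop("exactly one of `table` and `gate` must be supplied")
  if (!is.null(gate)) {
    gate <- match.arg(gate, names(.gate_tables))
    arity <- if (gate %in% c("BUFFER", "NOT")) 1L else 2L
    if (length(inputs) != arity)
      stop(sprintf("gate %s takes %d input(s), got %d",
                   gate, arity, length(inputs)))
    table <- .gate_tables[[gate]]
  } else {
    table <- as.integer(table)
    if (length(table) != 2L^length(inputs))
      stop(sprintf("truth table must have length 2^%d = %d, got %d",
                   length(inputs), 2L^length(inputs), length(table)))
    if (!all(table %in% c(0L, 1L)))
      stop("truth table entries must be 0 or 1")
  }
  if (!is.numeric(prob) || length(prob) != 1L || prob < 0 || prob > 1)
    stop("`prob` must be a single probability in [0, 1]")
  structure(list(inputs = inputs, table = as.integer(table),
                 gate = gate, prob = as.numeric(prob)),
            class = "pbn_function")
}

#' Construct a probabilistic Boolean network model
#'
#' @param genes Character vector of gene names; the order fixes the bit
#'   order of network states.
#' @param functions Named list (one element per gene, in any order, names
#'   matching `genes`) of lists of [pbn_function()] objects. Per gene the
#'   selection probabilities must sum to 1 within `1e-9`; inputs failing
#'   this are rejected, not renormalized.
#' @param perturbation Random gene perturbation probability `p` in `[0, 1)`:
#'   at each transition every gene independently flips with probability `p`,
#'   and when at least one gene flips the flip replaces the Boolean update.
#' @param periods Optional named/ordered integer vector of per-gene updating
#'   periods for deterministic-asynchronous (DA-PBN) semantics; gene `i`
#'   updates at times that are multiples of its period.
#' @return An object of class `pbn` with fields `genes`, `functions`,
#'   `perturbation`, `periods`.
#' @seealso [fixture_p53_mdm2()], [generate_random_pbn()],
#'   [transition_matrix_exact()]
#' @export
pbn_model <- function(genes, functions, perturbation = 0, periods = NULL) {
  if (!is.character(genes) || length(genes) < 1L || anyDuplicated(genes))
    stop("`genes` must be a character vector of unique gene names")
  if (!is.list(functions) || length(functions) != length(genes))
    stop("`functions` must be a list with one element per gene")
  if (is.null(names(functions))) {
    names(functions) <- genes
  } else if (!setequal(names(functions), genes)) {
    stop("names of `functions` must match `genes`")
  }
  functions <- functions[genes]
  for (g in genes) {
    fs <- functions[[g]]
    if (!is.list(fs) || length(fs) < 1L)
      stop(sprintf("gene %s needs at least one predictor function", g))
    for (fn in fs) {
      if (!inherits(fn, "pbn_function"))
        stop(sprintf("functions of gene %s must be pbn_function objects", g))
      missing <- setdiff(fn$inputs, genes)
      if (length(missing))
        stop(sprintf("gene %s: unknown input gene(s): %s",
                     g, paste(missing, collapse = ", ")))
    }
    csum <- sum(vapply(fs, `[[`, numeric(1), "prob"))
    if (abs(csum - 1) > 1e-9)
      stop(sprintf(
        "selection probabilities of gene %s sum to %.12g, not 1", g, csum))
  }
  if (!is.numeric(perturbation) || length(perturbation) != 1L ||
      perturbation < 0 || perturbation >= 1)
    stop("`perturbation` must be a probability in [0, 1)")
  if (!is.null(periods)) {
    periods <- as.integer(periods)
    if (length(periods) != length(genes) || any(periods < 1L) ||
        anyNA(periods))
      stop("`periods` must give a positive integer per gene")
    names(periods) <- genes
  }
  structure(list(genes = genes, functions = functions,
                 perturbation = as.numeric(perturbation), periods = periods),
            class = "pbn")
}

#' @export
print.pbn <- function(x, ...) {
  l <- vapply(x$functions, length, integer(1))
  cat(sprintf("Probabilistic Boolean network: %d gene(s), N = %d constituent BN(s)\n",
              length(x$genes), prod(l)))
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  cat("  functions per gene:", paste(l, collapse = ", "), "\n")
  if (x$perturbation > 0)
    cat(sprintf("  perturbation probability: %g\n", x$perturbation))
  if (!is.null(x$periods))
    cat("  updating periods:", paste(x$periods, collapse = ", "), "\n")
  invisible(x)
}

#' Number of genes / constituent Boolean networks of a PBN
#'
#' `n_genes()` returns the number of genes `n`; `n_networks()` returns
#' `N = prod(l(i))`, the number of constituent Boolean networks.
#' @param model A [pbn_model()] object.
#' @return An integer (a double for `n_networks`, which can be large).
#' @export
n_genes <- function(model) length(model$genes)

#' @rdname n_genes
#' @export
n_networks <- function(model)
  prod(vapply(model$functions, length, integer(1)))

## Per-gene function counts l(i)
.l_counts <- function(model) vapply(model$functions, length, integer(1))

## Evaluate one pbn_function on a state bit vector (bits ordered as genes)
.eval_function <- function(fn, bits, genes) {
  pos <- match(fn$inputs, genes)
  k <- length(pos)
  idx <- sum(bits[pos] * 2L^((k - 1L):0L)) + 1L
  fn$table[[idx]]
}

#' Selection probability of one constituent Boolean network
#'
#' The probability that a particular constituent Boolean network of an
#' independent PBN is selected is the product over genes of the selection
#' probabilities of the chosen functions,
#' \eqn{P_j = \prod_i c_{j(i)}^i}.
#'
#' @param model A [pbn_model()] object.
#' @param choice Integer vector of length `n_genes(model)`: for each gene
#'   the 1-based index of the chosen function.
#' @return A single probability.
#' @export
bn_selection_probability <- function(model, choice) {
  l <- .l_counts(model)
  choice <- as.integer(choice)
  if (length(choice) != length(l) || any(choice < 1L) || any(choice > l))
    stop("invalid choice vector: indices must lie in [1, l(i)] per gene")
  prod(mapply(function(fs, j) fs[[j]]$prob, model$functions, choice))
}

#' Apply one constituent Boolean network to a state
#'
#' Deterministically computes the synchronous next state when, for every
#' gene, the function indexed by `choice` is applied to the current state.
#'
#' @inheritParams bn_selection_probability
#' @param state Integer 0/1 vector of gene values, ordered as
#'   `model$genes`.
#' @return Integer 0/1 vector: the next state.
#' @export
evaluate_bn <- function(model, choice, state) {
  l <- .l_counts(model)
  choice <- as.integer(choice)
  if (length(choice) != length(l) || any(choice < 1L) || any(choice > l))
    stop("invalid choice vector: indices must lie in [1, l(i)] per gene")
  state <- as.integer(state)
  if (length(state) != length(model$genes) || !all(state %in% c(0L, 1L)))
    stop("`state` must be a 0/1 vector over the model's genes")
  vapply(seq_along(model$genes), function(i) {
    .eval_function(model$functions[[i]][[choice[i]]], state, model$genes)
  }, integer(1))
}
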
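#' State index codecs
#'
#' Two index conventions for the `2^n` network states are used in the
#' literature and both are supported, with every matrix and distribution in
#' this package carrying an explicit convention tag:
#'
#' * `"matrix"`: the first-listed gene is the most significant bit and
#'   indices are 0-based, so the rows of a 2-gene transition matrix are
#'   ordered 00, 01, 10, 11. This is the package-internal convention.
#' * `"eq10"`: gene `i` contributes `g(i) * 2^(i-1)` (first gene = least
#'   significant bit) and indices are 1-based,
#'   \eqn{k = \sum_i g_i 2^{i-1} + 1}. This is the coding used for the
#'   T-cell network state numbers (e.g. state 1730).
#'
#' @param state Integer 0/1 vector of gene values (for `encode_state`).
#' @param index State index in the chosen convention (for `decode_state`).
#' @param n Number of genes (for `decode_state` and `state_labels`).
#' @param convention `"matrix"` or `"eq10"`.
#' @return `encode_state()` returns an integer index; `decode_state()`
#'   returns an integer 0/1 vector; `state_labels()` returns the binary
#'   string labels of all `2^n` states in `"matrix"` row order.
#' @examples
#' encode_state(c(0, 1), "matrix")  # 1
#' encode_state(c(0, 1), "eq10")    # 3
#' decode_state(1730, 12, "eq10")
#' @export
encode_state <- function(state, convention = c("matrix", "eq10")) {
  convention <- match.arg(convention)
  state <- as.integer(state)
  if (!all(state %in% c(0L, 1L))) stop("`state` must be a 0/1 vector")
  n <- length(state)
  if (convention == "matrix") {
    sum(state * 2^((n - 1L):0L))
  } else {
    sum(state * 2^(0L:(n - 1L))) + 1L
  }
}

#' @rdname encode_state
#' @export
decode_state <- function(index, n, convention = c("matrix", "eq10")) {
  convention <- match.arg(convention)
  index <- as.numeric(index)
  first <- if (convention == "matrix") 0 else 1
  if (length(index) != 1L || index < first || index >= first + 2^n)
    stop(sprintf("state index out of range [%d, %d]", first,
                 first + 2^n - 1))
  v <- index - first
  bits <- (v %/% 2^(0:(n - 1L))) %% 2
  if (convention == "matrix") bits <- rev(bits)
  as.integer(bits)
}

#' @rdname encode_state
#' @export
state_labels <- function(n, convention = c("matrix", "eq10")) {
  convention <- match.arg(convention)
  vapply(0:(2^n - 1), function(s) {
    paste(decode_state(s, n, "matrix"), collapse = "")
  }, character(1))
}

#' Convert a state index between conventions
#'
#' @param index A state index in the `from` convention.
#' @param n Number of genes.
#' @param from,to Index conventions (see [encode_state()]).
#' @return The index in the `to` convention.
#' @export
convert_state_index <- function(index, n, from = "matrix", to = "eq10") {
  encode_state(decode_state(index, n, from), to)
}

## All 2^n states as a 2^n x n 0/1 matrix, rows in "matrix" order.
.state_bit_matrix <- function(n) {
  m <- matrix(0L, 2L^n, n)
  for (i in seq_len(n)) {
    ## gene i is bit (n - i) of the 0-based row index
    m[, i] <- as.integer((0:(2^n - 1)) %/% 2^(n - i)) %% 2L
  }
  m
}

## Tag a matrix/vector with its state-index convention
.tag_convention <- function(x, convention = "matrix") {
  attr(x, "convention") <- convention
  x
}

## Hamming distances between all pairs of states, 2^n x 2^n
.hamming_matrix <- function(n) {
  b <- .state_bit_matrix(n)
  h <- b %*% t(1 - b) + (1 - b) %*% t(b)
  storage.mode(h) <- "integer"
  h
}

.check_transition_matrix <- function(A, tol = 1e-9) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("a transition matrix must be square")
  if (any(A < -tol) || any(A > 1 + tol))
    stop("transition matrix entries must lie in [0, 1]")
  rs <- rowSums(A)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("transition matrix rows must sum to 1 (max deviation %.3g)",
                 max(abs(rs - 1))))
  invisible(A)
}
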
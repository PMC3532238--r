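#' Generate a fixed-count probability-encoding bitstream
#'
#' A probability is encoded as the proportion of 1's in a binary sequence.
#' Streams are *non-Bernoulli*: the number of 1's is fixed at
#' `round(p * L)` (ties to even) and their positions are a uniform random
#' permutation, which removes the sampling variance of the encoded value
#' itself and reduces the variance of downstream gate outputs relative to
#' i.i.d. Bernoulli sampling.
#'
#' @param p Probability in `[0, 1]`.
#' @param L Sequence length (`>= 1`).
#' @return An integer 0/1 vector of class `bitstream` with attribute
#'   `nominal_probability = p`. A warning is emitted when `p > 0` but
#'   `round(p * L) == 0`, i.e. `p` is not representable at this length.
#' @examples
#' s <- make_bitstream(0.4, 10)
#' sum(s)                  # exactly 4
#' decode_probability(s)   # 0.4
#' @export
make_bitstream <- function(p, L) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("`p` must be a probability in [0, 1]")
  if (!is.numeric(L) || length(L) != 1L || L < 1)
    stop("`L` must be a positive sequence length")
  L <- as.integer(L)
  k <- as.integer(round(p * L))
  if (k == 0L && p > 0)
    warning(sprintf(
      "p = %g is not representable at L = %d (round(p*L) = 0); use L >= %g",
      p, L, ceiling(1 / (2 * p))))
  bits <- integer(L)
  if (k > 0L) bits[sample.int(L, k)] <- 1L
  structure(bits, class = "bitstream", nominal_probability = p)
}

.as_bits <- function(x) {
  bits <- as.integer(unclass(x))
  if (!all(bits %in% c(0L, 1L))) stop("bitstreams must contain only 0/1")
  bits
}

.wrap_bits <- function(bits) structure(bits, class = "bitstream")

.check_lengths <- function(...) {
  lens <- vapply(list(...), length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("bitstream length mismatch: ", paste(lens, collapse = " vs "))
  invisible(lens[1L])
}

#' Stochastic logic gates on bitstreams
#'
#' Position-wise Boolean logic on equal-length bitstreams. For independent
#' input streams encoding probabilities `p_a`, `p_b`, the decoded outputs
#' approximate the arithmetic identities `1 - p` (NOT), `p_a p_b` (AND),
#' `p_a + p_b - p_a p_b` (OR) and `p_a(1-p_b) + p_b(1-p_a)` (XOR). Shared
#' (fanned-out) streams remain correlated: `gate_and(s, s)` returns `s`
#' itself, not an encoding of `p^2` — preserving such correlations is the
#' point of stochastic logic.
#'
#' @param a,b Bitstreams of equal length.
#' @return A `bitstream` of the same length.
#' @export
gate_not <- function(a) .wrap_bits(1L - .as_bits(a))

#' @rdname gate_not
#' @export
gate_buffer <- function(a) .wrap_bits(.as_bits(a))

#' @rdname gate_not
#' @export
gate_and <- function(a, b) {
  a <- .as_bits(a); b <- .as_bits(b); .check_lengths(a, b)
  .wrap_bits(a * b)
}

#' @rdname gate_not
#' @export
gate_nand <- function(a, b) gate_not(gate_and(a, b))

#' @rdname gate_not
#' @export
gate_or <- function(a, b) {
  a <- .as_bits(a); b <- .as_bits(b); .check_lengths(a, b)
  .wrap_bits(as.integer(a | b))
}

#' @rdname gate_not
#' @export
gate_nor <- function(a, b) gate_not(gate_or(a, b))

#' @rdname gate_not
#' @export
gate_xor <- function(a, b) {
  a <- .as_bits(a); b <- .as_bits(b); .check_lengths(a, b)
  .wrap_bits(bitwXor(a, b))
}

#' @rdname gate_not
#' @export
gate_xnor <- function(a, b) gate_not(gate_xor(a, b))

## Largest-remainder apportionment of probs * L into integer counts
.apportion_counts <- function(probs, L) {
  x <- probs * L
  counts <- floor(x)
  short <- L - sum(counts)
  if (short > 0) {
    rem <- x - counts
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

#' Generate a multiplexer selector stream
#'
#' Encodes a discrete distribution over `K` choices as a length-`L`
#' sequence of values in `0:(K-1)`, with per-value counts fixed by
#' largest-remainder apportionment of `probs * L` and positions uniformly
#' permuted. Used as the control sequence of a stochastic multiplexer:
#' for the p53-Mdm2 selection probabilities (0.5, 0.4, 0.09, 0.01) and
#' `L = 10000` the counts are exactly (5000, 4000, 900, 100).
#'
#' @param probs Numeric vector of `K` selection probabilities summing to 1
#'   within `1e-9`.
#' @param L Sequence length.
#' @return An integer vector of class `selector_stream` with attributes
#'   `target_probabilities` and `counts`.
#' @export
make_selector_stream <- function(probs, L) {
  if (!is.numeric(probs) || any(probs < 0))
    stop("`probs` must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9)
    stop(sprintf("`probs` must sum to 1 (got %.12g)", sum(probs)))
  if (!is.numeric(L) || length(L) != 1L || L < 1)
    stop("`L` must be a positive sequence length")
  L <- as.integer(L)
  counts <- .apportion_counts(probs, L)
  values <- rep.int(seq_along(probs) - 1L, counts)
  values <- values[sample.int(L)]
  structure(values, class = "selector_stream",
            target_probabilities = probs, counts = counts)
}

#' Express a selector stream as binary control bitstreams
#'
#' A `K`-way stochastic multiplexer is controlled by
#' `m = ceiling(log2(K))` binary sequences; control bit `j` of position
#' `t` is bit `j` of the selector value at `t` (bit 1 = most significant).
#'
#' @param selector A [make_selector_stream()] object.
#' @param K Number of choices; defaults to the length of the stored target
#'   probabilities.
#' @return A list of `m` bitstreams, most significant first.
#' @export
selector_control_bits <- function(selector,
                                  K = length(attr(selector,
                                                  "target_probabilities"))) {
  m <- max(1L, ceiling(log2(K)))
  v <- as.integer(unclass(selector))
  lapply(seq_len(m), function(j) {
    .wrap_bits(as.integer(v %/% 2^(m - j)) %% 2L)
  })
}

#' Stochastic multiplexer
#'
#' Position-wise pass-through: the output bit at position `t` is the bit of
#' input stream `selector[t] + 1` at position `t`. For independent inputs
#' the decoded output approximates
#' \eqn{\sum_k P(\mathrm{sel}=k)\, p_k}.
#'
#' @param inputs List of `K` bitstreams of equal length.
#' @param selector A selector stream (values in `0:(K-1)`) of the same
#'   length.
#' @return A `bitstream`.
#' @export
mux <- function(inputs, selector) {
  K <- length(inputs)
  mats <- lapply(inputs, .as_bits)
  sel <- as.integer(unclass(selector))
  do.call(.check_lengths, c(mats, list(sel)))
  if (any(sel < 0L) || any(sel >= K))
    stop(sprintf("selector values must lie in [0, %d)", K))
  M <- do.call(cbind, mats)
  .wrap_bits(M[cbind(seq_along(sel), sel + 1L)])
}

#' Decode the probability encoded in a bitstream
#'
#' @param stream A bitstream.
#' @return The fraction of 1's, `sum(bits) / L`.
#' @export
decode_probability <- function(stream) {
  bits <- .as_bits(stream)
  if (!length(bits)) stop("empty bitstream")
  sum(bits) / length(bits)
}

#' Decode joint state frequencies from per-gene bitstreams
#'
#' Interprets position `t` of `n` parallel bitstreams as one `n`-bit
#' network state and tabulates the relative frequency of each of the `2^n`
#' states (the statistics read off an SBN's output sequences).
#'
#' @param gene_streams A list of `n` bitstreams of equal length, or an
#'   `L x n` 0/1 matrix with one column per gene.
#' @return A numeric vector of length `2^n` summing to 1, with binary
#'   state labels, in the `"matrix"` index convention (first gene = most
#'   significant bit).
#' @export
decode_state_frequencies <- function(gene_streams) {
  if (is.list(gene_streams)) {
    mats <- lapply(gene_streams, .as_bits)
    do.call(.check_lengths, mats)
    B <- do.call(cbind, mats)
  } else {
    B <- gene_streams
    storage.mode(B) <- "integer"
  }
  n <- ncol(B)
  L <- nrow(B)
  idx <- as.integer(B %*% 2^((n - 1L):0L))
  freq <- tabulate(idx + 1L, nbins = 2L^n) / L
  names(freq) <- state_labels(n)
  .tag_convention(freq)
}
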
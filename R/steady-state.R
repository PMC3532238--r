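#' Convergence settings for steady-state estimation
#'
#' @param threshold Norm-infinity threshold on the change of the decoded
#'   state distribution between consecutive frames (or between frames one
#'   cycle apart).
#' @param max_frames Maximum number of time frames before giving up.
#' @param cycle_window Largest cycle period searched for.
#' @param L Sequence length used by the bitstream path. A warning (not an
#'   error) is emitted when `L < 100 / threshold`, i.e. when the stream
#'   resolution is less than two orders of magnitude below the threshold
#'   and convergence may be dominated by stochastic fluctuation.
#' @return A list of class `convergence_config`.
#' @export
convergence_config <- function(threshold = 1e-3, max_frames = 200L,
                               cycle_window = 10L, L = 1e5) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("`threshold` must be positive")
  if (max_frames < 1L || cycle_window < 1L || L < 1)
    stop("`max_frames`, `cycle_window` and `L` must be positive")
  if (L < 100 / threshold)
    warning(sprintf(
      "L = %g gives a resolution coarser than threshold/100; use L >= %g",
      L, 100 / threshold))
  structure(list(threshold = threshold, max_frames = as.integer(max_frames),
                 cycle_window = as.integer(cycle_window), L = as.integer(L)),
            class = "convergence_config")
}

#' Iterate a state distribution through a transition matrix
#'
#' Computes the distribution after `t` synchronous transitions,
#' \eqn{d_t = d_0 A^t} (left multiplication).
#'
#' @param A A row-stochastic transition matrix.
#' @param I0 Initial distribution over the `2^n` states.
#' @param t Number of transitions (`>= 0`).
#' @return The distribution after `t` steps.
#' @export
iterate_distribution <- function(A, I0, t) {
  .check_transition_matrix(A)
  d <- as.numeric(I0)
  if (length(d) != nrow(A)) stop("`I0` length must match the matrix order")
  if (abs(sum(d) - 1) > 1e-9 || any(d < 0))
    stop("`I0` must be a probability distribution")
  for (i in seq_len(t)) d <- as.numeric(d %*% A)
  names(d) <- rownames(A)
  .tag_convention(d)
}

#' Stationary distribution of a transition matrix
#'
#' Dominant left eigenvector of `A` (eigenvalue 1), normalized to sum 1.
#' For an ergodic chain (e.g. any PBN with perturbation `p > 0`) this is
#' the unique steady-state distribution.
#'
#' @param A A row-stochastic transition matrix.
#' @return A probability vector over states.
#' @export
stationary_distribution <- function(A) {
  .check_transition_matrix(A)
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-8))
    stop("dominant eigenvector is not a distribution; chain may be reducible")
  v[v < 0] <- 0
  names(v) <- rownames(A)
  .tag_convention(v / sum(v))
}

## Cycle detection shared by the analytic and bitstream paths.
## traj: frames x states matrix of distributions (row f = frame f).
## Returns the smallest lag k <= cycle_window such that the norm-inf
## difference at lag k is below threshold at the last two frames, or NULL.
.detect_cycle <- function(traj, cycle_window, threshold) {
  t <- nrow(traj)
  for (k in seq_len(min(cycle_window, t - 2L))) {
    d1 <- max(abs(traj[t, ] - traj[t - k, ]))
    d2 <- max(abs(traj[t - 1L, ] - traj[t - 1L - k, ]))
    if (d1 < threshold && d2 < threshold) return(k)
  }
  NULL
}

#' Detect attractor cycles from matrix iteration or a trajectory
#'
#' Iterates the distribution (or scans a supplied trajectory of
#' distributions) and finds the smallest period `k <= cycle_window` at
#' which the distribution repeats within `threshold` in norm-infinity on
#' two consecutive frames; the first detection wins. An ergodic
#' (perturbed) chain yields period 1; a periodic orbit yields its period;
#' a decaying oscillation is reported with the period of its transient
#' argmax cycle. The states reported are the most probable state of each
#' phase of the detected cycle.
#'
#' @param x Either a square row-stochastic transition matrix (iterated
#'   from `init`) or a `frames x 2^n` trajectory matrix of distributions.
#' @param init Initial distribution (matrix input only); a single state
#'   index (0-based, `"matrix"` convention) is also accepted and taken as
#'   a one-hot distribution. Defaults to uniform.
#' @param threshold Norm-infinity tolerance for cycle detection.
#' @param cycle_window Largest period searched for.
#' @param max_iter Maximum iterations (matrix input only).
#' @param burn_in Frames discarded before detection starts.
#' @return A list of class `attractor_report` with elements `converged`,
#'   `period`, `states` (0-based indices of the top state per phase, in
#'   trajectory order), `labels`, `frames` and `distribution` (last
#'   frame). When no cycle is found within the window a non-converged
#'   report is returned, not an error.
#' @export
detect_attractors <- function(x, init = NULL, threshold = 1e-6,
                              cycle_window = 10L, max_iter = 1000L,
                              burn_in = 5L) {
  if (is.matrix(x) && nrow(x) == ncol(x) &&
      all(abs(rowSums(x) - 1) < 1e-6)) {
    A <- x
    M <- nrow(A)
    n <- round(log2(M))
    if (is.null(init)) init <- rep(1 / M, M)
    if (length(init) == 1L) {
      d0 <- numeric(M); d0[as.integer(init) + 1L] <- 1; init <- d0
    }
    d <- as.numeric(init)
    traj <- matrix(d, 1L, M)
    period <- NULL
    for (t in seq_len(max_iter)) {
      d <- as.numeric(d %*% A)
      traj <- rbind(traj, d)
      if (t > burn_in) {
        period <- .detect_cycle(traj, cycle_window, threshold)
        if (!is.null(period)) break
      }
    }
  } else {
    traj <- x
    M <- ncol(traj)
    n <- round(log2(M))
    period <- NULL
    for (t in (burn_in + 2L):nrow(traj)) {
      period <- .detect_cycle(traj[seq_len(t), , drop = FALSE],
                              cycle_window, threshold)
      if (!is.null(period)) { traj <- traj[seq_len(t), , drop = FALSE]; break }
    }
  }
  frames <- nrow(traj) - 1L
  if (is.null(period)) {
    return(structure(list(converged = FALSE, period = NA_integer_,
                          states = integer(0), labels = character(0),
                          frames = frames,
                          distribution = .tag_convention(traj[nrow(traj), ])),
                     class = "attractor_report"))
  }
  t <- nrow(traj)
  phases <- traj[(t - period + 1L):t, , drop = FALSE]
  states <- apply(phases, 1L, which.max) - 1L
  structure(list(converged = TRUE, period = period, states = states,
                 labels = state_labels(n)[states + 1L], frames = frames,
                 distribution = .tag_convention(traj[t, ])),
            class = "attractor_report")
}

#' @export
print.attractor_report <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("No cycle detected within the window (%d frames run)\n",
                x$frames))
  } else if (x$period == 1L) {
    cat(sprintf("Converged to a stationary distribution after %d frames; ",
                x$frames))
    cat(sprintf("top state: %s\n", x$labels[1L]))
  } else {
    cat(sprintf("Cycle of period %d after %d frames; phase top states: %s\n",
                x$period, x$frames, paste(x$labels, collapse = " -> ")))
  }
  invisible(x)
}

#' Steady-state estimation by time-frame expansion of an SBN
#'
#' Unrolls the temporal iteration of the SBN into a chain of identical
#' copies: the state bitstreams produced by frame `t` feed frame `t + 1`,
#' with fresh selector and perturbation streams drawn per frame. After
#' each frame the state distribution is decoded; the run stops when the
#' norm-infinity change between consecutive frames falls below the
#' threshold (ergodic, perturbed case) or when a distribution cycle of
#' period `<= cycle_window` is detected (unperturbed, periodic case).
#'
#' @param sbn An `sbn` object.
#' @param initial Either an integer 0/1 state vector of length `n`, or a
#'   probability distribution of length `2^n` (encoded as a selector
#'   stream over states so within-state bit correlation is preserved).
#' @param cfg A [convergence_config()].
#' @param seed Optional integer seed.
#' @return A list of class `sbn_steady` with elements `distribution`
#'   (last decoded frame), `frames`, `converged`, `period`,
#'   `phase_distributions` (the last `period` decoded frames) and
#'   `trajectory`. If `max_frames` is exceeded a non-converged result with
#'   the same structure is returned.
#' @examples
#' sbn <- build_sbn(fixture_p53_mdm2(), perturbation = 0.01)
#' cfg <- convergence_config(threshold = 1e-2, L = 1e4)
#' time_frame_expansion(sbn, c(0, 0), cfg, seed = 1)
#' @export
time_frame_expansion <- function(sbn, initial, cfg = convergence_config(),
                                 seed = NULL) {
  stopifnot(inherits(sbn, "sbn"), inherits(cfg, "convergence_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- n_genes(sbn$model)
  L <- cfg$L
  if (length(initial) == n && all(initial %in% c(0, 1))) {
    B <- .state_to_stream_matrix(as.integer(initial), L)
  } else if (length(initial) == 2^n) {
    if (abs(sum(initial) - 1) > 1e-9 || any(initial < 0))
      stop("`initial` distribution must be non-negative and sum to 1")
    sel <- make_selector_stream(as.numeric(initial), L)
    B <- .state_bit_matrix(n)[as.integer(sel) + 1L, , drop = FALSE]
  } else {
    stop("`initial` must be a 0/1 state of length n or a distribution ",
         "of length 2^n")
  }
  traj <- matrix(decode_state_frequencies(B), 1L, 2L^n)
  period <- NULL
  for (t in seq_len(cfg$max_frames)) {
    B <- .sbn_step(sbn, B)
    traj <- rbind(traj, decode_state_frequencies(B))
    if (t >= 2L) {
      period <- .detect_cycle(traj, cfg$cycle_window, cfg$threshold)
      if (!is.null(period)) break
    }
  }
  t <- nrow(traj)
  converged <- !is.null(period)
  if (!converged) period <- NA_integer_
  phases <- if (converged)
    traj[(t - period + 1L):t, , drop = FALSE] else NULL
  d <- traj[t, ]
  names(d) <- state_labels(n)
  structure(list(distribution = .tag_convention(d), frames = t - 1L,
                 converged = converged, period = period,
                 phase_distributions = phases, trajectory = traj,
                 L = L, threshold = cfg$threshold),
            class = "sbn_steady")
}

#' @export
print.sbn_steady <- function(x, ...) {
  status <- if (!x$converged) "did not converge"
    else if (x$period == 1L) "converged"
    else sprintf("cycle of period %d detected", x$period)
  cat(sprintf(
    "Time-frame expansion: %s after %d frame(s) (L = %d, threshold = %g)\n",
    status, x$frames, x$L, x$threshold))
  top <- order(x$distribution, decreasing = TRUE)[1:min(3, length(x$distribution))]
  cat("  top states:",
      paste(sprintf("%s (%.4f)", names(x$distribution)[top],
                    x$distribution[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Report pseudo-attractors of a perturbed steady state
#'
#' Pseudo-attractors are states that carry high stationary probability
#' under random gene perturbation but are not attractors of the
#' unperturbed dynamics. Each state with probability at least `min_prob`
#' that is not in `attractors` is annotated with its nearest attractor(s)
#' by Hamming distance and with the genes in which it differs.
#'
#' @param dist Steady-state distribution over `2^n` states (`"matrix"`
#'   index convention).
#' @param attractors Integer vector of attractor state indices, 0-based in
#'   the `"matrix"` convention (use [convert_state_index()] for
#'   LSB-first 1-based state numbers).
#' @param min_prob Minimum reported probability.
#' @param genes Optional character vector of gene names; defaults to
#'   `g(1)...g(n)`.
#' @return A data frame with columns `state` (0-based index), `label`,
#'   `probability`, `nearest_attractor` (label(s), ties joined with
#'   `" | "`), `hamming` and `genes_differing`, ordered by decreasing
#'   probability. Attractor states themselves are excluded.
#' @export
pseudo_attractor_report <- function(dist, attractors, min_prob = 0.01,
                                    genes = NULL) {
  M <- length(dist)
  n <- round(log2(M))
  if (2^n != M) stop("`dist` length must be a power of two")
  if (abs(sum(dist) - 1) > 1e-6) stop("`dist` must sum to 1")
  if (is.null(genes)) genes <- sprintf("g(%d)", seq_len(n))
  attractors <- as.integer(attractors)
  if (any(attractors < 0L) || any(attractors >= M))
    stop("attractor indices out of range")
  bits <- .state_bit_matrix(n)
  labels <- state_labels(n)
  cand <- setdiff(which(dist >= min_prob) - 1L, attractors)
  cand <- cand[order(dist[cand + 1L], decreasing = TRUE)]
  rows <- lapply(cand, function(s) {
    h <- colSums(abs(t(bits[attractors + 1L, , drop = FALSE]) -
                       bits[s + 1L, ]))
    nearest <- which(h == min(h))
    diff_genes <- vapply(nearest, function(a) {
      paste(genes[bits[attractors[a] + 1L, ] != bits[s + 1L, ]],
            collapse = ", ")
    }, character(1))
    data.frame(state = s, label = labels[s + 1L],
               probability = dist[s + 1L],
               nearest_attractor = paste(labels[attractors[nearest] + 1L],
                                         collapse = " | "),
               hamming = min(h),
               genes_differing = paste(unique(diff_genes), collapse = " | "),
               row.names = NULL)
  })
  if (!length(rows))
    return(data.frame(state = integer(0), label = character(0),
                      probability = numeric(0),
                      nearest_attractor = character(0),
                      hamming = integer(0), genes_differing = character(0)))
  do.call(rbind, rows)
}
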
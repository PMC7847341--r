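#' Construct a Hopfield network
#'
#' A single-layer recurrent associative memory over bipolar states
#' \eqn{\delta \in \{-1,+1\}^N}. Weights must be symmetric; the binary mode
#' additionally requires a zero diagonal (no self-connection), while the
#' continuous mode permits a nonnegative diagonal (the Lyapunov guarantee of
#' [run_async()] holds for symmetric weights with nonnegative diagonal).
#'
#' @param weights N x N symmetric numeric matrix.
#' @param biases length-N numeric vector of node biases (default 0).
#' @param mode `"binary"` (default) or `"continuous"`.
#' @param sigmoid_shift horizontal shift of the continuous-mode sigmoid.
#' @return object of class `hopfield_net`.
#' @export
hopfield_net <- function(weights, biases = rep(0, nrow(weights)),
                         mode = c("binary", "continuous"),
                         sigmoid_shift = 0) {
  mode <- match.arg(mode)
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    stop("`weights` must be a square matrix", call. = FALSE)
  }
  if (max(abs(weights - t(weights))) > 1e-8) {
    stop("`weights` must be symmetric", call. = FALSE)
  }
  if (mode == "binary" && any(abs(diag(weights)) > 1e-12)) {
    stop("binary mode requires a zero weight diagonal", call. = FALSE)
  }
  if (length(biases) != nrow(weights)) {
    stop("`biases` must have one entry per node", call. = FALSE)
  }
  structure(list(n = nrow(weights), weights = weights, biases = as.numeric(biases),
                 mode = mode, sigmoid_shift = sigmoid_shift),
            class = "hopfield_net")
}

assert_bipolar <- function(state, n, arg = "state") {
  if (length(state) != n) {
    stop(sprintf("`%s` must have length %d", arg, n), call. = FALSE)
  }
  if (!all(state == 1 | state == -1)) {
    stop(sprintf("`%s` must be bipolar (-1/+1)", arg), call. = FALSE)
  }
  invisible(state)
}

#' Propagation rule
#'
#' Net input of node `i`: \eqn{\phi_i = \sum_j \delta_j \psi_{ij} + \wp_i}.
#'
#' @param net a `hopfield_net`.
#' @param state bipolar state vector of length N.
#' @param i node index (1-based).
#' @return the scalar net input \eqn{\phi_i}.
#' @export
propagate <- function(net, state, i) {
  stopifnot(inherits(net, "hopfield_net"))
  assert_bipolar(state, net$n)
  if (!(i >= 1L && i <= net$n)) stop("node index out of range", call. = FALSE)
  sum(net$weights[i, ] * state) + net$biases[i]
}

#' Bipolar threshold activation
#'
#' Returns +1 for positive net input, -1 for negative net input, and holds the
#' current state on an exact tie (\eqn{\phi = 0}), which keeps the energy
#' trace monotone.
#'
#' @param phi net input.
#' @param current current bipolar state of the node.
#' @return -1 or +1.
#' @export
step_activation <- function(phi, current) {
  if (phi > 0) 1 else if (phi < 0) -1 else current
}

#' Continuous-mode sigmoid activation
#'
#' \eqn{f(\phi) = 1 / (1 + e^{-(\phi - \iota)})} where \eqn{\iota} is the
#' network's horizontal shift.
#'
#' @param net a `hopfield_net` in continuous mode.
#' @param phi net input (vectorized).
#' @return value in (0, 1).
#' @export
sigmoid_activation <- function(net, phi) {
  stopifnot(inherits(net, "hopfield_net"))
  if (net$mode != "continuous") {
    stop("sigmoid activation requires a continuous-mode network", call. = FALSE)
  }
  1 / (1 + exp(-(phi - net$sigmoid_shift)))
}

#' Hebbian learning
#'
#' Stores bipolar exemplar patterns by the outer-product rule
#' \eqn{\psi_{ij} = \sum_\eta \gamma_i^\eta \gamma_j^\eta} (i != j), zero
#' diagonal, zero biases. Weights are symmetric by construction.
#'
#' @param patterns matrix with one bipolar pattern per row, or a list of
#'   bipolar vectors of equal length.
#' @return a binary-mode `hopfield_net`.
#' @export
hebbian_learn <- function(patterns) {
  if (is.list(patterns)) {
    lens <- vapply(patterns, length, 1L)
    if (length(unique(lens)) != 1L) {
      stop("all patterns must have the same length", call. = FALSE)
    }
    patterns <- do.call(rbind, patterns)
  }
  if (!is.matrix(patterns) || nrow(patterns) < 1L) {
    stop("at least one pattern is required", call. = FALSE)
  }
  if (!all(patterns == 1 | patterns == -1)) {
    stop("patterns must be bipolar (-1/+1)", call. = FALSE)
  }
  w <- crossprod(patterns)
  diag(w) <- 0
  hopfield_net(w)
}

#' Lyapunov energy
#'
#' \eqn{E = -\tfrac12 \sum_i \sum_j \psi_{ij}\delta_i\delta_j -
#' \sum_i \wp_i \delta_i}. Under asynchronous threshold updates with
#' symmetric weights and nonnegative diagonal, E is non-increasing and the
#' dynamics reach a fixed point.
#'
#' @param net a `hopfield_net`.
#' @param state bipolar state vector.
#' @return scalar energy.
#' @export
hopfield_energy <- function(net, state) {
  stopifnot(inherits(net, "hopfield_net"))
  assert_bipolar(state, net$n)
  -0.5 * sum(state * (net$weights %*% state)) - sum(net$biases * state)
}

#' Asynchronous relaxation
#'
#' Repeated single-node threshold updates until a full sweep changes no state
#' or `max_sweeps` is reached. Update orders: `"sequential"` (row order),
#' `"checkerboard"` (odd-index nodes then even-index nodes, the alternating
#' parity schedule of the sign-sequencing matrix flattened to one row), and
#' `"random"` (a fresh seeded permutation each sweep).
#'
#' @param net a `hopfield_net`.
#' @param init bipolar initial state.
#' @param max_sweeps maximum number of full sweeps (default 100).
#' @param order update order.
#' @param seed RNG seed used by the `"random"` order; ignored otherwise.
#' @return list with `state`, `energy_trace` (energy after initialization and
#'   after each sweep), `converged`, `sweeps`.
#' @export
run_async <- function(net, init, max_sweeps = 100L,
                      order = c("sequential", "checkerboard", "random"),
                      seed = NULL) {
  stopifnot(inherits(net, "hopfield_net"), max_sweeps >= 1L)
  order <- match.arg(order)
  state <- as.numeric(assert_bipolar(init, net$n, "init"))
  if (!is.null(seed)) set.seed(seed)
  n <- net$n
  trace <- hopfield_energy(net, state)
  converged <- FALSE
  sweeps <- 0L
  for (s in seq_len(max_sweeps)) {
    idx <- switch(order,
      sequential   = seq_len(n),
      checkerboard = c(seq.int(1L, n, by = 2L),
                       if (n > 1L) seq.int(2L, n, by = 2L)),
      random       = sample.int(n)
    )
    changed <- FALSE
    for (i in idx) {
      phi <- sum(net$weights[i, ] * state) + net$biases[i]
      new <- step_activation(phi, state[i])
      if (new != state[i]) {
        state[i] <- new
        changed <- TRUE
      }
    }
    sweeps <- s
    trace <- c(trace, hopfield_energy(net, state))
    if (!changed) {
      converged <- TRUE
      break
    }
  }
  list(state = state, energy_trace = trace, converged = converged,
       sweeps = sweeps)
}

#' Serialize network parameters to JSON
#'
#' @param net a `hopfield_net`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "hopfield_net"))
  jsonlite::write_json(
    list(n_nodes = net$n,
         weights = net$weights,
         biases = net$biases,
         mode = net$mode,
         sigmoid_shift = net$sigmoid_shift),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read network parameters from JSON
#' @param path file written by [write_network()].
#' @return a `hopfield_net`.
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  hopfield_net(matrix(as.numeric(doc$weights), doc$n_nodes, doc$n_nodes,
                      byrow = FALSE),
               biases = as.numeric(doc$biases),
               mode = doc$mode,
               sigmoid_shift = doc$sigmoid_shift)
}
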
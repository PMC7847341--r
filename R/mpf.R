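# Minimum probability flow (MPF) estimation of bipolar Hopfield parameters.
# MPF minimizes the probability flow from the observed states to their
# single-bit-flip Hamming neighbors under the Gibbs distribution
# P(x) ~ exp(-E(x)), which avoids the partition function entirely: the
# objective only involves energy differences across one-bit flips.

assert_mpf_data <- function(data) {
  if (is.list(data)) data <- do.call(rbind, data)
  if (!is.matrix(data) || nrow(data) < 1L) {
    stop("`data` must be a nonempty matrix of bipolar rows", call. = FALSE)
  }
  if (!all(data == 1 | data == -1)) {
    stop("`data` entries must be -1/+1", call. = FALSE)
  }
  data
}

assert_theta <- function(weights, biases) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    stop("`weights` must be square", call. = FALSE)
  }
  if (max(abs(weights - t(weights))) > 1e-10 || any(abs(diag(weights)) > 1e-12)) {
    stop("`weights` must be symmetric with zero diagonal", call. = FALSE)
  }
  if (length(biases) != nrow(weights)) {
    stop("`biases` must have one entry per node", call. = FALSE)
  }
  invisible(NULL)
}

# Net inputs phi for all samples at once: rows = samples.
mpf_phi <- function(data, weights, biases) {
  data %*% weights + matrix(biases, nrow(data), length(biases), byrow = TRUE)
}

#' MPF objective
#'
#' \eqn{K(\theta) = \frac{1}{|D|}\sum_{x \in D}\sum_{x'} \exp[(E(x) -
#' E(x'))/2]} over all single-bit-flip neighbors x' of each datum, with E the
#' Hopfield energy. For a flip of bit i the exponent equals
#' \eqn{-\delta_i \phi_i}, so K depends on energy differences only (it is
#' invariant to adding a constant to E). At \eqn{\theta = 0}, K = N.
#'
#' @param data matrix of bipolar \{-1,+1\} rows (or list of vectors).
#' @param weights symmetric zero-diagonal N x N matrix.
#' @param biases length-N vector.
#' @return positive scalar.
#' @export
mpf_objective <- function(data, weights, biases = rep(0, nrow(weights))) {
  data <- assert_mpf_data(data)
  assert_theta(weights, biases)
  phi <- mpf_phi(data, weights, biases)
  mean(rowSums(exp(-data * phi)))
}

#' Analytic MPF gradient
#'
#' Exact gradient of [mpf_objective()] with the symmetry and zero-diagonal
#' constraints applied; matches central finite differences on small problems.
#'
#' @inheritParams mpf_objective
#' @return list with `weights` (symmetric, zero diagonal) and `biases`.
#' @export
mpf_gradient <- function(data, weights, biases = rep(0, nrow(weights))) {
  data <- assert_mpf_data(data)
  assert_theta(weights, biases)
  phi <- mpf_phi(data, weights, biases)
  tmat <- exp(-data * phi)          # samples x nodes
  n <- nrow(data)
  m <- crossprod(data, data * tmat) # m[a,b] = sum_x d_a d_b t_{x,b}
  gw <- -(m + t(m)) / n
  diag(gw) <- 0
  gb <- -colSums(data * tmat) / n
  list(weights = gw, biases = gb)
}

#' Fit Hopfield parameters by minimum probability flow
#'
#' Gradient descent on the MPF objective with Armijo backtracking line
#' search; the objective trace is non-increasing. Stops when the sup-norm of
#' the gradient falls below `tol` or after `max_iters` iterations.
#'
#' @param data matrix of bipolar rows.
#' @param init optional list with starting `weights` and `biases`
#'   (default: zeros).
#' @param step_size initial step for the line search.
#' @param max_iters iteration budget (default 500).
#' @param tol sup-norm gradient tolerance (default 1e-5).
#' @param fit_biases estimate biases as well as weights (default TRUE).
#' @return list with `weights`, `biases`, `k_trace`, `converged`, `iters`.
#' @export
fit_mpf <- function(data, init = NULL, step_size = 0.2, max_iters = 500L,
                    tol = 1e-5, fit_biases = TRUE) {
  data <- assert_mpf_data(data)
  nn <- ncol(data)
  w <- if (is.null(init)) matrix(0, nn, nn) else init$weights
  b <- if (is.null(init) || is.null(init$biases)) rep(0, nn) else init$biases
  assert_theta(w, b)
  k <- mpf_objective(data, w, b)
  k_trace <- k
  step <- step_size
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iters)) {
    g <- mpf_gradient(data, w, b)
    if (!fit_biases) g$biases[] <- 0
    gnorm <- max(abs(g$weights), abs(g$biases))
    if (gnorm < tol) {
      converged <- TRUE
      break
    }
    gsq <- sum(g$weights^2) + sum(g$biases^2)
    accepted <- FALSE
    st <- step
    while (st > 1e-14) {
      w2 <- w - st * g$weights
      b2 <- b - st * g$biases
      k2 <- mpf_objective(data, w2, b2)
      if (k2 <= k - 1e-4 * st * gsq) {
        accepted <- TRUE
        break
      }
      st <- st / 2
    }
    if (!accepted) break    # no descent step found at minimal step size
    w <- w2; b <- b2; k <- k2
    k_trace <- c(k_trace, k)
    step <- min(st * 2, step_size * 10)
    iters <- it
  }
  list(weights = w, biases = b, k_trace = k_trace, converged = converged,
       iters = iters)
}

#' Single-site Gibbs sampler for a bipolar Hopfield model
#'
#' Samples \eqn{P(x) \propto \exp(-E_\theta(x))} by sequential single-site
#' updates: \eqn{P(\delta_i = +1 \mid rest) = 1/(1 + e^{-2\phi_i})}. One
#' sample is recorded per full sweep after `burn_in` sweeps. Reproducible for
#' a given seed.
#'
#' @param weights symmetric zero-diagonal N x N matrix.
#' @param biases length-N vector.
#' @param n_samples number of samples to record.
#' @param burn_in discarded initial sweeps (default 100).
#' @param seed RNG seed.
#' @return `n_samples` x N matrix of bipolar states.
#' @export
gibbs_sample <- function(weights, biases = rep(0, nrow(weights)),
                         n_samples = 1000L, burn_in = 100L, seed = 1L) {
  assert_theta(weights, biases)
  nn <- nrow(weights)
  set.seed(seed)
  state <- sample(c(-1, 1), nn, replace = TRUE)
  out <- matrix(0, n_samples, nn)
  total <- burn_in + n_samples
  for (t in seq_len(total)) {
    u <- stats::runif(nn)
    for (i in seq_len(nn)) {
      phi <- sum(weights[i, ] * state) + biases[i]
      state[i] <- if (u[i] < 1 / (1 + exp(-2 * phi))) 1 else -1
    }
    if (t > burn_in) out[t - burn_in, ] <- state
  }
  out
}
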
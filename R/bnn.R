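#' Network topology for the Bayesian neural network classifier
#'
#' One hidden tanh layer, a single logistic output unit, independent biases
#' on hidden and output units.  The full-size representation of the UGT
#' panel uses 86 covering-window positions times 7 indices = 602 inputs and
#' 301 hidden units.
#'
#' @param n_in Number of inputs.
#' @param n_hidden Number of hidden units.
#' @return Object of class `bnn_topology` (`n_out` is always 1).
#' @export
bnn_topology <- function(n_in, n_hidden) {
  stopifnot(n_in >= 1, n_hidden >= 1)
  structure(list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
                 n_out = 1L),
            class = "bnn_topology")
}

#' Total parameter count of a topology
#'
#' `n_in * n_hidden` input-to-hidden weights, `n_hidden` hidden biases,
#' `n_hidden * n_out` hidden-to-output weights and `n_out` output bias; the
#' (602, 301, 1) default totals 181805.
#'
#' @param t A [bnn_topology()].
#' @return Integer parameter count.
#' @export
#' @examples
#' param_count(bnn_topology(602, 301))
param_count <- function(t) {
  stopifnot(inherits(t, "bnn_topology"))
  t$n_in * t$n_hidden + t$n_hidden + t$n_hidden * t$n_out + t$n_out
}

#' Gamma hyperprior density over a group precision
#'
#' The precision tau of a parameter group's zero-mean Gaussian priors is
#' itself given a Gamma hyperprior with shape `alpha/2` and rate
#' `alpha/(2w)`:
#' `P(tau) = (alpha/2w)^(alpha/2) / Gamma(alpha/2) * tau^(alpha/2-1) *
#'  exp(-tau * alpha / (2w))`.
#' Its mean is exactly `w` (the scale hyperparameter approximates the
#' typical precision) and its variance `2 w^2 / alpha`, so decreasing the
#' shape parameter spreads the distribution and makes the hyperprior vaguer.
#'
#' @param tau Precision value(s), positive.
#' @param alpha Shape control, positive.
#' @param w Scale control (approximate mean), positive.
#' @return Density value(s).
#' @export
gamma_hyperprior_pdf <- function(tau, alpha, w) {
  if (any(tau <= 0) || alpha <= 0 || w <= 0)
    stop("tau, alpha and w must be positive")
  stats::dgamma(tau, shape = alpha / 2, rate = alpha / (2 * w))
}

#' Draw from the Gamma hyperprior
#' @inheritParams gamma_hyperprior_pdf
#' @param n Number of draws.
#' @return Numeric vector of precisions.
#' @export
gamma_hyperprior_draw <- function(n, alpha, w) {
  stats::rgamma(n, shape = alpha / 2, rate = alpha / (2 * w))
}

#' Gibbs update of a group precision given its weights
#'
#' With zero-mean Gaussian weights of common precision tau and the Gamma
#' hyperprior above, the full conditional is conjugate:
#' `tau | w_1..w_k ~ Gamma(alpha/2 + k/2, alpha/(2w) + sum(w_i^2)/2)`.
#' An empty group returns a draw from the prior.
#'
#' @param group_weights Numeric vector of the group's current weights.
#' @inheritParams gamma_hyperprior_pdf
#' @return One precision draw.
#' @export
gibbs_update_precision <- function(group_weights, alpha, w) {
  k <- length(group_weights)
  stats::rgamma(1, shape = alpha / 2 + k / 2,
                rate = alpha / (2 * w) + sum(group_weights^2) / 2)
}

# ---------------------------------------------------------------- core -----

# parameter packing: theta = c(W1, b1, W2, b2); group index bookkeeping
bnn_groups_idx <- function(t) {
  n1 <- t$n_in * t$n_hidden
  list(W1 = seq_len(n1),
       b1 = n1 + seq_len(t$n_hidden),
       W2 = n1 + t$n_hidden + seq_len(t$n_hidden),
       b2 = n1 + 2L * t$n_hidden + 1L)
}

bnn_forward <- function(theta, t, X) {
  gi <- bnn_groups_idx(t)
  W1 <- matrix(theta[gi$W1], t$n_in, t$n_hidden)
  H <- tanh(sweep(X %*% W1, 2, theta[gi$b1], `+`))
  f <- drop(H %*% theta[gi$W2]) + theta[gi$b2]
  list(H = H, f = f)
}

# potential energy U = prior quadratic + Bernoulli cross-entropy, and grad
bnn_potential <- function(theta, t, X, y, tau) {
  gi <- bnn_groups_idx(t)
  tau_vec <- numeric(length(theta))
  for (g in names(gi)) tau_vec[gi[[g]]] <- tau[[g]]
  U <- 0.5 * sum(tau_vec * theta^2)
  grad <- tau_vec * theta
  if (length(y)) {
    fw <- bnn_forward(theta, t, X)
    p <- stats::plogis(fw$f)
    # cross-entropy via log1p for stability
    U <- U + sum(log1p(exp(-abs(fw$f))) + pmax(fw$f, 0) - y * fw$f)
    r <- p - y
    W2 <- theta[gi$W2]
    G <- (r %*% t(W2)) * (1 - fw$H^2)
    grad[gi$W1] <- grad[gi$W1] + as.vector(crossprod(X, G))
    grad[gi$b1] <- grad[gi$b1] + colSums(G)
    grad[gi$W2] <- grad[gi$W2] + drop(crossprod(fw$H, r))
    grad[gi$b2] <- grad[gi$b2] + sum(r)
  }
  list(U = U, grad = grad)
}

# one Hamiltonian Monte Carlo trajectory; returns new theta and acceptance
hmc_step <- function(theta, t, X, y, tau, step, n_leapfrog) {
  p0 <- stats::rnorm(length(theta))
  cur <- bnn_potential(theta, t, X, y, tau)
  if (n_leapfrog == 0L)  # identity proposal: always accepted
    return(list(theta = theta, accepted = TRUE, divergent = FALSE,
                dH = 0))
  th <- theta
  p <- p0 - 0.5 * step * cur$grad
  for (l in seq_len(n_leapfrog)) {
    th <- th + step * p
    pe <- bnn_potential(th, t, X, y, tau)
    if (l < n_leapfrog) p <- p - step * pe$grad
  }
  p <- p - 0.5 * step * pe$grad
  dH <- (pe$U + 0.5 * sum(p^2)) - (cur$U + 0.5 * sum(p0^2))
  if (!is.finite(dH) || dH > 1000)
    return(list(theta = theta, accepted = FALSE, divergent = TRUE,
                dH = dH))
  acc <- log(stats::runif(1)) < -dH
  list(theta = if (acc) th else theta, accepted = acc, divergent = FALSE,
       dH = dH)
}

#' Default hyperprior configuration for the four parameter groups
#'
#' Input-to-hidden weights, hidden biases and hidden-to-output weights get
#' Gamma hyperpriors with `alpha = 1`, `w = 1`; the output bias keeps a
#' fixed unit precision (sigma = 1), following the convention of always
#' fixing the output unit's prior.
#'
#' @return Named list; each element has either `alpha`/`w` or `fixed_tau`.
#' @export
bnn_default_groups <- function() {
  list(W1 = list(alpha = 1, w = 1),
       b1 = list(alpha = 1, w = 1),
       W2 = list(alpha = 1, w = 1),
       b2 = list(fixed_tau = 1))
}

#' Train a hierarchical Bayesian neural network by MCMC
#'
#' Weights and biases start at zero and carry independent zero-mean Gaussian
#' priors whose precisions are shared within four groups (input-to-hidden
#' weights, hidden biases, hidden-to-output weights, output bias).  Training
#' alternates (a) Hamiltonian Monte Carlo trajectories that update the
#' parameters under the current priors and the Bernoulli likelihood of the
#' binary labels, and (b) Gibbs draws of each group precision from its
#' conjugate Gamma conditional.  Sampling runs in two phases: a short phase
#' at fixed precisions to move near equilibrium, then the alternating phase;
#' post-burn-in samples are thinned.  A divergent trajectory (non-finite or
#' exploding energy) halves the step size with a warning.
#'
#' The convention `sigma = tau^(-1/2)` relates a group's precision to its
#' prior standard deviation.
#'
#' @param X Numeric feature matrix (rows = records), e.g. from
#'   [flatten_dataset()].  May have zero rows, in which case the posterior
#'   is the prior (useful for sampler validation).
#' @param y Logical/0-1 labels (length `nrow(X)`).
#' @param topology A [bnn_topology()] matching `ncol(X)`.
#' @param groups Hyperprior configuration as in [bnn_default_groups()].
#' @param phase1 Iterations at fixed precisions.
#' @param phase2 Alternating iterations.
#' @param step Leapfrog step size.
#' @param n_leapfrog Leapfrog steps per trajectory.
#' @param thin Keep every `thin`-th sample after discarding the first half
#'   of phase 2.
#' @param seed Optional integer seed.
#' @return Object of class `bnn_fit`: list with `samples` (each a list of
#'   `theta`, `tau`, `iter`), `topology`, `groups` and `diagnostics` (per-
#'   iteration training mean squared error, acceptance rate, step-size
#'   history, hyperparameter ranges).
#' @export
mcmc_train <- function(X, y, topology, groups = bnn_default_groups(),
                       phase1 = 100L, phase2 = 1000L, step = 0.05,
                       n_leapfrog = 10L, thin = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) && any(!y %in% c(0, 1)))
    stop("labels must be binary")
  if (length(y) != nrow(X)) stop("label / feature row mismatch")
  t <- topology
  stopifnot(inherits(t, "bnn_topology"), ncol(X) == t$n_in || !length(y))
  gi <- bnn_groups_idx(t)
  theta <- numeric(param_count(t))
  # fixed-phase precisions: the hyperprior mean w, or the fixed value
  tau <- lapply(groups, function(g)
    if (!is.null(g$fixed_tau)) g$fixed_tau else g$w)
  mse <- function(th) {
    if (!length(y)) return(NA_real_)
    mean((stats::plogis(bnn_forward(th, t, X)$f) - y)^2)
  }
  diag_mse <- numeric(0); diag_acc <- logical(0); diag_step <- numeric(0)
  samples <- list()
  total <- phase1 + phase2
  if (total == 0L)
    return(structure(list(samples = list(list(theta = theta,
                                              tau = unlist(tau),
                                              iter = 0L)),
                          topology = t, groups = groups,
                          diagnostics = list(mse = diag_mse,
                                             acceptance = diag_acc,
                                             step = diag_step)),
                     class = "bnn_fit"))
  burn <- phase1 + floor(phase2 / 2)
  for (it in seq_len(total)) {
    hs <- hmc_step(theta, t, X, y, tau, step, n_leapfrog)
    if (hs$divergent) {
      step <- step / 2
      warning("divergent trajectory at iteration ", it,
              "; halving step size to ", signif(step, 3))
    }
    theta <- hs$theta
    if (it > phase1) {  # phase 2: Gibbs precision updates
      for (g in names(groups)) {
        cfg <- groups[[g]]
        if (is.null(cfg$fixed_tau))
          tau[[g]] <- gibbs_update_precision(theta[gi[[g]]],
                                             cfg$alpha, cfg$w)
      }
    }
    diag_mse <- c(diag_mse, mse(theta))
    diag_acc <- c(diag_acc, hs$accepted)
    diag_step <- c(diag_step, step)
    if (it > burn && (it - burn) %% thin == 0L)
      samples[[length(samples) + 1L]] <-
        list(theta = theta, tau = unlist(tau), iter = it)
  }
  if (!length(samples))
    samples <- list(list(theta = theta, tau = unlist(tau), iter = total))
  tau_mat <- do.call(rbind, lapply(samples, `[[`, "tau"))
  structure(list(samples = samples, topology = t, groups = groups,
                 diagnostics = list(mse = diag_mse, acceptance = diag_acc,
                                    step = diag_step,
                                    tau_range = apply(tau_mat, 2, range))),
            class = "bnn_fit")
}

#' @export
print.bnn_fit <- function(x, ...) {
  cat("<bnn_fit> topology (", x$topology$n_in, ", ", x$topology$n_hidden,
      ", 1), ", length(x$samples), " posterior samples, acceptance ",
      round(mean(x$diagnostics$acceptance), 2), "\n", sep = "")
  invisible(x)
}

#' Posterior-mean prediction from a BNN fit
#'
#' Averages the logistic output over the posterior samples; the single
#' expectation value is thresholded at 0.5 for the binary label.
#'
#' @param fit A [mcmc_train()] result (must contain samples).
#' @param X Feature matrix of query records.
#' @return List with `probability` (posterior-mean output per row) and
#'   `label` (logical).
#' @export
bnn_predict <- function(fit, X) {
  stopifnot(inherits(fit, "bnn_fit"))
  if (!length(fit$samples)) stop("empty sample list")
  X <- as.matrix(X)
  per_sample <- vapply(fit$samples, function(s)
    stats::plogis(bnn_forward(s$theta, fit$topology, X)$f),
    numeric(nrow(X)))
  if (is.null(dim(per_sample)))
    per_sample <- matrix(per_sample, nrow = nrow(X))
  probs <- rowMeans(per_sample)
  list(probability = probs, label = probs > 0.5)
}
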
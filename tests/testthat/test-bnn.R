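test_that("parameter counts follow the closed form", {
  expect_equal(param_count(bnn_topology(602, 301)), 181805L)
  expect_equal(param_count(bnn_topology(1, 1)), 4L)
  # closed form vs structural count for assorted topologies
  for (t in list(bnn_topology(3, 5), bnn_topology(10, 2),
                 bnn_topology(7, 7))) {
    gi <- ugtregio:::bnn_groups_idx(t)
    expect_equal(param_count(t), length(unlist(gi)))
    expect_equal(sort(unlist(gi)), seq_len(param_count(t)),
                 ignore_attr = TRUE)  # groups partition the parameters
  }
})

test_that("the Gamma hyperprior has the stated normalization and moments", {
  f <- function(tau) gamma_hyperprior_pdf(tau, alpha = 4, w = 2)
  expect_equal(stats::integrate(f, 0, Inf)$value, 1, tolerance = 1e-6)
  set.seed(21)
  draws <- gamma_hyperprior_draw(1e5, alpha = 4, w = 2)
  expect_equal(mean(draws), 2, tolerance = 0.05)      # mean = w
  # decreasing alpha at fixed w spreads the distribution (var = 2w^2/a)
  v_wide <- stats::var(gamma_hyperprior_draw(1e5, alpha = 0.5, w = 2))
  expect_gt(v_wide, stats::var(draws))
  expect_equal(stats::var(draws), 2 * 2^2 / 4, tolerance = 0.1)
  expect_error(gamma_hyperprior_pdf(-1, 1, 1), "positive")
})

test_that("the Gibbs precision update matches the conjugate posterior", {
  set.seed(22)
  alpha <- 3; w <- 1.5
  weights <- rnorm(40, sd = 0.7)
  shape <- alpha / 2 + length(weights) / 2
  rate <- alpha / (2 * w) + sum(weights^2) / 2
  draws <- replicate(1e5, gibbs_update_precision(weights, alpha, w))
  expect_equal(mean(draws), shape / rate, tolerance = 0.02)
  expect_equal(stats::var(draws), shape / rate^2, tolerance = 0.05)
  # empty group: prior draw
  set.seed(23)
  prior_draws <- replicate(2e4, gibbs_update_precision(numeric(), alpha,
                                                       w))
  expect_equal(mean(prior_draws), w, tolerance = 0.1)
  # zero weights shift only the shape
  set.seed(24)
  d0 <- replicate(2e4, gibbs_update_precision(c(0, 0), alpha, w))
  expect_equal(mean(d0), (alpha / 2 + 1) / (alpha / (2 * w)),
               tolerance = 0.1)
  # scale covariance: scaling weights by c scales the data rate term by c^2
  expect_equal(alpha / (2 * w) + sum((2 * weights)^2) / 2 -
                 alpha / (2 * w),
               4 * sum(weights^2) / 2)
})

test_that("degenerate schedules return the initial zero state", {
  X <- matrix(rnorm(6), 3, 2)
  y <- c(1, 0, 1)
  fit <- mcmc_train(X, y, bnn_topology(2, 2), phase1 = 0L, phase2 = 0L)
  expect_equal(length(fit$samples), 1L)
  expect_equal(fit$samples[[1]]$theta,
               numeric(param_count(bnn_topology(2, 2))))
  # zero-leapfrog identity proposal is always accepted
  fit2 <- mcmc_train(X, y, bnn_topology(2, 2), phase1 = 5L,
                     phase2 = 5L, n_leapfrog = 0L, seed = 1)
  expect_true(all(fit2$diagnostics$acceptance))
  expect_error(mcmc_train(X, c(1, 2, 0), bnn_topology(2, 2)),
               "binary")
})

test_that("with no data the sampler reproduces the Gaussian prior", {
  # flat likelihood (empty data), fixed precisions: long-run weight
  # marginals must match the prior N(0, 1/tau)
  t <- bnn_topology(2, 2)
  groups <- list(W1 = list(fixed_tau = 4), b1 = list(fixed_tau = 4),
                 W2 = list(fixed_tau = 4), b2 = list(fixed_tau = 4))
  # an occasional divergence-triggered step halving is acceptable here
  fit <- suppressWarnings(
    mcmc_train(matrix(numeric(), 0, 2), numeric(), t,
               groups = groups, phase1 = 50L, phase2 = 4000L,
               step = 0.3, n_leapfrog = 8L, thin = 2L, seed = 31))
  th <- vapply(fit$samples, function(s) s$theta[1], 0)
  expect_gt(length(th), 500)
  # rejected proposals legitimately repeat values; the tie warning from
  # the KS approximation is expected for an MCMC chain
  ks <- suppressWarnings(stats::ks.test(th, "pnorm", 0, sd = 1 / sqrt(4)))
  expect_gt(ks$p.value, 0.01)
})

test_that("energy is approximately conserved at small step size", {
  set.seed(33)
  t <- bnn_topology(2, 3)
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0, 1), 5)
  tau <- list(W1 = 1, b1 = 1, W2 = 1, b2 = 1)
  theta <- rnorm(param_count(t), sd = 0.3)
  dHs <- replicate(50, ugtregio:::hmc_step(theta, t, X, y, tau,
                                           step = 0.005,
                                           n_leapfrog = 20)$dH)
  U0 <- ugtregio:::bnn_potential(theta, t, X, y, tau)$U
  expect_lt(stats::median(abs(dHs)) / (abs(U0) + 1), 0.01)
})

test_that("a tiny network learns linearly separable data", {
  ok <- 0
  for (s in 1:5) {
    set.seed(400 + s)
    X <- rbind(matrix(rnorm(20, -2, 0.5), 10, 2),
               matrix(rnorm(20, 2, 0.5), 10, 2))
    y <- rep(c(0, 1), each = 10)
    fit <- mcmc_train(X, y, bnn_topology(2, 3), phase1 = 50L,
                      phase2 = 300L, step = 0.05, n_leapfrog = 10L,
                      seed = s)
    pred <- bnn_predict(fit, X)
    ok <- ok + (mean(pred$label == (y == 1)) >= 0.95)
  }
  expect_gte(ok, 4)
})

test_that("posterior-mean prediction averages the sample outputs", {
  t <- bnn_topology(2, 2)
  mk <- function(theta) list(theta = theta, tau = c(1, 1, 1, 1),
                             iter = 1L)
  th1 <- rnorm(param_count(t)); th2 <- rnorm(param_count(t))
  fit <- structure(list(samples = list(mk(th1), mk(th2)), topology = t,
                        groups = bnn_default_groups()),
                   class = "bnn_fit")
  X <- matrix(c(0.3, -1, 2, 0.5), 2, 2)
  direct <- (stats::plogis(ugtregio:::bnn_forward(th1, t, X)$f) +
               stats::plogis(ugtregio:::bnn_forward(th2, t, X)$f)) / 2
  expect_equal(bnn_predict(fit, X)$probability, direct)
  # identical samples reduce to a single network
  fit1 <- structure(list(samples = list(mk(th1), mk(th1)), topology = t),
                    class = "bnn_fit")
  expect_equal(bnn_predict(fit1, X)$probability,
               stats::plogis(ugtregio:::bnn_forward(th1, t, X)$f))
  # symmetric logits average to probability one half
  gi <- ugtregio:::bnn_groups_idx(t)
  th_neg <- th1
  th_neg[gi$W2] <- -th1[gi$W2]; th_neg[gi$b2] <- -th1[gi$b2]
  fit_sym <- structure(list(samples = list(mk(th1), mk(th_neg)),
                            topology = t),
                       class = "bnn_fit")
  expect_equal(bnn_predict(fit_sym, X)$probability, c(0.5, 0.5),
               tolerance = 1e-12)
})
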
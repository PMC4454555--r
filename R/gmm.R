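#' Two-component GMM state for one frequency band
#'
#' Holds the per-band parameter set: weights (`w0`, `w1` = a priori non-burst
#' and burst probabilities), component means (dB) and variances (dB^2).
#' Component 0 models non-burst (background-noise) log power, component 1
#' models EMG-burst log power.
#'
#' @param w1 Burst-component weight in (0, 1); `w0 = 1 - w1`.
#' @param mu0,mu1 Component means in dB.
#' @param kappa0,kappa1 Component variances in dB^2 (positive).
#' @return Object of class `gmm_state`.
#' @export
gmm_state <- function(w1, mu0, mu1, kappa0, kappa1) {
  if (!(w1 > 0 && w1 < 1)) stop("`w1` must lie in (0, 1)")
  if (!(kappa0 > 0 && kappa1 > 0)) stop("variances must be positive")
  structure(list(w0 = 1 - w1, w1 = w1, mu0 = mu0, mu1 = mu1,
                 kappa0 = kappa0, kappa1 = kappa1),
            class = "gmm_state")
}

#' @export
print.gmm_state <- function(x, ...) {
  cat(sprintf(
    "<gmm_state> w = (%.3f, %.3f), mu = (%.2f, %.2f) dB, kappa = (%.2f, %.2f) dB^2\n",
    x$w0, x$w1, x$mu0, x$mu1, x$kappa0, x$kappa1))
  invisible(x)
}

#' Sequential GMM configuration
#'
#' @param alpha Forgetting factor in (0, 1]; `alpha = (L-1)/L` corresponds to
#'   an effective causal window of `L` frames (default 0.99, L = 100).
#' @param delta Minimum burst/non-burst mean gap in dB (default 3.5). Large
#'   values suppress false alarms, small values reduce missed weak bursts.
#' @param epsilon Floor on the burst weight (default 0.03), keeping the
#'   burst hypothesis reachable after long non-burst stretches.
#' @param m_init Number of frames used to initialize the model by EM
#'   (default 80).
#' @param em_tol Log-likelihood convergence tolerance for EM (default 1e-6).
#' @param em_max_iter Maximum EM iterations (default 300).
#' @return Object of class `gmm_config`.
#' @export
gmm_config <- function(alpha = 0.99, delta = 3.5, epsilon = 0.03,
                       m_init = 80, em_tol = 1e-6, em_max_iter = 300) {
  if (!(alpha > 0 && alpha <= 1)) stop("`alpha` must be in (0, 1]")
  if (!(delta > 0)) stop("`delta` must be > 0")
  if (!(epsilon > 0 && epsilon < 0.5)) stop("`epsilon` must be in (0, 0.5)")
  if (m_init < 10) stop("`m_init` must be >= 10")
  structure(list(alpha = alpha, delta = delta, epsilon = epsilon,
                 m_init = as.integer(m_init), em_tol = em_tol,
                 em_max_iter = as.integer(em_max_iter)),
            class = "gmm_config")
}

#' Gaussian component density
#'
#' @param x Log power in dB (vectorised).
#' @param mu Mean (dB).
#' @param kappa Variance (dB^2, positive).
#' @return Density value(s).
#' @export
component_density <- function(x, mu, kappa) {
  if (!(is.numeric(kappa) && all(kappa > 0)))
    stop("`kappa` must be positive")
  stats::dnorm(x, mean = mu, sd = sqrt(kappa))
}

#' Posterior probability of EMG burst presence
#'
#' The responsibility of the burst component for an observation:
#' \deqn{p(s = 1 \mid x, \lambda) = \frac{w_1 f_1(x)}{w_0 f_0(x) + w_1 f_1(x)}}
#' computed in the log domain so extreme observations never produce NaN.
#'
#' @param x Log power in dB (vectorised).
#' @param state A [gmm_state()].
#' @return Probability in `[0, 1]`.
#' @export
posterior_burst_prob <- function(x, state) {
  l0 <- log(state$w0) + stats::dnorm(x, state$mu0, sqrt(state$kappa0), log = TRUE)
  l1 <- log(state$w1) + stats::dnorm(x, state$mu1, sqrt(state$kappa1), log = TRUE)
  stats::plogis(l1 - l0)
}

# Vectorised over bands: columns w0 w1 mu0 mu1 k0 k1. Returns p1 per band.
gmm_post_mat <- function(S, x) {
  l0 <- log(S[, 1]) + stats::dnorm(x, S[, 3], sqrt(S[, 5]), log = TRUE)
  l1 <- log(S[, 2]) + stats::dnorm(x, S[, 4], sqrt(S[, 6]), log = TRUE)
  stats::plogis(l1 - l0)
}

#' Batch EM fit of the log-power distribution
#'
#' Fits either a single Gaussian (closed-form MLE) or the two-component
#' mixture by expectation-maximization, used to build the initial per-band
#' model from the first `m_init` frames. The two-component fit starts from
#' the 25th/75th percentiles with shared variance and equal weights (fixed,
#' for determinism) and iterates until the log-likelihood gain drops below
#' `tol` or `max_iter` iterations. When `n_components = 2` the component
#' with the smaller mean is labelled non-burst (ties broken by smaller
#' variance).
#'
#' @param x Numeric vector of log powers (length >= 10).
#' @param n_components 1 or 2.
#' @param tol,max_iter EM stopping controls.
#' @return List with `state` (a [gmm_state()] for 2 components, or a list
#'   `(mu, kappa)` for 1), `loglik`, `n_iter`, `loglik_trace`, and
#'   `variance_floored` flag.
#' @export
em_fit <- function(x, n_components = 2, tol = 1e-6, max_iter = 300) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  m <- length(x)
  if (m < 10) stop("need at least 10 observations")
  var_floor <- 1e-6
  if (n_components == 1) {
    mu <- mean(x)
    kappa <- mean((x - mu)^2)
    floored <- kappa < var_floor
    kappa <- max(kappa, var_floor)
    ll <- sum(stats::dnorm(x, mu, sqrt(kappa), log = TRUE))
    return(list(state = list(mu = mu, kappa = kappa), loglik = ll,
                n_iter = 0L, loglik_trace = ll, variance_floored = floored))
  }
  if (n_components != 2) stop("`n_components` must be 1 or 2")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  mu <- c(q[1], q[2])
  kappa <- rep(max(stats::var(x) * (m - 1) / m, var_floor), 2)
  w <- c(0.5, 0.5)
  floored <- FALSE
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    l0 <- log(w[1]) + stats::dnorm(x, mu[1], sqrt(kappa[1]), log = TRUE)
    l1 <- log(w[2]) + stats::dnorm(x, mu[2], sqrt(kappa[2]), log = TRUE)
    lmax <- pmax(l0, l1)
    ll <- sum(lmax + log(exp(l0 - lmax) + exp(l1 - lmax)))
    trace <- c(trace, ll)
    if (ll - ll_old < tol && it > 1) break
    ll_old <- ll
    p1 <- stats::plogis(l1 - l0)
    p0 <- 1 - p1
    n0 <- sum(p0); n1 <- sum(p1)
    w <- c(n0, n1) / m
    mu <- c(sum(p0 * x) / n0, sum(p1 * x) / n1)
    kappa <- c(sum(p0 * (x - mu[1])^2) / n0, sum(p1 * (x - mu[2])^2) / n1)
    if (any(kappa < var_floor)) {
      floored <- TRUE
      kappa <- pmax(kappa, var_floor)
    }
  }
  # label the smaller-mean component non-burst
  ord <- order(mu, kappa)
  w <- w[ord]; mu <- mu[ord]; kappa <- kappa[ord]
  w1 <- min(max(w[2], 1e-12), 1 - 1e-12)
  list(state = gmm_state(w1, mu[1], mu[2], kappa[1], kappa[2]),
       loglik = trace[length(trace)], n_iter = length(trace),
       loglik_trace = trace, variance_floored = floored)
}

#' Minimum description length model selection at initialization
#'
#' Decides whether the initialization frames contain an EMG burst by
#' comparing a single Gaussian against the two-component mixture with the
#' two-part MDL score \eqn{-\log L + (p/2)\ln M}, where the free parameter
#' counts are 2 (mean, variance) and 5 (two means, two variances, one free
#' weight). Returns 1 (noise only) or 2 (burst present).
#'
#' @param x Numeric vector of log powers (length >= 10).
#' @inheritParams em_fit
#' @return Integer 1 or 2.
#' @export
mdl_select <- function(x, tol = 1e-6, max_iter = 300) {
  m <- length(x)
  f1 <- em_fit(x, 1, tol, max_iter)
  f2 <- em_fit(x, 2, tol, max_iter)
  mdl <- c(-f1$loglik + (2 / 2) * log(m),
           -f2$loglik + (5 / 2) * log(m))
  which.min(mdl)
}

#' Apply the burst/non-burst relationship constraints
#'
#' Enforces, in order: burst variance at least the non-burst variance
#' (\eqn{\kappa_1 \leftarrow \max\{\kappa_0, \kappa_1\}}), burst mean at
#' least `delta` dB above the non-burst mean
#' (\eqn{\mu_1 \leftarrow \max\{\mu_1, \mu_0 + \delta\}}), and a floor
#' `epsilon` on the burst weight with `w0 = 1 - w1`. Under sustained
#' non-burst input these turn the burst component into a "virtual"
#' component at `mu0 + delta` with variance `kappa0`, preserving the model's
#' ability to detect a later burst. Idempotent.
#'
#' @param state A [gmm_state()].
#' @param config A [gmm_config()].
#' @return Constrained `gmm_state`.
#' @export
apply_constraints <- function(state, config = gmm_config()) {
  S <- gmm_constrain_mat(state_to_row(state), config)
  row_to_state(S)
}

state_to_row <- function(state) {
  matrix(c(state$w0, state$w1, state$mu0, state$mu1,
           state$kappa0, state$kappa1), nrow = 1)
}

row_to_state <- function(S) {
  gmm_state(w1 = S[1, 2], mu0 = S[1, 3], mu1 = S[1, 4],
            kappa0 = S[1, 5], kappa1 = S[1, 6])
}

gmm_constrain_mat <- function(S, config) {
  S[, 6] <- pmax(S[, 5], S[, 6])
  S[, 4] <- pmax(S[, 4], S[, 3] + config$delta)
  # weight floor; when it binds the model has seen no burst for ~L frames,
  # so the burst component is replaced by the virtual one at mu0 + delta
  # with the non-burst variance, keeping discrimination ability intact
  virt <- S[, 2] < config$epsilon
  if (any(virt)) {
    S[virt, 4] <- S[virt, 3] + config$delta
    S[virt, 6] <- S[virt, 5]
  }
  S[, 2] <- pmax(S[, 2], config$epsilon)
  S[, 1] <- 1 - S[, 2]
  S
}

#' First-order sequential update of the GMM
#'
#' One frame of the online estimator. With the burst/non-burst posteriors
#' \eqn{p_i} computed from the *old* state, the parameters are updated with
#' forgetting factor \eqn{\alpha}:
#' \deqn{w_i' = \alpha w_i + (1-\alpha) p_i}
#' \deqn{\mu_i' = (\alpha w_i \mu_i + (1-\alpha) p_i x) / w_i'}
#' \deqn{\kappa_i' = (\alpha w_i \kappa_i + (1-\alpha) p_i (x - \mu_i')^2) / w_i'}
#' after which the constraints of [apply_constraints()] are enforced. The
#' weights sum to 1 before the weight-floor step. A non-finite observation
#' leaves the state unchanged with a warning.
#'
#' @param state A [gmm_state()].
#' @param x_new New log-power observation (dB).
#' @param config A [gmm_config()].
#' @return Updated `gmm_state`.
#' @export
sequential_update <- function(state, x_new, config = gmm_config()) {
  if (!is.finite(x_new)) {
    warning("non-finite observation skipped; state unchanged")
    return(state)
  }
  S <- gmm_update_mat(state_to_row(state), x_new, config)
  row_to_state(S)
}

# Vectorised sequential update: S rows are bands, x is the per-band
# observation vector. Returns list(S = updated matrix, p1 = posteriors).
gmm_update_mat <- function(S, x, config) {
  a <- config$alpha
  p1 <- gmm_post_mat(S, x)
  p0 <- 1 - p1
  w0n <- a * S[, 1] + (1 - a) * p0
  w1n <- a * S[, 2] + (1 - a) * p1
  mu0n <- (a * S[, 1] * S[, 3] + (1 - a) * p0 * x) / w0n
  mu1n <- (a * S[, 2] * S[, 4] + (1 - a) * p1 * x) / w1n
  k0n <- (a * S[, 1] * S[, 5] + (1 - a) * p0 * (x - mu0n)^2) / w0n
  k1n <- (a * S[, 2] * S[, 6] + (1 - a) * p1 * (x - mu1n)^2) / w1n
  Sn <- cbind(w0n, w1n, mu0n, mu1n, k0n, k1n, deparse.level = 0)
  Sn <- gmm_constrain_mat(Sn, config)
  attr(Sn, "p1") <- p1
  Sn
}

#' Bayes-optimal burst/non-burst classification threshold
#'
#' Solves \eqn{w_1 f_1(\theta) = w_0 f_0(\theta)} for the threshold that
#' minimizes the weighted classification error of the rule "log power below
#' \eqn{\theta} is non-burst, above is burst". With equal variances the
#' closed form
#' \eqn{\theta = (\mu_0+\mu_1)/2 + \kappa \ln(w_0/w_1)/(\mu_1-\mu_0)}
#' is used; otherwise equating the weighted log densities gives a quadratic
#' whose root nearest the inter-mean interval (the error minimizer; the
#' far-tail crossing is a local maximum) is returned.
#'
#' @param state A constrained [gmm_state()] with `mu1 > mu0`.
#' @return Threshold in dB.
#' @export
optimal_threshold <- function(state) {
  if (!(state$mu1 > state$mu0))
    stop("threshold requires a constrained state with mu1 > mu0")
  gmm_threshold_mat(state_to_row(state))
}

# Vectorised threshold over band rows of S.
gmm_threshold_mat <- function(S) {
  w0 <- S[, 1]; w1 <- S[, 2]; mu0 <- S[, 3]; mu1 <- S[, 4]
  k0 <- S[, 5]; k1 <- S[, 6]
  r <- log(w0 / w1) + 0.5 * log(k1 / k0)
  a <- (k1 - k0) / (2 * k0 * k1)
  b <- mu1 / k1 - mu0 / k0
  cc <- mu0^2 / (2 * k0) - mu1^2 / (2 * k1) - r
  theta <- numeric(length(w0))
  lin <- abs(a) < 1e-12
  if (any(lin)) {
    kap <- k0[lin]
    theta[lin] <- (mu0[lin] + mu1[lin]) / 2 +
      kap * log(w0[lin] / w1[lin]) / (mu1[lin] - mu0[lin])
  }
  if (any(!lin)) {
    aa <- a[!lin]; bb <- b[!lin]; ccq <- cc[!lin]
    disc <- bb^2 - 4 * aa * ccq
    # disc < 0: the weighted burst density dominates at every x (possible
    # with a wide, heavy burst component pinned at mu0 + delta); the Bayes
    # decision is then "always burst", i.e. threshold -Inf
    th <- rep(-Inf, length(aa))
    pos <- disc >= 0
    sq <- sqrt(disc[pos])
    # the error-minimizing crossing (w1 f1 - w0 f0 goes negative -> positive);
    # the other root is the far-tail local maximum and is discarded
    th[pos] <- (-bb[pos] + sq) / (2 * aa[pos])
    theta[!lin] <- th
  }
  theta
}
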
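# Shared fixtures and independent oracles for the test suite.

# confirmatory-trial generating parameters of the worked two-treatment /
# two-biomarker illustration (full-model labels)
theta_confirm <- c(alpha = -0.326, beta1 = -0.155, beta2 = 0.324,
                   gamma1 = 0.794, gamma2 = 1.061, delta11 = -0.014,
                   delta12 = 0.290, delta21 = 0.426, delta22 = -0.784)

# summary-statistics scenario: the four subgroup-matched treatment effects
# all equal -0.2, the mismatched ones are all +0.2
theta_flat02 <- c(alpha = 0, beta1 = -0.2, beta2 = 0.2, gamma1 = 1,
                  gamma2 = 1, delta11 = 0, delta12 = 0.4, delta21 = 0,
                  delta22 = -0.4)

# phase II generating parameters of the worked illustration
theta_phase2 <- c(alpha = -0.356, beta1 = -0.213, beta2 = 0.240,
                  gamma1 = 1, gamma2 = 1, delta11 = -0.182,
                  delta12 = 0.240, delta21 = 0.527, delta22 = -0.586)

# prior of the worked illustration: vague on everything except mildly
# negative subgroup-matched interactions
example_prior <- function() {
  nig_prior(theta0 = c(0, 0, 0, 0, 0, -0.1, 0, 0, -0.1),
            V0 = c(1, 1, 1, 1, 1, 2, 1, 1, 2), a = 1e-4, b = 1e-4)
}

# expected 0/1 coefficient pattern of the eight hypotheses (rows = the nine
# full-model parameters, columns = r)
contrast_pattern_22 <- function() {
  m <- matrix(0, 9, 8, dimnames = list(full_term_labels(2, 2), 1:8))
  m["beta1", 1:4] <- 1
  m["beta2", 5:8] <- 1
  m["delta11", c(2, 4)] <- 1
  m["delta12", c(3, 4)] <- 1
  m["delta21", c(6, 8)] <- 1
  m["delta22", c(7, 8)] <- 1
  m
}

# active full-model parameters at each of the 12 design points, in support
# order (profile-major, control first within profile)
active_params_22 <- list(
  c("alpha"),
  c("alpha", "beta1"),
  c("alpha", "beta2"),
  c("alpha", "gamma2"),
  c("alpha", "gamma2", "beta1", "delta12"),
  c("alpha", "gamma2", "beta2", "delta22"),
  c("alpha", "gamma1"),
  c("alpha", "gamma1", "beta1", "delta11"),
  c("alpha", "gamma1", "beta2", "delta21"),
  c("alpha", "gamma1", "gamma2"),
  c("alpha", "gamma1", "gamma2", "beta1", "delta11", "delta12"),
  c("alpha", "gamma1", "gamma2", "beta2", "delta22", "delta21"))

# random-walk Metropolis sampler for the normal linear model with an NIG
# prior, using only density evaluations (no conjugate algebra); returns
# draws of theta. Oracle for nig_update / contrast_posterior_prob.
metropolis_nig <- function(X, y, theta0, V0, a, b, iters = 60000,
                           step = 0.15) {
  p <- ncol(X)
  V0inv_chol <- chol(solve(V0))
  log_post <- function(th, log_s2) {
    s2 <- exp(log_s2)
    r <- y - drop(X %*% th)
    d <- drop(V0inv_chol %*% (th - theta0))
    # log IG(a,b) density in s2 plus Jacobian of the log transform
    (-a - 1) * log_s2 - b / s2 + log_s2 +
      (-length(y) / 2 - p / 2) * log(s2) -
      sum(r^2) / (2 * s2) - sum(d^2) / (2 * s2)
  }
  draws <- matrix(NA_real_, iters, p)
  th <- theta0
  ls2 <- 0
  lp <- log_post(th, ls2)
  for (i in seq_len(iters)) {
    prop_th <- th + rnorm(p, 0, step)
    prop_ls2 <- ls2 + rnorm(1, 0, step)
    lp_prop <- log_post(prop_th, prop_ls2)
    if (log(runif(1)) < lp_prop - lp) {
      th <- prop_th; ls2 <- prop_ls2; lp <- lp_prop
    }
    draws[i, ] <- th
  }
  draws[-seq_len(iters %/% 4), , drop = FALSE]
}

# closed-form weighted L objective for a saturated 3-cell one-way layout
# (control + two arms, no biomarkers): each treatment-vs-control variance is
# 1/p0 + 1/pk, so the criterion is fully explicit in p.
saturated_objective <- function(p0, p1, p2, w1, w2) {
  w1 * (1 / p0 + 1 / p1) + w2 * (1 / p0 + 1 / p2)
}
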
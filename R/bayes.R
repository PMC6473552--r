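# Conjugate Bayesian analysis of the exploratory (phase II) data. With a
# normal-inverse-gamma prior on (theta, sigma2), the posterior is again NIG
# and the marginal of theta is multivariate Student-t, so the posterior
# probability that a contrast lies below its threshold has a closed form.
# Bootstrap resampling of the phase II patients propagates small-sample
# variability into the hypothesis weights.

#' Normal-inverse-gamma prior
#'
#' Prior for the regression coefficients and residual variance of the normal
#' linear model: `sigma2 ~ IG(a, b)` and `theta | sigma2 ~ N(theta0,
#' sigma2 * V0)`.
#'
#' @param theta0 Prior mean vector (named by parameter label if desired).
#' @param V0 Prior scale matrix, or a vector taken as its diagonal.
#' @param a,b Inverse-gamma shape and rate (> 0). Small values (default
#'   `1e-4`) give a vague variance prior.
#' @return Object of class `nig_prior`.
#' @export
nig_prior <- function(theta0, V0, a = 1e-4, b = 1e-4) {
  if (is.vector(V0) && is.null(dim(V0))) V0 <- diag(V0, length(V0))
  stopifnot(nrow(V0) == length(theta0), ncol(V0) == length(theta0),
            a > 0, b > 0)
  ch <- tryCatch(chol(V0), error = function(e) {
    stop("V0 must be symmetric positive definite")
  })
  structure(list(theta0 = theta0, V0 = V0, a = a, b = b, chol_V0 = ch),
            class = "nig_prior")
}

#' Conjugate posterior update
#'
#' Standard normal-inverse-gamma update for the linear model `y = X theta +
#' eps`: the posterior scale is `V* = (V0^-1 + X'X)^-1`, the posterior mean
#' `theta* = V* (V0^-1 theta0 + X'y)`, `a* = a + n/2`,
#' `b* = b + (theta0' V0^-1 theta0 + y'y - theta*' V*^-1 theta*)/2`. The
#' marginal posterior of `theta` is multivariate Student-t with `2 a*`
#' degrees of freedom and scale `Sigma* = (b*/a*) V*`.
#'
#' @param prior A [nig_prior()].
#' @param X Design matrix (`n x p`, possibly 0 rows).
#' @param y Response vector of length `nrow(X)`.
#' @return Object of class `nig_posterior` with elements `theta_m`, `V`,
#'   `a`, `b`, `Sigma`, `df`.
#' @export
nig_update <- function(prior, X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncol(X) == length(prior$theta0))
  V0inv <- chol2inv(prior$chol_V0)
  Vstar_inv <- V0inv + crossprod(X)
  chV <- chol(Vstar_inv)
  Vstar <- chol2inv(chV)
  rhs <- V0inv %*% prior$theta0 + crossprod(X, y)
  theta_m <- drop(Vstar %*% rhs)
  names(theta_m) <- colnames(X) %||% names(prior$theta0)
  astar <- prior$a + length(y) / 2
  bstar <- prior$b + 0.5 * (drop(t(prior$theta0) %*% V0inv %*% prior$theta0) +
                            sum(y^2) - sum(theta_m * rhs))
  Sigma <- (bstar / astar) * Vstar
  dimnames(Sigma) <- list(names(theta_m), names(theta_m))
  structure(list(theta_m = theta_m, V = Vstar, a = astar, b = bstar,
                 Sigma = Sigma, df = 2 * astar),
            class = "nig_posterior")
}

#' @export
print.nig_posterior <- function(x, ...) {
  cat(sprintf("NIG posterior: %d parameters, a*=%.4g, b*=%.4g, df=%.4g\n",
              length(x$theta_m), x$a, x$b, x$df))
  print(round(x$theta_m, 4))
  invisible(x)
}

#' Posterior probability that a contrast is below its threshold
#'
#' `P_r = P(c' theta < tau)` under the marginal posterior of `theta`; since
#' the marginal is multivariate Student-t, `c' theta` is scalar-t with mean
#' `c' theta_m`, scale `sqrt(c' Sigma* c)` and `df = 2 a*`. The default is
#' the exact t CDF; `method = "normal"` uses the normal approximation, and
#' `method = "mc"` estimates the probability from posterior draws (useful
#' mainly to mirror a sampling-based analysis).
#'
#' @param post A [nig_posterior()].
#' @param con A [contrast()] or named coefficient vector.
#' @param tau Threshold; defaults to the contrast's own `tau`.
#' @param method `"exact"`, `"normal"` or `"mc"`.
#' @param draws Number of posterior draws in MC mode.
#' @return Probability in `[0, 1]`.
#' @export
contrast_posterior_prob <- function(post, con, tau = NULL,
                                    method = c("exact", "normal", "mc"),
                                    draws = 10000) {
  method <- match.arg(method)
  cf <- if (inherits(con, "contrast")) con$coef else con
  if (is.null(tau)) tau <- if (inherits(con, "contrast")) con$tau else 0
  idx <- match(names(cf), names(post$theta_m))
  stopifnot(!anyNA(idx))
  cv <- setNames(numeric(length(post$theta_m)), names(post$theta_m))
  cv[idx] <- cf
  m <- sum(cv * post$theta_m)
  s2 <- drop(t(cv) %*% post$Sigma %*% cv)
  if (s2 <= 0) stop("contrast has non-positive posterior scale")
  zq <- (tau - m) / sqrt(s2)
  switch(method,
         exact  = pt(zq, df = post$df),
         normal = pnorm(zq),
         mc     = mean(m + sqrt(s2) * rt(draws, df = post$df) < tau))
}

#' Bootstrap hypothesis weights from phase II data
#'
#' Resamples the phase II patients with replacement `B` times; on each
#' bootstrap sample runs the conjugate update and computes `P_r = P(c_r'
#' theta < tau_r)` for every candidate hypothesis. The weight of hypothesis
#' `r` is `w_r = E(P_r)` (mean over bootstrap replications) if it reaches
#' the selection threshold `kappa`, else 0; a hypothesis with `w_r > 0` is
#' selected and its subgroup enrolled in the confirmatory trial. The
#' weights need not sum to 1.
#'
#' @param data Data frame with columns `x1..xL`, `arm`, `y` (see
#'   [simulate_phase2()] for the schema).
#' @param prior A [nig_prior()] for the full model.
#' @param contrasts Candidate hypotheses, e.g. [contrast_catalogue()].
#' @param spec Full-model [regression_spec()].
#' @param B Number of bootstrap replications (`B = 1` with
#'   `resample = FALSE` analyzes the observed data once).
#' @param kappa Selection threshold(s) in `[0, 1]`, recycled over hypotheses.
#' @param tau Threshold(s) in response units, recycled; overrides the
#'   contrasts' own `tau` when non-`NULL`.
#' @param method,draws Passed to [contrast_posterior_prob()].
#' @param resample Set `FALSE` to skip resampling (identity bootstrap).
#' @param seed Optional RNG seed.
#' @return Object of class `weight_result` with matrix `P` (`B x R`),
#'   vectors `EP` and `w`, and `selected` (indices with `w > 0`).
#' @export
bootstrap_weights <- function(data, prior, contrasts, spec, B = 10000,
                              kappa = 0.5, tau = NULL,
                              method = c("exact", "normal", "mc"),
                              draws = 10000, resample = TRUE, seed = NULL) {
  method <- match.arg(method)
  stopifnot(nrow(data) >= 1, B >= 1)
  if (!is.null(seed)) set.seed(seed)
  X <- trial_design_matrix(data, spec)
  y <- data$y
  n <- nrow(X)
  R <- length(contrasts)
  kappa <- rep_len(kappa, R)
  taus <- if (is.null(tau)) vapply(contrasts, `[[`, numeric(1), "tau")
          else rep_len(tau, R)
  P <- matrix(NA_real_, B, R)
  for (b in seq_len(B)) {
    idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
    post <- nig_update(prior, X[idx, , drop = FALSE], y[idx])
    for (r in seq_len(R)) {
      P[b, r] <- contrast_posterior_prob(post, contrasts[[r]], tau = taus[r],
                                         method = method, draws = draws)
    }
  }
  EP <- colMeans(P)
  w <- ifelse(EP >= kappa, EP, 0)
  structure(list(P = P, EP = EP, w = w, kappa = kappa, tau = taus,
                 B = B, selected = which(w > 0)),
            class = "weight_result")
}

#' @export
print.weight_result <- function(x, ...) {
  tab <- data.frame(r = seq_along(x$EP), `E(P)` = round(x$EP, 3),
                    w = round(x$w, 3), check.names = FALSE)
  cat(sprintf("bootstrap hypothesis weights (B = %d, kappa = %s)\n",
              x$B, paste(unique(x$kappa), collapse = "/")))
  print(tab, row.names = FALSE)
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
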
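# Monte Carlo evaluation of randomization schemes. Trials are generated
# under the full interaction model (biomarkers ~ independent Bernoulli,
# arms ~ per-subgroup randomization probabilities, responses ~ normal),
# analyzed by ordinary least squares, and every analysis contrast is tested
# one-sided by Wald statistic. Rejection rates are classified as power or
# type I error by the sign of the true full-model contrast value, and the
# expected number of correct rejections (ENCR) sums the powers.

#' Simulate biomarker profiles
#'
#' Independent Bernoulli indicators per biomarker per patient.
#'
#' @param n Number of patients.
#' @param prevalence Per-biomarker positivity probabilities (length `L`).
#' @return `n x L` 0/1 matrix.
#' @export
simulate_biomarkers <- function(n, prevalence) {
  L <- length(prevalence)
  stopifnot(all(prevalence >= 0), all(prevalence <= 1))
  matrix(rbinom(n * L, 1, rep(prevalence, each = n)), n, L,
         dimnames = list(NULL, if (L) paste0("x", seq_len(L))))
}

# subgroup index in profile-major order (biomarker 1 most significant),
# matching enumerate_support()
subgroup_index <- function(profiles) {
  L <- ncol(profiles)
  if (L == 0) return(rep(1L, nrow(profiles)))
  1L + as.integer(profiles %*% 2^((L - 1):0))
}

#' Randomize patients and generate responses
#'
#' Arms are drawn from each patient's subgroup-specific randomization
#' probabilities; patients in subgroups the scheme does not enroll are
#' excluded. Responses follow the full model:
#' `y = f(x, T) theta + N(0, sigma2)`.
#'
#' @param profiles Biomarker matrix from [simulate_biomarkers()].
#' @param scheme A `randomization_scheme` (see [fixed_scheme()]).
#' @param theta Named full-model parameter vector.
#' @param sigma2 Residual variance (>= 0).
#' @return Data frame with columns `id`, `x1..xL`, `arm`, `y`.
#' @export
assign_and_respond <- function(profiles, scheme, theta, sigma2) {
  K <- attr(scheme, "K"); L <- attr(scheme, "L")
  stopifnot(ncol(profiles) == L, sigma2 >= 0)
  sg <- subgroup_index(profiles)
  keep <- scheme$enrolled[sg]
  profiles <- profiles[keep, , drop = FALSE]
  sg <- sg[keep]
  n <- nrow(profiles)
  pm <- as.matrix(scheme[, paste0("arm", 0:K), drop = FALSE])
  cum <- t(apply(pm, 1, cumsum))
  arm <- as.integer(rowSums(runif(n) > cum[sg, , drop = FALSE]))
  spec <- regression_spec(K, L)
  mu <- design_rows(cbind(as.data.frame(profiles),
                          data.frame(arm = arm)), spec) %*%
        theta[spec$terms]
  y <- drop(mu) + rnorm(n, 0, sqrt(sigma2))
  out <- data.frame(id = seq_len(n))
  for (l in seq_len(L)) out[[paste0("x", l)]] <- profiles[, l]
  out$arm <- arm
  out$y <- y
  out
}

#' Simulate an equal-randomization exploratory (phase II) trial
#'
#' Biomarkers are Bernoulli with the given prevalences and every patient is
#' randomized with probability `1/(K+1)` to each arm.
#'
#' @param n Phase II sample size.
#' @param prevalence Biomarker prevalences (length `L`).
#' @param theta Named full-model parameter vector.
#' @param sigma2 Residual variance.
#' @param K Number of experimental treatments.
#' @param seed Optional RNG seed.
#' @return Trial data frame (`id`, `x1..xL`, `arm`, `y`).
#' @export
simulate_phase2 <- function(n, prevalence, theta, sigma2, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(prevalence)
  profiles <- simulate_biomarkers(n, prevalence)
  assign_and_respond(profiles, fixed_scheme("rct", K, L), theta, sigma2)
}

#' Ordinary least-squares fit of a trial data set
#'
#' @param data Trial data frame (`x1..xL`, `arm`, `y`).
#' @param spec Analysis-model [regression_spec()].
#' @return List with `theta_hat`, `cov` (using the residual variance
#'   estimate `RSS/(n - p)`), `sigma2_hat` and `df`; errors if the design
#'   matrix is rank deficient.
#' @export
fit_least_squares <- function(data, spec) {
  X <- trial_design_matrix(data, spec)
  y <- data$y
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  theta_hat <- qr.coef(qx, y)
  res <- y - drop(X %*% theta_hat)
  df <- nrow(X) - ncol(X)
  sigma2_hat <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  dimnames(XtXinv) <- list(spec$terms, spec$terms)
  list(theta_hat = theta_hat, cov = sigma2_hat * XtXinv,
       sigma2_hat = sigma2_hat, df = df)
}

# resolve the analysis argument: NULL -> full model with full catalogue;
# reduced_model -> its spec/contrasts; list(spec=, contrasts=) passed through
resolve_analysis <- function(analysis, K, L) {
  if (is.null(analysis)) {
    list(spec = regression_spec(K, L), contrasts = contrast_catalogue(K, L))
  } else if (inherits(analysis, "reduced_model")) {
    list(spec = analysis$spec, contrasts = analysis$contrasts)
  } else {
    stopifnot(is.list(analysis), !is.null(analysis$spec),
              !is.null(analysis$contrasts))
    analysis
  }
}

# true full-model value of an analysis-coordinates contrast
true_contrast_values <- function(contrasts, spec, theta_true) {
  vapply(contrasts, function(con) {
    cf <- setNames(numeric(length(spec$terms)), spec$terms)
    cf[names(con$coef)] <- con$coef
    sum(drop(spec$map %*% cf) * theta_true[rownames(spec$map)])
  }, numeric(1))
}

#' Operating characteristics of a randomization scheme
#'
#' Nested Monte Carlo evaluation of a confirmatory trial: biomarker profiles
#' are re-simulated `reps_bio` times and, for each profile set, treatment
#' allocation and responses are re-drawn `reps_alloc` times. Each replicate
#' is fit by least squares under the analysis model and every analysis
#' contrast is tested one-sided at level `alpha`. A contrast whose true
#' full-model value is negative is a false null, and its rejection rate a
#' power; otherwise the rate is a type I error. ENCR is the sum of the
#' powers.
#'
#' When the scheme leaves some subgroups unenrolled, profiles are drawn
#' conditionally on enrollment so that `n` always counts enrolled patients.
#'
#' @param scheme A `randomization_scheme`.
#' @param theta_true Named full-model parameter vector generating the data.
#' @param sigma2 Residual variance.
#' @param n Confirmatory sample size.
#' @param prevalence Biomarker prevalences.
#' @param alpha One-sided test level.
#' @param analysis `NULL` for the full model and full hypothesis catalogue,
#'   or a [reduce_model()] result, or `list(spec=, contrasts=)`.
#' @param reps_bio,reps_alloc Nested replication counts.
#' @param sigma2_test Residual variance treated as known when standardizing
#'   the test statistics (a z test with presumed-known variance); `NULL`
#'   (default) studentizes with the residual estimate `RSS/(n - p)`. The
#'   nominal level is attained exactly only when this matches the true
#'   residual variance.
#' @param seed Optional RNG seed.
#' @return Object of class `simulation_result`: per-contrast table
#'   (`r`, `label`, `true_value`, `rejection_rate`, `class`), `encr`,
#'   replication counts and the number of dropped (rank-deficient)
#'   replicates.
#' @export
run_confirmatory <- function(scheme, theta_true, sigma2, n, prevalence,
                             alpha = 0.05, analysis = NULL,
                             reps_bio = 100, reps_alloc = 100,
                             sigma2_test = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- attr(scheme, "K"); L <- attr(scheme, "L")
  stopifnot(length(prevalence) == L)
  ana <- resolve_analysis(analysis, K, L)
  spec_a <- ana$spec
  contrasts <- ana$contrasts
  R <- length(contrasts)
  truev <- true_contrast_values(contrasts, spec_a, theta_true)

  cells <- enumerate_support(K, L)
  spec_full <- regression_spec(K, L)
  mu_cell <- drop(design_rows(cells, spec_full) %*% theta_true[spec_full$terms])
  Fa <- design_rows(cells, spec_a)
  p <- length(spec_a$terms)
  stopifnot(n > p)
  Cm <- vapply(contrasts, function(con) {
    cf <- setNames(numeric(p), spec_a$terms)
    cf[names(con$coef)] <- con$coef
    cf
  }, numeric(p))
  z <- qnorm(1 - alpha)
  pm <- as.matrix(scheme[, paste0("arm", 0:K), drop = FALSE])
  pm[!scheme$enrolled, ] <- 0
  cum <- t(apply(pm, 1, function(r) cumsum(ifelse(is.na(r), 0, r))))
  enrolled_sg <- which(scheme$enrolled)

  rejects <- numeric(R)
  dropped <- 0L
  total <- 0L
  sd_eps <- sqrt(sigma2)
  for (ib in seq_len(reps_bio)) {
    profiles <- simulate_biomarkers(n, prevalence)
    sg <- subgroup_index(profiles)
    # redraw patients falling in unenrolled subgroups (n counts enrolled)
    while (any(bad <- !(sg %in% enrolled_sg))) {
      nb <- sum(bad)
      profiles[bad, ] <- simulate_biomarkers(nb, prevalence)
      sg[bad] <- subgroup_index(profiles[bad, , drop = FALSE])
    }
    for (ia in seq_len(reps_alloc)) {
      arm <- as.integer(rowSums(runif(n) > cum[sg, , drop = FALSE]))
      cell <- (sg - 1L) * (K + 1L) + arm + 1L
      y <- mu_cell[cell] + rnorm(n, 0, sd_eps)
      Xa <- Fa[cell, , drop = FALSE]
      M <- crossprod(Xa)
      ch <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(ch)) { dropped <- dropped + 1L; next }
      Xty <- crossprod(Xa, y)
      theta_hat <- backsolve(ch, forwardsolve(t(ch), Xty))
      s2 <- if (is.null(sigma2_test)) {
        max(sum(y^2) - sum(theta_hat * Xty), 0) / (n - p)
      } else {
        sigma2_test
      }
      tmp <- forwardsolve(t(ch), Cm)
      se <- sqrt(s2 * colSums(tmp^2))
      stat <- drop(crossprod(Cm, theta_hat)) / se
      rejects <- rejects + (stat < -z)
      total <- total + 1L
    }
  }
  if (total == 0L) stop("every replicate was rank deficient")
  if (dropped / (dropped + total) > 0.01) {
    warning(sprintf("%.1f%% of replicates dropped for rank deficiency",
                    100 * dropped / (dropped + total)))
  }
  rate <- rejects / total
  tab <- data.frame(
    r = vapply(contrasts, function(con) as.integer(con$r), integer(1)),
    label = vapply(contrasts, `[[`, character(1), "label"),
    true_value = truev,
    rejection_rate = rate,
    class = ifelse(truev < 0, "power", "type1"))
  structure(list(table = tab, encr = sum(rate[truev < 0]),
                 reps_bio = reps_bio, reps_alloc = reps_alloc,
                 n = n, alpha = alpha, dropped = dropped),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "confirmatory simulation: n=%d, %d x %d replicates, alpha=%.3g%s\n",
    x$n, x$reps_bio, x$reps_alloc, x$alpha,
    if (x$dropped) sprintf(" (%d dropped)", x$dropped) else ""))
  tab <- x$table
  tab$true_value <- round(tab$true_value, 3)
  tab$rejection_rate <- round(tab$rejection_rate, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("ENCR = %.3f\n", x$encr))
  invisible(x)
}

#' Normal-approximation power of a scheme (analytic cross-check)
#'
#' Uses the expected per-patient information `E[f'f]` under the biomarker
#' prevalences and the scheme's randomization probabilities (conditioned on
#' enrollment) to approximate the sampling covariance, then computes the
#' one-sided rejection probability `Phi(-z - c'theta / se)`. Serves as an
#' independent check on [run_confirmatory()]. With `sigma2_test` the
#' statistic is standardized by that known variance while the estimator
#' noise still follows `sigma2`, so the rejection probability becomes
#' `Phi((-z * sqrt(sigma2_test) - c'theta / se_unit) / sqrt(sigma2))` with
#' `se_unit = sqrt(c' M^-1 c)`.
#'
#' @inheritParams run_confirmatory
#' @return Numeric vector of approximate rejection probabilities, one per
#'   analysis contrast.
#' @export
analytic_power <- function(scheme, theta_true, sigma2, n, prevalence,
                           alpha = 0.05, analysis = NULL,
                           sigma2_test = NULL) {
  K <- attr(scheme, "K"); L <- attr(scheme, "L")
  ana <- resolve_analysis(analysis, K, L)
  spec_a <- ana$spec
  contrasts <- ana$contrasts
  truev <- true_contrast_values(contrasts, spec_a, theta_true)
  cells <- enumerate_support(K, L)
  Fa <- design_rows(cells, spec_a)
  # subgroup probabilities under the prevalences, conditioned on enrollment
  sgp <- vapply(seq_len(nrow(scheme)), function(s) {
    x <- as.numeric(scheme[s, paste0("x", seq_len(L))])
    prod(ifelse(x == 1, prevalence, 1 - prevalence))
  }, numeric(1))
  sgp[!scheme$enrolled] <- 0
  sgp <- sgp / sum(sgp)
  pm <- as.matrix(scheme[, paste0("arm", 0:K), drop = FALSE])
  wts <- numeric(nrow(cells))
  for (s in seq_len(nrow(scheme))) {
    for (a in 0:K) {
      wts[(s - 1) * (K + 1) + a + 1] <-
        sgp[s] * if (scheme$enrolled[s]) pm[s, a + 1] else 0
    }
  }
  M <- n * crossprod(Fa, wts * Fa)
  ch <- chol(M)
  p <- length(spec_a$terms)
  Cm <- vapply(contrasts, function(con) {
    cf <- setNames(numeric(p), spec_a$terms)
    cf[names(con$coef)] <- con$coef
    cf
  }, numeric(p))
  se_unit <- sqrt(colSums(forwardsolve(t(ch), Cm)^2))
  st <- sqrt(sigma2_test %||% sigma2)
  pnorm((-qnorm(1 - alpha) * st - truev / se_unit) / sqrt(sigma2))
}
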
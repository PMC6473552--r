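# Linear response model for a multi-arm trial stratified by binary biomarkers:
#   y = alpha + sum_k beta_k T_k + sum_l gamma_l x_l
#         + sum_{k,l} delta_kl T_k x_l + eps,   eps ~ N(0, sigma2).
# Parameters are addressed by label ("alpha", "beta1", "gamma2", "delta12", ...)
# so that reduced (parsimonious) reparameterizations can track which full-model
# combination each term estimates.

#' Parameter labels of the full interaction model
#'
#' Canonical ordering is intercept, treatment main effects, biomarker main
#' effects, then interactions in treatment-major order
#' (`delta11, delta12, ..., delta21, ...`).
#'
#' @param K Number of experimental treatments (>= 1).
#' @param L Number of binary biomarkers (>= 0).
#' @return Character vector of parameter labels.
#' @export
#' @examples
#' full_term_labels(2, 2)
full_term_labels <- function(K, L) {
  stopifnot(K >= 1, K <= 9, L >= 0, L <= 9)
  c("alpha",
    paste0("beta", seq_len(K)),
    if (L > 0) paste0("gamma", seq_len(L)),
    if (L > 0) as.vector(t(outer(seq_len(K), seq_len(L),
                                 function(k, l) paste0("delta", k, l)))))
}

#' Define a regression model structure
#'
#' A `regression_spec` records which parameters are present in the analysis
#' model and, for reduced models, which full-model linear combination each
#' retained term estimates (e.g. a combined effect `beta2p = beta2 + delta22`
#' when treatment 2 is only ever given to biomarker-2-positive patients).
#'
#' @param K Number of experimental treatments.
#' @param L Number of biomarkers.
#' @param terms Parameter labels of the model; default is the full model.
#' @param substitutions Named list mapping a reduced-model label to a named
#'   coefficient vector over full-model labels (e.g.
#'   `list(beta2p = c(beta2 = 1, delta22 = 1))`).
#' @param support Optional integer vector of design-point indices (rows of
#'   [enumerate_support()]) on which a reduced model is valid.
#' @return An object of class `regression_spec`.
#' @export
#' @examples
#' regression_spec(2, 2)
regression_spec <- function(K, L, terms = NULL, substitutions = NULL,
                            support = NULL) {
  full <- full_term_labels(K, L)
  if (is.null(terms)) terms <- full
  stopifnot("alpha" %in% terms || any(names(substitutions) %in% terms))
  substitutions <- substitutions %||% list()
  plain <- setdiff(terms, names(substitutions))
  if (!all(plain %in% full)) {
    stop("unknown term(s): ", paste(setdiff(plain, full), collapse = ", "))
  }
  # full-model -> analysis-model coefficient map; column m gives the
  # full-model combination that parameter m of this spec estimates
  A <- matrix(0, length(full), length(terms),
              dimnames = list(full, terms))
  for (tm in terms) {
    if (tm %in% names(substitutions)) {
      comb <- substitutions[[tm]]
      stopifnot(all(names(comb) %in% full))
      A[names(comb), tm] <- comb
    } else {
      A[tm, tm] <- 1
    }
  }
  structure(list(K = K, L = L, terms = terms,
                 substitutions = substitutions, map = A,
                 support = support),
            class = "regression_spec")
}

#' @export
print.regression_spec <- function(x, ...) {
  kind <- if (length(x$substitutions) || length(x$terms) <
              length(full_term_labels(x$K, x$L))) "reduced" else "full"
  cat(sprintf("%s regression model: K=%d treatments, L=%d biomarkers, %d terms\n",
              kind, x$K, x$L, length(x$terms)))
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  for (tm in names(x$substitutions)) {
    comb <- x$substitutions[[tm]]
    cat(sprintf("  %s = %s\n", tm,
                paste(names(comb), collapse = " + ")))
  }
  if (!is.null(x$support)) {
    cat("  valid on design points:", paste(x$support, collapse = ", "), "\n")
  }
  invisible(x)
}

is_full_spec <- function(spec) {
  identical(spec$terms, full_term_labels(spec$K, spec$L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-model feature values for one patient, as a named vector
feature_row_full <- function(x, arm, K, L) {
  stopifnot(length(x) == L, all(x %in% c(0, 1)), arm %in% 0:K)
  Tk <- as.numeric(seq_len(K) == arm)
  v <- c(1, Tk, x, if (L > 0) as.vector(t(outer(Tk, as.numeric(x)))))
  names(v) <- full_term_labels(K, L)
  v
}

#' Feature (design-matrix) row for one biomarker profile and treatment
#'
#' For the full model the entries are the intercept, treatment indicators,
#' biomarker indicators and their products. For a reduced model a merged
#' term takes the value of its constituent columns, which coincide on the
#' support the reduction was derived for.
#'
#' @param x Binary biomarker profile (length `spec$L`).
#' @param arm Treatment arm, `0` = control, `1..K` = experimental.
#' @param spec A [regression_spec()].
#' @return Named numeric vector of length `length(spec$terms)`.
#' @export
#' @examples
#' feature_row(c(1, 0), 1, regression_spec(2, 2))
feature_row <- function(x, arm, spec) {
  fv <- feature_row_full(x, arm, spec$K, spec$L)
  out <- vapply(spec$terms, function(tm) {
    if (tm %in% names(fv)) fv[[tm]]
    else fv[[names(spec$substitutions[[tm]])[1L]]]
  }, numeric(1))
  names(out) <- spec$terms
  out
}

#' Enumerate the biomarker-treatment design points
#'
#' All `(K+1) * 2^L` combinations of a biomarker profile and an assigned arm,
#' ordered profile-major (profiles in binary counting order with biomarker 1
#' most significant) and control-first within each profile.
#'
#' @inheritParams full_term_labels
#' @return Data frame with columns `i`, `x1..xL`, `arm`.
#' @export
#' @examples
#' enumerate_support(2, 2)  # the 12 points of the two-treatment design
enumerate_support <- function(K, L) {
  stopifnot(K >= 1, L >= 0)
  if (L > 0) {
    g <- expand.grid(rev(rep(list(0:1), L)))[, L:1, drop = FALSE]
    profiles <- as.matrix(g)
  } else {
    profiles <- matrix(0, nrow = 1, ncol = 0)
  }
  nprof <- nrow(profiles)
  out <- data.frame(i = seq_len(nprof * (K + 1)))
  if (L > 0) {
    for (l in seq_len(L)) {
      out[[paste0("x", l)]] <- rep(profiles[, l], each = K + 1)
    }
  }
  out$arm <- rep(0:K, times = nprof)
  out
}

# design matrix for a set of points (data.frame with x1..xL, arm)
design_rows <- function(points, spec) {
  L <- spec$L
  xs <- if (L > 0) {
    as.matrix(points[, paste0("x", seq_len(L)), drop = FALSE])
  } else {
    matrix(0, nrow(points), 0)
  }
  F <- t(vapply(seq_len(nrow(points)),
                function(i) feature_row(xs[i, ], points$arm[i], spec),
                numeric(length(spec$terms))))
  colnames(F) <- spec$terms
  F
}

#' Design matrix of a trial data set
#'
#' @param data Data frame with columns `x1..xL` and `arm` (0 = control).
#' @param spec A [regression_spec()].
#' @return Numeric matrix, one row per patient.
#' @export
trial_design_matrix <- function(data, spec) design_rows(data, spec)

#' Hypothesis contrast
#'
#' A contrast is a coefficient vector over the parameters of a model, tested
#' one-sided against a minimum-uninteresting-difference threshold `tau`
#' (negative values are beneficial by convention).
#'
#' @param coef Named numeric vector over model parameter labels, not all zero.
#' @param tau Threshold in response units (default 0).
#' @param r Optional hypothesis index.
#' @param label Optional human-readable label.
#' @return Object of class `contrast`.
#' @export
contrast <- function(coef, tau = 0, r = NA_integer_, label = NULL) {
  stopifnot(is.numeric(coef), !is.null(names(coef)), any(coef != 0))
  if (is.null(label)) {
    nz <- coef[coef != 0]
    label <- paste(ifelse(nz == 1, names(nz),
                          paste0(nz, "*", names(nz))), collapse = " + ")
  }
  structure(list(coef = coef, tau = tau, r = r, label = label),
            class = "contrast")
}

#' @export
print.contrast <- function(x, ...) {
  cat(sprintf("contrast%s: %s  (tau = %g)\n",
              if (is.na(x$r)) "" else paste0(" r=", x$r), x$label, x$tau))
  invisible(x)
}

#' Catalogue of treatment-versus-control hypotheses
#'
#' For each treatment `k` and each subset `S` of biomarkers, the contrast
#' `beta_k + sum_{l in S} delta_kl` is the difference between treatment `k`
#' and control in the subgroup positive exactly for the biomarkers in `S`.
#' This yields `2^L * K` hypotheses; ordering is treatment-major with subsets
#' in binary counting order (biomarker 1 least significant), which for
#' `K = L = 2` gives the familiar eight contrasts `beta1`, `beta1+delta11`,
#' `beta1+delta12`, `beta1+delta11+delta12`, then the same for treatment 2.
#'
#' @inheritParams full_term_labels
#' @param tau Threshold(s), recycled over hypotheses.
#' @return List of [contrast()] objects over the full-model labels.
#' @export
contrast_catalogue <- function(K, L, tau = 0) {
  full <- full_term_labels(K, L)
  R <- (2^L) * K
  tau <- rep_len(tau, R)
  out <- vector("list", R)
  r <- 0L
  for (k in seq_len(K)) {
    for (mask in 0:(2^L - 1)) {
      r <- r + 1L
      cf <- setNames(numeric(length(full)), full)
      cf[paste0("beta", k)] <- 1
      for (l in seq_len(L)) {
        if (bitwAnd(mask, bitwShiftL(1L, l - 1L)) != 0L) {
          cf[paste0("delta", k, l)] <- 1
        }
      }
      out[[r]] <- contrast(cf, tau = tau[r], r = r)
    }
  }
  out
}

#' True value of a contrast under a parameter vector
#'
#' @param con A [contrast()] (or named numeric coefficient vector).
#' @param theta Named numeric parameter vector covering the contrast's terms.
#' @return The inner product `c' theta`.
#' @export
contrast_value <- function(con, theta) {
  cf <- if (inherits(con, "contrast")) con$coef else con
  stopifnot(!is.null(names(theta)), all(names(cf) %in% names(theta)))
  sum(cf * theta[names(cf)])
}

#' Information matrix of a continuous design
#'
#' `M = n * sum_i p_i f(x_i, T_i)' f(x_i, T_i)` over the support points of a
#' design measure. Its inverse scaled by `sigma2` is the covariance of the
#' least-squares estimator under the corresponding allocation.
#'
#' @param p Proportions over the support rows (must sum to 1).
#' @param support Data frame of design points (see [enumerate_support()]).
#' @param spec A [regression_spec()].
#' @param n Sample-size scale factor (default 1).
#' @return Symmetric positive semidefinite matrix.
#' @export
information_matrix <- function(p, support, spec, n = 1) {
  stopifnot(length(p) == nrow(support), all(p >= -1e-12),
            abs(sum(p) - 1) < 1e-9)
  F <- design_rows(support, spec)
  M <- n * crossprod(F, p * F)
  (M + t(M)) / 2
}

#' One-sided Wald test of a contrast
#'
#' Rejects the null `c' theta = 0` in favour of `c' theta < 0` when
#' `c' theta_hat / sqrt(c' cov c) < -z(alpha)`. Beneficial effects are
#' negative by convention; set `direction = "greater"` to flip the sign
#' convention.
#'
#' @param theta_hat Estimated parameter vector (named or aligned with `con`).
#' @param cov Covariance matrix of `theta_hat`.
#' @param con A [contrast()] or coefficient vector aligned with `theta_hat`.
#' @param alpha One-sided type I error level (0 < alpha < 0.5).
#' @param direction `"less"` (default) or `"greater"`.
#' @return List with `statistic`, `reject`, `z`.
#' @export
wald_test <- function(theta_hat, cov, con, alpha = 0.05,
                      direction = c("less", "greater")) {
  direction <- match.arg(direction)
  stopifnot(alpha > 0, alpha < 0.5)
  cf <- if (inherits(con, "contrast")) con$coef else con
  if (!is.null(names(cf)) && !is.null(names(theta_hat))) {
    idx <- match(names(cf), names(theta_hat))
    stopifnot(!anyNA(idx))
    cfull <- setNames(numeric(length(theta_hat)), names(theta_hat))
    cfull[idx] <- cf
    cf <- cfull
  }
  stopifnot(length(cf) == length(theta_hat))
  v <- drop(t(cf) %*% cov %*% cf)
  if (v <= 0) stop("contrast is not estimable: zero or negative variance")
  stat <- sum(cf * theta_hat) / sqrt(v)
  z <- qnorm(1 - alpha)
  reject <- if (direction == "less") stat < -z else stat > z
  list(statistic = stat, reject = reject, z = z)
}
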
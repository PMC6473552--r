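# Weighted L-optimal continuous designs. The criterion is the weighted sum
# of contrast variances sum_r w_r c_r' M(p)^-1 c_r with information matrix
# M(p) = n sum_i p_i f_i' f_i over the design simplex; it reduces to
# c-optimality for a single contrast. The optimum is found with the
# multiplicative algorithm for linear (A/L-type) criteria, certified by the
# general equivalence theorem, and converted to per-subgroup randomization
# probabilities rather than rounded to an exact design.

#' Define a weighted L-optimal design problem
#'
#' @param spec Analysis-model [regression_spec()] (possibly reduced).
#' @param contrasts Selected hypotheses expressed in `spec` coordinates.
#' @param w Positive importance weights, one per contrast.
#' @param support Data frame of candidate design points (default: the
#'   spec's own support if reduced, else all points).
#' @param exclusions Design-point indices (`i` values) whose proportion is
#'   forced to zero.
#' @param n Sample-size scale factor; it does not affect the optimizing
#'   proportions, only the reported criterion value.
#' @return Object of class `design_problem`.
#' @export
design_problem <- function(spec, contrasts, w, support = NULL,
                           exclusions = integer(0), n = 1) {
  stopifnot(length(w) == length(contrasts), all(w > 0), n > 0)
  if (is.null(support)) {
    support <- enumerate_support(spec$K, spec$L)
    if (!is.null(spec$support)) {
      support <- support[support$i %in% spec$support, , drop = FALSE]
    }
  }
  active <- !(support$i %in% exclusions)
  stopifnot(any(active))
  F <- design_rows(support[active, , drop = FALSE], spec)
  C <- vapply(contrasts, function(con) {
    cf <- setNames(numeric(length(spec$terms)), spec$terms)
    cf[names(con$coef)] <- con$coef
    cf
  }, numeric(length(spec$terms)))
  if (qr(F)$rank < ncol(F)) {
    # contrasts may still be estimable on a rank-deficient candidate set,
    # but the criterion as implemented requires a nonsingular M somewhere
    if (qr(rbind(F, t(C)))$rank > qr(F)$rank) {
      stop("some contrast is not estimable on the candidate support")
    }
  }
  structure(list(spec = spec, contrasts = contrasts, w = w,
                 support = support, active = active, F = F, C = C, n = n),
            class = "design_problem")
}

# expand a proportion vector given over active points (or all points) to the
# active subset, validating the simplex constraint
active_p <- function(p, problem) {
  m_all <- nrow(problem$support)
  m_act <- sum(problem$active)
  if (length(p) == m_all) {
    if (any(abs(p[!problem$active]) > 1e-9)) {
      stop("excluded design points must have zero proportion")
    }
    p <- p[problem$active]
  } else if (length(p) != m_act) {
    stop("p must have length ", m_all, " or ", m_act)
  }
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9) {
    stop("p must lie on the simplex")
  }
  pmax(p, 0)
}

#' Weighted L-optimality criterion
#'
#' `sum_r w_r c_r' M(p)^-1 c_r` with `M(p) = n sum_i p_i f_i' f_i`. Returns
#' `Inf` when the information matrix at `p` is singular (some contrast
#' non-estimable at that allocation).
#'
#' @param p Proportions over the problem's support (full support with zeros
#'   at excluded points, or over the active points only).
#' @param problem A [design_problem()].
#' @return Criterion value (scalar, possibly `Inf`).
#' @export
weighted_l_objective <- function(p, problem) {
  p <- active_p(p, problem)
  M <- problem$n * crossprod(problem$F, p * problem$F)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  tmp <- forwardsolve(t(ch), problem$C)
  sum(problem$w * colSums(tmp^2))
}

# criterion value plus the variance-function values d_i = n * sum_r w_r
# (f_i' M^-1 c_r)^2 used by the multiplicative algorithm and the
# equivalence-theorem gap; at the optimum max_i d_i = objective.
l_directional <- function(p_act, problem) {
  M <- problem$n * crossprod(problem$F, p_act * problem$F)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  tmp <- forwardsolve(t(ch), problem$C)      # p x R
  MinvC <- backsolve(ch, tmp)                # M^-1 C
  FMC <- problem$F %*% MinvC                 # m x R
  list(obj = sum(problem$w * colSums(tmp^2)),
       d = problem$n * drop(FMC^2 %*% problem$w))
}

#' Solve for the weighted L-optimal design
#'
#' Minimizes the criterion over the simplex (with excluded points fixed at
#' zero) using the multiplicative algorithm `p_i <- p_i (d_i / mean)^(1/2)`,
#' where `d_i` is the variance function; the criterion is convex in `p`, and
#' convergence is certified by the general-equivalence-theorem gap
#' `max_i d_i / objective - 1`. Multiple starts (equal allocation plus
#' Dirichlet draws) guard against numerical stalling and verify uniqueness.
#'
#' @param problem A [design_problem()].
#' @param starts Number of starting points (first is equal allocation).
#' @param tol Convergence tolerance on the equivalence-theorem gap.
#' @param max_iter Iteration cap per start.
#' @param zero_clip Proportions below this are reported as exactly zero.
#' @param seed Optional RNG seed for the random starts.
#' @return Object of class `design_measure`: the problem support with
#'   optimal proportions `p`, criterion value `objective`, certificate
#'   `gap`, and the per-start objectives.
#' @export
solve_design <- function(problem, starts = 5, tol = 1e-9, max_iter = 20000,
                         zero_clip = 1e-6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- sum(problem$active)
  inits <- c(list(rep(1 / m, m)),
             lapply(seq_len(max(0, starts - 1)), function(s) {
               g <- rgamma(m, 1); g / sum(g)
             }))
  runs <- lapply(inits, function(p) {
    obj_prev <- Inf
    gap <- Inf
    for (it in seq_len(max_iter)) {
      dd <- l_directional(p, problem)
      if (is.null(dd)) return(NULL)
      gap <- max(dd$d) / dd$obj - 1
      if (gap < tol || abs(obj_prev - dd$obj) < 1e-15 * dd$obj && it > 50) {
        return(list(p = p, obj = dd$obj, gap = gap, iter = it))
      }
      obj_prev <- dd$obj
      p <- p * sqrt(dd$d / dd$obj)
      p <- p / sum(p)
    }
    list(p = p, obj = obj_prev, gap = gap, iter = max_iter)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("design optimization failed from every start")
  objs <- vapply(runs, `[[`, numeric(1), "obj")
  best <- runs[[which.min(objs)]]
  if (best$gap > 1e-6) {
    warning(sprintf("equivalence-theorem gap %.2e above certificate level",
                    best$gap))
  }
  p_act <- best$p
  p_act[p_act < zero_clip] <- 0
  p_act <- p_act / sum(p_act)
  p <- numeric(nrow(problem$support))
  p[problem$active] <- p_act
  structure(list(support = problem$support, p = p,
                 objective = weighted_l_objective(p, problem),
                 gap = best$gap, iterations = best$iter,
                 start_objectives = objs, problem = problem),
            class = "design_measure")
}

#' @export
print.design_measure <- function(x, ...) {
  tab <- x$support
  tab$p <- round(x$p, 4)
  cat(sprintf("optimal continuous design (criterion %.6g, certificate gap %.1e)\n",
              x$objective, x$gap))
  print(tab, row.names = FALSE)
  invisible(x)
}

profile_key <- function(points, L) {
  if (L == 0) return(rep("", nrow(points)))
  apply(points[, paste0("x", seq_len(L)), drop = FALSE], 1, paste,
        collapse = "")
}

#' Convert a design measure to per-subgroup randomization probabilities
#'
#' Within each biomarker subgroup the optimal proportions are renormalized
#' to sum to one, giving the probability of randomizing a patient of that
#' subgroup to each arm; no rounding to an exact design is needed. A
#' subgroup carrying (almost) no mass is marked not enrolled.
#'
#' @param measure A [design_measure()], or a list with elements `support`
#'   (design points) and `p` (proportions) plus `K`, `L` given explicitly.
#' @param K,L Model dimensions; defaults taken from the measure's problem.
#' @param mass_threshold Subgroup mass below which it is not enrolled.
#' @return A `randomization_scheme`: data frame over all `2^L` subgroups
#'   with columns `x1..xL`, `enrolled`, `arm0..armK`.
#' @export
to_randomization_scheme <- function(measure, K = NULL, L = NULL,
                                    mass_threshold = 1e-6) {
  if (is.null(K)) K <- measure$problem$spec$K
  if (is.null(L)) L <- measure$problem$spec$L
  if (sum(measure$p) <= 0) stop("design measure has no mass")
  full <- enumerate_support(K, L)
  scheme <- unique(full[full$arm == 0, c(paste0("x", seq_len(L))),
                        drop = FALSE])
  rownames(scheme) <- NULL
  keys <- profile_key(scheme, L)
  mkeys <- profile_key(measure$support, L)
  probs <- matrix(0, nrow(scheme), K + 1,
                  dimnames = list(NULL, paste0("arm", 0:K)))
  enrolled <- logical(nrow(scheme))
  for (s in seq_len(nrow(scheme))) {
    sel <- mkeys == keys[s]
    mass <- sum(measure$p[sel])
    if (mass >= mass_threshold) {
      enrolled[s] <- TRUE
      for (a in 0:K) {
        probs[s, a + 1] <- sum(measure$p[sel & measure$support$arm == a]) / mass
      }
    } else {
      probs[s, ] <- NA_real_
    }
  }
  out <- cbind(scheme, enrolled = enrolled, as.data.frame(probs))
  structure(out, class = c("randomization_scheme", "data.frame"),
            K = K, L = L)
}

#' Fixed comparator randomization schemes
#'
#' `"rct"` is the randomized controlled trial: every subgroup is randomized
#' equally across control and all `K` treatments. `"linked"` is the
#' biomarker-treatment linked trial: a subgroup is offered control plus each
#' treatment whose linked biomarker it is positive for (all arms when every
#' biomarker is negative), with equal probabilities among the offered arms.
#'
#' @param kind `"rct"` or `"linked"`.
#' @inheritParams full_term_labels
#' @param linkage Integer vector mapping treatment `k` to a biomarker index;
#'   default `k -> k` (requires `K <= L`).
#' @return A `randomization_scheme` (see [to_randomization_scheme()]).
#' @export
#' @examples
#' fixed_scheme("linked", 2, 2)
fixed_scheme <- function(kind = c("rct", "linked"), K, L, linkage = NULL) {
  kind <- match.arg(kind)
  full <- enumerate_support(K, L)
  scheme <- unique(full[full$arm == 0, paste0("x", seq_len(L)),
                        drop = FALSE])
  rownames(scheme) <- NULL
  probs <- matrix(0, nrow(scheme), K + 1,
                  dimnames = list(NULL, paste0("arm", 0:K)))
  if (kind == "rct") {
    probs[] <- 1 / (K + 1)
  } else {
    if (is.null(linkage)) {
      if (K > L) stop("default linkage k -> k needs K <= L")
      linkage <- seq_len(K)
    }
    stopifnot(length(linkage) == K, all(linkage %in% seq_len(L)))
    for (s in seq_len(nrow(scheme))) {
      x <- as.numeric(scheme[s, ])
      offered <- c(0, which(x[linkage] == 1))
      if (length(offered) == 1) offered <- 0:K  # no positive biomarker
      probs[s, offered + 1] <- 1 / length(offered)
    }
  }
  out <- cbind(scheme, enrolled = TRUE, as.data.frame(probs))
  structure(out, class = c("randomization_scheme", "data.frame"),
            K = K, L = L)
}

#' @export
print.randomization_scheme <- function(x, ...) {
  cat(sprintf("randomization scheme (K=%d, L=%d)\n",
              attr(x, "K"), attr(x, "L")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1)) & grepl("^arm", names(y))
  y[num] <- lapply(y[num], round, 3)
  print(y, row.names = FALSE)
  invisible(x)
}
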
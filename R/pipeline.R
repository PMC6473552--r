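# End-to-end workflow: phase II data (observed or simulated) -> bootstrap
# hypothesis weights -> parsimonious analysis model -> weighted L-optimal
# randomization scheme -> confirmatory operating characteristics for the
# optimal and comparator schemes. A single top-level seed deterministically
# spawns per-stage substreams so that adding a comparator never perturbs an
# earlier stage.

#' Run the full design pipeline
#'
#' @param config Named list with components:
#'   \describe{
#'     \item{K, L}{model dimensions.}
#'     \item{phase2}{either `list(data = <data.frame>)` with columns
#'       `x1..xL`, `arm`, `y`, or simulation parameters
#'       `list(n=, prevalence=, theta=, sigma2=)`.}
#'     \item{prior}{a [nig_prior()] or `list(theta0=, V0=, a=, b=)`.}
#'     \item{weights}{`list(B=, kappa=, tau=, method=)` for
#'       [bootstrap_weights()]; defaults `B = 10000`, `kappa = 0.5`,
#'       `tau = 0`.}
#'     \item{design}{optional [solve_design()] settings
#'       (`starts`, `tol`, `zero_clip`).}
#'     \item{evaluate}{confirmatory settings `list(n=, prevalence=,
#'       theta=, sigma2=, alpha=, reps_bio=, reps_alloc=,
#'       comparators=c("rct", "linked"))`; set to `NULL` to skip
#'       simulation.}
#'     \item{seed}{mandatory integer seed.}
#'     \item{out_dir}{optional directory for CSV/JSON artifacts.}
#'   }
#' @return Object of class `trial_design_report` containing the weights, the
#'   reduced model, the optimal measure and scheme, and a `simulation_result`
#'   per evaluated scheme with an ENCR comparison table. If no hypothesis
#'   reaches the selection threshold the report carries the weights and a
#'   guidance message only.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed),
            !is.null(config$K), !is.null(config$L))
  K <- config$K; L <- config$L
  seed <- as.integer(config$seed)
  spec <- regression_spec(K, L)
  catalogue <- contrast_catalogue(K, L)
  as_theta <- function(v) {
    v <- unlist(v)
    if (is.null(names(v))) names(v) <- spec$terms
    v
  }

  # stage 1: phase II data
  ph2 <- config$phase2
  if (!is.null(ph2$data)) {
    data <- ph2$data
  } else {
    data <- simulate_phase2(ph2$n, ph2$prevalence, as_theta(ph2$theta),
                            ph2$sigma2, K = K, seed = seed + 1L)
  }

  # stage 2: bootstrap hypothesis weights
  prior <- config$prior
  if (!inherits(prior, "nig_prior")) {
    prior <- nig_prior(prior$theta0, prior$V0,
                       prior$a %||% 1e-4, prior$b %||% 1e-4)
  }
  wcfg <- config$weights %||% list()
  weights <- bootstrap_weights(
    data, prior, catalogue, spec,
    B = wcfg$B %||% 10000, kappa = wcfg$kappa %||% 0.5,
    tau = wcfg$tau, method = wcfg$method %||% "exact",
    draws = wcfg$draws %||% 10000, seed = seed + 2L)

  report <- list(config = config, seed = seed, data = data,
                 weights = weights,
                 package_version = as.character(utils::packageVersion("optrial")))
  if (!length(weights$selected)) {
    report$message <- paste(
      "no hypothesis reached the selection threshold kappa;",
      "lower kappa or collect more phase II data")
    class(report) <- "trial_design_report"
    return(report)
  }

  # stage 3: parsimonious model + optimal design
  selected <- catalogue[weights$selected]
  reduced <- reduce_model(selected, spec)
  dcfg <- config$design %||% list()
  problem <- design_problem(reduced$spec, reduced$contrasts,
                            w = weights$w[weights$selected])
  measure <- solve_design(problem, starts = dcfg$starts %||% 5,
                          tol = dcfg$tol %||% 1e-9,
                          zero_clip = dcfg$zero_clip %||% 1e-6,
                          seed = seed + 3L)
  scheme <- to_randomization_scheme(measure)
  report$reduced <- reduced
  report$measure <- measure
  report$scheme <- scheme

  # stage 4: confirmatory evaluation
  ev <- config$evaluate
  if (!is.null(ev)) {
    schemes <- list(optimal = scheme)
    for (cmp in ev$comparators %||% c("rct", "linked")) {
      schemes[[cmp]] <- fixed_scheme(cmp, K, L)
    }
    results <- list()
    j <- 0L
    for (nm in names(schemes)) {
      j <- j + 1L
      ana <- if (nm == "optimal") reduced else NULL
      results[[nm]] <- run_confirmatory(
        schemes[[nm]], as_theta(ev$theta), ev$sigma2, ev$n, ev$prevalence,
        alpha = ev$alpha %||% 0.05, analysis = ana,
        reps_bio = ev$reps_bio %||% 100,
        reps_alloc = ev$reps_alloc %||% 100,
        sigma2_test = ev$sigma2_test,
        seed = seed + 10L + j)
    }
    report$results <- results
    report$encr <- data.frame(
      scheme = names(results),
      encr = vapply(results, `[[`, numeric(1), "encr"))
  }
  class(report) <- "trial_design_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.trial_design_report <- function(x, ...) {
  cat("== trial design report (seed", x$seed, ")==\n\n")
  print(x$weights)
  if (!is.null(x$message)) {
    cat("\n", x$message, "\n", sep = "")
    return(invisible(x))
  }
  cat("\n")
  print(x$reduced)
  cat("\n")
  print(x$scheme)
  if (!is.null(x$encr)) {
    cat("\nENCR comparison:\n")
    tab <- x$encr
    tab$encr <- round(tab$encr, 3)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

# write CSV/JSON artifacts for a pipeline report
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- report$weights
  utils::write.csv(
    data.frame(r = seq_along(w$EP), EP = w$EP, w = w$w),
    file.path(dir, "weights.csv"), row.names = FALSE)
  if (!is.null(report$measure)) {
    m <- report$measure
    tab <- m$support
    names(tab)[names(tab) == "i"] <- "i_prime"
    tab$p <- m$p
    utils::write.csv(tab, file.path(dir, "design_measure.csv"),
                     row.names = FALSE)
    sch <- as.data.frame(report$scheme)
    utils::write.csv(sch, file.path(dir, "scheme.csv"), row.names = FALSE)
  }
  if (!is.null(report$results)) {
    for (nm in names(report$results)) {
      utils::write.csv(report$results[[nm]]$table,
                       file.path(dir, paste0("results_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  summary <- list(
    package_version = report$package_version,
    seed = report$seed,
    selected = report$weights$selected,
    encr = report$encr,
    message = report$message)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate deterministic CSV fixtures
#'
#' Writes a synthetic phase II or confirmatory data set with the standard
#' trial schema (`id`, `x1..xL`, `arm`, `y`) for tests and demos.
#'
#' @param kind `"phase2"` (equal randomization) or `"confirmatory"`
#'   (randomization per `params$scheme`).
#' @param params List with `n`, `prevalence`, `theta`, `sigma2`, `K` and,
#'   for `"confirmatory"`, a `scheme`.
#' @param seed Integer seed.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
generate_fixture <- function(kind = c("phase2", "confirmatory"), params,
                             seed, path) {
  kind <- match.arg(kind)
  set.seed(seed)
  L <- length(params$prevalence)
  if (is.null(names(params$theta))) {
    K_fx <- params$K %||% attr(params$scheme, "K")
    names(params$theta) <- full_term_labels(K_fx, L)
  }
  data <- if (kind == "phase2") {
    simulate_phase2(params$n, params$prevalence, params$theta,
                    params$sigma2, K = params$K)
  } else {
    assign_and_respond(simulate_biomarkers(params$n, params$prevalence),
                       params$scheme, params$theta, params$sigma2)
  }
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
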
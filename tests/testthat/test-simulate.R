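test_that("biomarker simulation follows the prevalences", {
  set.seed(1)
  expect_equal(simulate_biomarkers(50, c(0, 0)),
               matrix(0, 50, 2, dimnames = list(NULL, c("x1", "x2"))))
  expect_equal(simulate_biomarkers(50, c(1, 1)),
               matrix(1, 50, 2, dimnames = list(NULL, c("x1", "x2"))))
  n <- 1e5
  x <- simulate_biomarkers(n, c(0.3, 0.3))
  f11 <- mean(x[, 1] == 1 & x[, 2] == 1)
  expect_lt(abs(f11 - 0.09), 3 * sqrt(0.09 * 0.91 / n))
})

test_that("responses follow the model and schemes gate the arms", {
  set.seed(2)
  sup <- enumerate_support(2, 2)
  spec <- regression_spec(2, 2)
  # noiseless responses equal the design-point means
  profiles <- as.matrix(sup[, c("x1", "x2")])
  dat <- assign_and_respond(profiles, fixed_scheme("rct", 2, 2),
                            theta_confirm, sigma2 = 0)
  mu <- drop(trial_design_matrix(dat, spec) %*% theta_confirm)
  expect_equal(dat$y, mu)
  # the linked trial never gives a treatment to its unmatched-only subgroup
  x <- simulate_biomarkers(4000, c(0.3, 0.3))
  tdat <- assign_and_respond(x, fixed_scheme("linked", 2, 2),
                             theta_confirm, 1)
  expect_equal(nrow(tdat[tdat$x1 == 0 & tdat$x2 == 1 & tdat$arm == 1, ]), 0L)
  expect_equal(nrow(tdat[tdat$x1 == 1 & tdat$x2 == 0 & tdat$arm == 2, ]), 0L)
  expect_gt(nrow(tdat[tdat$x1 == 1 & tdat$x2 == 1 & tdat$arm == 1, ]), 0L)
  # unenrolled subgroups are excluded from the trial table
  sch <- fixed_scheme("rct", 2, 2)
  sch$enrolled[4] <- FALSE
  ddat <- assign_and_respond(x, sch, theta_confirm, 1)
  expect_equal(nrow(ddat[ddat$x1 == 1 & ddat$x2 == 1, ]), 0L)
  expect_equal(nrow(ddat), sum(!(x[, 1] == 1 & x[, 2] == 1)))
  # large-sample subgroup-arm mean matches its parameterization
  big <- assign_and_respond(simulate_biomarkers(2e4, c(0.5, 0.5)),
                            fixed_scheme("rct", 2, 2), theta_confirm, 1)
  cell <- big[big$x1 == 1 & big$x2 == 0 & big$arm == 1, ]
  mu_cell <- sum(theta_confirm[c("alpha", "gamma1", "beta1", "delta11")])
  expect_lt(abs(mean(cell$y) - mu_cell), 3 / sqrt(nrow(cell)))
})

test_that("least squares recovers noiseless parameters and matches lm", {
  spec <- regression_spec(2, 2)
  sup <- enumerate_support(2, 2)
  dat <- sup[rep(1:12, 2), ]
  dat$y <- rep(drop(trial_design_matrix(sup, spec) %*% theta_confirm), 2)
  fit <- fit_least_squares(dat, spec)
  expect_equal(unname(fit$theta_hat), unname(theta_confirm), tolerance = 1e-10)
  expect_equal(fit$sigma2_hat, 0, tolerance = 1e-20)
  set.seed(3)
  dat$y <- dat$y + rnorm(24)
  fit2 <- fit_least_squares(dat, spec)
  lmfit <- lm(y ~ arm1 + arm2 + x1 + x2 + x1:arm1 + x2:arm1 + x1:arm2 +
                x2:arm2,
              data = transform(dat, arm1 = as.numeric(arm == 1),
                               arm2 = as.numeric(arm == 2)))
  expect_equal(unname(fit2$theta_hat), unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(unname(fit2$cov), unname(vcov(lmfit)), tolerance = 1e-10)
  # rank deficiency is an error
  expect_error(fit_least_squares(dat[dat$arm != 2, ], spec),
               "rank deficient")
})

test_that("confirmatory simulation is internally consistent and reproducible", {
  res <- run_confirmatory(fixed_scheme("rct", 2, 2), theta_confirm, 1.15,
                          n = 400, prevalence = c(0.3, 0.3),
                          reps_bio = 5, reps_alloc = 10, seed = 1)
  expect_equal(res$encr,
               sum(res$table$rejection_rate[res$table$true_value < 0]))
  expect_equal(res$table$class,
               ifelse(res$table$true_value < 0, "power", "type1"))
  expect_true(all(res$table$rejection_rate >= 0 &
                    res$table$rejection_rate <= 1))
  res2 <- run_confirmatory(fixed_scheme("rct", 2, 2), theta_confirm, 1.15,
                           n = 400, prevalence = c(0.3, 0.3),
                           reps_bio = 5, reps_alloc = 10, seed = 1)
  expect_identical(res, res2)   # bit-reproducible under a fixed seed
})

test_that("type I error sits at the nominal level when every null is true", {
  theta0 <- setNames(rep(0, 9), full_term_labels(2, 2))
  theta0[c("alpha", "gamma1", "gamma2")] <- c(0.2, 1, 1)
  res <- run_confirmatory(fixed_scheme("rct", 2, 2), theta0, 1.15,
                          n = 500, prevalence = c(0.3, 0.3),
                          reps_bio = 40, reps_alloc = 40, seed = 1)
  expect_true(all(res$table$class == "type1"))
  # nested replication clusters, so allow a little beyond binomial error
  expect_true(all(abs(res$table$rejection_rate - 0.05) < 0.025))
  expect_equal(res$encr, 0)
})

test_that("simulated power tracks the analytic approximation", {
  ap <- analytic_power(fixed_scheme("linked", 2, 2), theta_confirm, 1.15,
                       n = 1000, prevalence = c(0.3, 0.3))
  res <- run_confirmatory(fixed_scheme("linked", 2, 2), theta_confirm, 1.15,
                          n = 1000, prevalence = c(0.3, 0.3),
                          reps_bio = 50, reps_alloc = 50, seed = 1)
  expect_true(all(abs(res$table$rejection_rate - ap) < 0.03))
})

test_that("analytic power is exact at the null and monotone in effect size", {
  sch <- fixed_scheme("rct", 2, 2)
  theta0 <- setNames(rep(0, 9), full_term_labels(2, 2))
  expect_equal(analytic_power(sch, theta0, 1.15, 1000, c(0.3, 0.3)),
               rep(0.05, 8))
  half <- theta_flat02
  half[c("beta1", "beta2", "delta12", "delta22")] <-
    half[c("beta1", "beta2", "delta12", "delta22")] / 2
  p_full <- analytic_power(sch, theta_flat02, 1.15, 1000, c(0.3, 0.3))
  p_half <- analytic_power(sch, half, 1.15, 1000, c(0.3, 0.3))
  idx <- c(1, 2, 7, 8)  # the false nulls
  expect_true(all(p_half[idx] < p_full[idx]))
  # doubling n never decreases power on the false nulls
  p_2n <- analytic_power(sch, theta_flat02, 1.15, 2000, c(0.3, 0.3))
  expect_true(all(p_2n[idx] >= p_full[idx]))
})

test_that("phase II simulation has the right schema and recovers parameters", {
  set.seed(4)
  d <- simulate_phase2(400, c(0.3, 0.3), theta_phase2, 1.15, K = 2)
  expect_named(d, c("id", "x1", "x2", "arm", "y"))
  expect_equal(nrow(d), 400L)
  expect_true(all(d$arm %in% 0:2))
  frac00 <- mean(d$x1 == 0 & d$x2 == 0)
  expect_lt(abs(frac00 - 0.49), 3 * sqrt(0.49 * 0.51 / 400))
  d0 <- simulate_phase2(50, c(0.3, 0.3),
                        setNames(rep(0, 9), full_term_labels(2, 2)),
                        0, K = 2)
  expect_equal(d0$y, rep(0, 50))
  # consistency at large n
  big <- simulate_phase2(40000, c(0.3, 0.3), theta_phase2, 1.15, K = 2)
  fit <- fit_least_squares(big, regression_spec(2, 2))
  expect_equal(unname(fit$theta_hat), unname(theta_phase2), tolerance = 0.06)
})
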
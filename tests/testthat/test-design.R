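# the worked reduced design problem: subgroup-matched hypotheses 1, 2, 7, 8
# on the 8-point support, with the illustration's bootstrap weights
worked_problem <- function() {
  cat22 <- contrast_catalogue(2, 2)
  red <- reduce_model(cat22[c(1, 2, 7, 8)], regression_spec(2, 2))
  design_problem(red$spec, red$contrasts, w = c(0.761, 0.683, 0.883, 0.501))
}

test_that("the criterion has its closed-form values on a two-point problem", {
  # intercept + slope on {control, treatment}: M = [[1, p2], [p2, p2]]
  spec <- regression_spec(1, 0)
  sup <- enumerate_support(1, 0)
  con <- contrast(c(beta1 = 1), r = 1)
  prob <- design_problem(spec, list(con), w = 1, support = sup)
  expect_equal(weighted_l_objective(c(0.5, 0.5), prob), 4)
  expect_equal(weighted_l_objective(c(0.25, 0.75), prob), 16 / 3)
  # singular allocation is flagged non-estimable
  expect_equal(weighted_l_objective(c(1, 0), prob), Inf)
})

test_that("the criterion is convex on the simplex", {
  prob <- worked_problem()
  m <- sum(prob$active)
  set.seed(1)
  for (it in 1:25) {
    p <- rgamma(m, 1); p <- p / sum(p)
    q <- rgamma(m, 1); q <- q / sum(q)
    lam <- runif(1)
    expect_lte(weighted_l_objective(lam * p + (1 - lam) * q, prob),
               lam * weighted_l_objective(p, prob) +
                 (1 - lam) * weighted_l_objective(q, prob) + 1e-9)
  }
})

test_that("a symmetric two-arm c-optimal problem allocates half and half", {
  spec <- regression_spec(1, 0)
  prob <- design_problem(spec, list(contrast(c(beta1 = 1), r = 1)), w = 1,
                         support = enumerate_support(1, 0))
  m <- solve_design(prob, seed = 1)
  expect_equal(m$p, c(0.5, 0.5), tolerance = 1e-5)
})

test_that("the solver matches a closed-form grid oracle on a 3-cell problem", {
  # control + two treatments, no biomarkers, saturated model: each
  # treatment-vs-control variance is 1/p0 + 1/pk in closed form
  spec <- regression_spec(2, 0)
  sup <- enumerate_support(2, 0)
  cons <- list(contrast(c(beta1 = 1), r = 1), contrast(c(beta2 = 1), r = 2))
  w <- c(1, 0.4)
  prob <- design_problem(spec, cons, w = w, support = sup)
  grid <- expand.grid(p0 = seq(0.001, 0.998, by = 0.001),
                      p1 = seq(0.001, 0.998, by = 0.001))
  grid <- grid[grid$p0 + grid$p1 < 0.999, ]
  obj <- saturated_objective(grid$p0, grid$p1, 1 - grid$p0 - grid$p1,
                             w[1], w[2])
  best_grid <- grid[which.min(obj), ]
  m <- solve_design(prob, seed = 1)
  expect_equal(m$p[1], best_grid$p0, tolerance = 2e-3)
  expect_equal(m$p[2], best_grid$p1, tolerance = 2e-3)
  # closed-form optimum: p0 : p1 : p2 = sqrt(w1+w2) : sqrt(w1) : sqrt(w2)
  exact <- sqrt(c(w[1] + w[2], w[1], w[2]))
  exact <- exact / sum(exact)
  expect_equal(m$p, exact, tolerance = 1e-4)
  expect_equal(weighted_l_objective(m$p, prob),
               saturated_objective(exact[1], exact[2], exact[3], w[1], w[2]),
               tolerance = 1e-6)
})

test_that("the optimum dominates equal allocation and random designs", {
  prob <- worked_problem()
  m <- solve_design(prob, seed = 1)
  opt <- m$objective
  meq <- sum(prob$active)
  expect_lt(opt, weighted_l_objective(rep(1 / meq, meq), prob))
  set.seed(2)
  for (it in 1:100) {
    p <- rgamma(meq, 1); p <- p / sum(p)
    expect_lte(opt, weighted_l_objective(p, prob) + 1e-9)
  }
})

test_that("multistart solutions agree and weights scale out", {
  prob <- worked_problem()
  m1 <- solve_design(prob, starts = 5, seed = 1)
  expect_lt(diff(range(m1$start_objectives)) / m1$objective, 1e-6)
  m2 <- solve_design(prob, starts = 5, seed = 99)
  expect_equal(m1$p, m2$p, tolerance = 1e-3)
  expect_lt(m1$gap, 1e-6)
  # multiplying every weight by a constant moves the criterion, not the argmin
  prob10 <- worked_problem()
  prob10$w <- prob10$w * 10
  m10 <- solve_design(prob10, seed = 1)
  expect_equal(m10$p, m1$p, tolerance = 1e-4)
  expect_equal(m10$objective, 10 * m1$objective, tolerance = 1e-8)
})

test_that("exclusions pin proportions to zero and match the restricted support", {
  cat22 <- contrast_catalogue(2, 2)
  red <- reduce_model(cat22[c(1, 2, 7, 8)], regression_spec(2, 2))
  w <- c(0.761, 0.683, 0.883, 0.501)
  full_sup <- enumerate_support(2, 2)
  prob_ex <- design_problem(red$spec, red$contrasts, w = w,
                            support = full_sup,
                            exclusions = c(3, 5, 9, 11))
  m_ex <- solve_design(prob_ex, seed = 1)
  expect_true(all(m_ex$p[c(3, 5, 9, 11)] == 0))
  m_sub <- solve_design(worked_problem(), seed = 1)
  expect_equal(m_ex$p[-c(3, 5, 9, 11)], m_sub$p, tolerance = 1e-4)
})

test_that("design measures convert to per-subgroup randomization probabilities", {
  # equal mass on all 12 points: every subgroup randomizes 1/3 each
  sup <- enumerate_support(2, 2)
  eq <- list(support = sup, p = rep(1 / 12, 12))
  sch <- to_randomization_scheme(eq, K = 2, L = 2)
  expect_true(all(sch$enrolled))
  for (a in 0:2) expect_equal(sch[[paste0("arm", a)]], rep(1 / 3, 4))
  # probabilities per enrolled subgroup sum to one exactly
  m <- solve_design(worked_problem(), seed = 1)
  sch2 <- to_randomization_scheme(m)
  expect_equal(unname(rowSums(as.matrix(sch2[sch2$enrolled, paste0("arm", 0:2)]))),
               rep(1, sum(sch2$enrolled)))
  # a subgroup with no mass is not enrolled
  p0 <- rep(1 / 9, 12)
  p0[10:12] <- 0
  sch3 <- to_randomization_scheme(list(support = sup, p = p0), K = 2, L = 2)
  expect_equal(sch3$enrolled, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(is.na(sch3[4, paste0("arm", 0:2)])))
  expect_error(to_randomization_scheme(list(support = sup, p = rep(0, 12)),
                                       K = 2, L = 2), "no mass")
})

test_that("fixed comparator schemes reproduce the standard allocations", {
  rct <- fixed_scheme("rct", 2, 2)
  for (a in 0:2) expect_equal(rct[[paste0("arm", a)]], rep(1 / 3, 4))
  tlt <- fixed_scheme("linked", 2, 2)
  # profile order: (0,0), (0,1), (1,0), (1,1)
  expect_equal(unname(as.matrix(tlt[, paste0("arm", 0:2)])),
               rbind(c(1 / 3, 1 / 3, 1 / 3),
                     c(1 / 2, 0, 1 / 2),
                     c(1 / 2, 1 / 2, 0),
                     c(1 / 3, 1 / 3, 1 / 3)))
  expect_error(fixed_scheme("linked", 2, 2, linkage = c(1, 5)))
  expect_error(fixed_scheme("linked", 3, 2))  # default linkage needs K <= L
})
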
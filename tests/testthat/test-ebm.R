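test_that("data-driven epsilon and weights match the hand-computed
           affinity index", {
  y <- matrix(c(1, 1, 1), 1)
  # proportional input rows: affinity 1, no diversity, epsilon 0
  p <- determine_epsilon_weights(rbind(c(1, 2, 3), c(2, 4, 6)), y,
                                 common_epsilon = FALSE)
  expect_equal(p$epsilon_in, 0)
  # rows (1,10,1) and (10,1,1): log ratios (-ln10, ln10, 0) give mean
  # absolute deviation ln10 * 2/3 over range 2 ln10, so D = 1/3,
  # affinity 1/3, top eigenvalue 4/3, epsilon (2 - 4/3)/(2 - 1) = 2/3
  p2 <- determine_epsilon_weights(rbind(c(1, 10, 1), c(10, 1, 1)), y,
                                  common_epsilon = FALSE)
  expect_equal(p2$epsilon_in, 2 / 3, tolerance = 1e-10)
  expect_equal(p2$w_in, c(0.5, 0.5), tolerance = 1e-10)
  # single input: no non-radial content
  p3 <- determine_epsilon_weights(matrix(c(1, 2, 3), 1), y,
                                  common_epsilon = FALSE)
  expect_equal(p3$epsilon_in, 0)
  expect_equal(p3$w_in, 1)
})

test_that("non-oriented radial super-efficiency solves the two-unit case
           and duplicates support each other at 1", {
  X <- matrix(c(1, 2), 1); Y <- matrix(c(1, 1), 1)
  p0 <- ebm_params(0, 0, w_in = 1, w_out = 1)
  expect_equal(solve_ebm_super(X, Y, NULL, 1, p0)$gamma, 2,
               tolerance = 1e-8)
  expect_equal(solve_ebm_super(X, Y, NULL, 2, p0)$gamma, 0.5,
               tolerance = 1e-8)
  Xt <- matrix(c(1.3, 1.3), 1); Yt <- matrix(c(0.7, 0.7), 1)
  for (k in 1:2)
    expect_equal(solve_ebm_super(Xt, Yt, NULL, k,
                                 ebm_params(0.5, 0.5, 1, 1))$gamma, 1,
                 tolerance = 1e-8)
})

test_that("epsilon = 0 reproduces the radial model and theta = epsilon = 1
           reproduces the slack-based model", {
  set.seed(101)
  for (i in 1:50) {
    inst <- random_instance(8, 2, 1, 1)
    pr <- ebm_params(0, 0, w_in = c(.5, .5), w_out = .5, w_bad = .5)
    ps <- ebm_params(1, 1, w_in = c(.5, .5), w_out = .5, w_bad = .5)
    for (k in 1:8) {
      e0 <- solve_ebm_super(inst$x, inst$y, inst$u, k, params = pr)
      r0 <- solve_radial_super(inst$x, inst$y, inst$u, k)
      expect_equal(e0$feasible, r0$feasible)
      if (e0$feasible)
        expect_equal(e0$gamma, r0$gamma, tolerance = 1e-6)
      es <- solve_ebm_super(inst$x, inst$y, inst$u, k, params = ps,
                            form = "sbm")
      rs <- solve_sbm_super(inst$x, inst$y, inst$u, k,
                            w_in = c(.5, .5), w_out = .5, w_bad = .5)
      expect_equal(es$feasible, rs$feasible)
      if (es$feasible)
        expect_equal(es$gamma, rs$gamma, tolerance = 1e-6)
    }
  }
})

test_that("scores match the grid/refinement oracle on small instances", {
  set.seed(202)
  for (i in 1:12) {
    n <- sample(2:3, 1); m <- sample(1:2, 1); q <- sample(0:2, 1)
    inst <- random_instance(n, m, 1, q)
    p <- determine_epsilon_weights(inst$x, inst$y, inst$u)
    for (k in seq_len(n)) {
      lp <- solve_ebm_super(inst$x, inst$y, inst$u, k, params = p)
      or <- oracle_ebm(inst$x, inst$y, inst$u, k, p)
      if (!lp$feasible) {
        expect_true(is.na(or))
      } else {
        expect_equal(lp$gamma, or, tolerance = 1e-4)
      }
    }
  }
})

test_that("scores are invariant to rescaling any variable", {
  set.seed(303)
  inst <- random_instance(8, 2, 1, 1)
  p <- determine_epsilon_weights(inst$x, inst$y, inst$u)
  g1 <- vapply(1:8, function(k)
    solve_ebm_super(inst$x, inst$y, inst$u, k, params = p)$gamma,
    numeric(1))
  x2 <- inst$x; x2[2, ] <- x2[2, ] * 1000
  y2 <- inst$y * 0.01
  u2 <- inst$u * 50
  p2 <- determine_epsilon_weights(x2, y2, u2)
  expect_equal(p2$epsilon_in, p$epsilon_in, tolerance = 1e-10)
  g2 <- vapply(1:8, function(k)
    solve_ebm_super(x2, y2, u2, k, params = p2)$gamma, numeric(1))
  expect_equal(g1, g2, tolerance = 1e-8)
})

test_that("weakly worsening the evaluated unit never raises its score", {
  set.seed(404)
  for (i in 1:10) {
    inst <- random_instance(6, 2, 1, 1)
    p <- ebm_params(0.4, 0.4, c(.6, .4), .7, .3)
    k <- sample(6, 1)
    base <- solve_ebm_super(inst$x, inst$y, inst$u, k, params = p)
    worse <- inst
    worse$x[, k] <- worse$x[, k] * runif(2, 1, 1.5)
    worse$y[, k] <- worse$y[, k] * runif(1, 0.7, 1)
    worse$u[, k] <- worse$u[, k] * runif(1, 1, 1.5)
    w <- solve_ebm_super(worse$x, worse$y, worse$u, k, params = p)
    if (base$feasible && w$feasible)
      expect_lte(w$gamma, base$gamma + 1e-7)
  }
})

test_that("super-efficiency agrees with the full-reference score for
           inefficient units and infeasible cells are flagged", {
  set.seed(505)
  saw_infeasible <- FALSE
  for (i in 1:10) {
    inst <- random_instance(8, 2, 1, 1)
    p <- determine_epsilon_weights(inst$x, inst$y, inst$u)
    for (k in 1:8) {
      s1 <- solve_ebm_super(inst$x, inst$y, inst$u, k, params = p)
      s0 <- solve_ebm_super(inst$x, inst$y, inst$u, k, params = p,
                            super = FALSE)
      expect_true(s0$feasible)
      if (!s1$feasible) { saw_infeasible <- TRUE; next }
      if (s0$gamma < 1 - 1e-6)
        expect_equal(s1$gamma, s0$gamma, tolerance = 1e-6)
      expect_true(all(s1$lambda >= -1e-10))
      expect_equal(s1$lambda[k], 0)
    }
  }
  expect_true(saw_infeasible)  # the known pathology occurs and is flagged
})

test_that("panel scoring is deterministic and ignores dominated entrants", {
  gen <- generate_frontier_panel(frontier_spec(n_units = 10, n_years = 2,
                                               seed = 7))
  t1 <- score_panel(gen$panel)
  t2 <- score_panel(gen$panel)
  expect_identical(t1$scores, t2$scores)
  # add a unit strictly dominated by unit 1 of a 5-unit cross-section
  inst <- random_instance(5, 2, 1, 1)
  p <- ebm_params(0.3, 0.3, c(.5, .5), .6, .4)
  base <- vapply(1:5, function(k)
    solve_ebm_super(inst$x, inst$y, inst$u, k, params = p)$gamma,
    numeric(1))
  x6 <- cbind(inst$x, inst$x[, 1] * 1.4)
  y6 <- cbind(inst$y, inst$y[, 1] * 0.7)
  u6 <- cbind(inst$u, inst$u[, 1] * 1.4)
  after <- vapply(1:5, function(k)
    solve_ebm_super(x6, y6, u6, k, params = p)$gamma, numeric(1))
  expect_equal(after, base, tolerance = 1e-7)
})

test_that("scale efficiency is TE/PTE and CRS never beats VRS", {
  expect_equal(decompose_efficiency(0.6, 0.8), 0.75)
  expect_equal(decompose_efficiency(0.7, 0.7), 1)
  expect_error(decompose_efficiency(0.5, 0), "> 0")
  set.seed(606)
  for (i in 1:20) {
    inst <- random_instance(8, 2, 1, 1)
    p <- determine_epsilon_weights(inst$x, inst$y, inst$u)
    pv <- ebm_params(p$epsilon_in, p$epsilon_out, p$w_in, p$w_out,
                     p$w_bad, "vrs")
    for (k in 1:8) {
      te <- solve_ebm_super(inst$x, inst$y, inst$u, k, params = p,
                            super = FALSE)$gamma
      pte <- solve_ebm_super(inst$x, inst$y, inst$u, k, params = pv,
                             super = FALSE)$gamma
      expect_lte(te, pte + 1e-7)
      expect_lte(decompose_efficiency(te, pte), 1 + 1e-7)
    }
  }
})
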
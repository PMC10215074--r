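test_that("matched curves with clean convergence give exactly zero", {
  ref <- toy_trace(strain = 0.02, kin = 1.5)
  spec <- objective_spec(c("ap", "PCL"), c(1, 1), ref)
  val <- objective_from_trace(toy_trace(strain = 0.02, kin = 1.5), spec)
  expect_identical(as.numeric(val), 0)
  expect_false(attr(val, "penalized"))
})

test_that("a unit constant deviation on one variable contributes exactly w", {
  ref <- toy_trace()
  tr <- toy_trace()
  tr$pose$ap <- tr$pose$ap + 1
  for (w in c(1, 2.5, 8)) {
    spec <- objective_spec(c("ap", "lm"), c(w, 1), ref)
    expect_equal(as.numeric(objective_from_trace(tr, spec)), w)
  }
})

test_that("objective is linear in the weights", {
  ref <- toy_trace()
  tr <- toy_trace(kin = 0.7, strain = 0.01)
  v <- tkaplan:::KIN_VARS
  s1 <- objective_spec(v, rep(1, 5), ref)
  s2 <- objective_spec(v, rep(2, 5), ref)
  expect_equal(2 * as.numeric(objective_from_trace(tr, s1)),
               as.numeric(objective_from_trace(tr, s2)))
})

test_that("a residual above 5 N adds the penalty exactly once", {
  ref <- toy_trace()
  spec <- objective_spec("ap", 1, ref)
  tr <- toy_trace()
  tr$residual[3] <- 6
  expect_equal(as.numeric(objective_from_trace(tr, spec)), 1e3)
  tr$residual[5] <- 7        # second trigger, same condition class
  expect_equal(as.numeric(objective_from_trace(tr, spec)), 1e3)
  tr$residual <- rep(0, 5); tr$converged[2] <- FALSE
  expect_equal(as.numeric(objective_from_trace(tr, spec)), 1e3)
})

test_that("a strain above its pre-diseased peak adds the penalty", {
  ref <- toy_trace(strain = 0.02)
  caps <- apply(ref$strain, 2, max)
  spec <- objective_spec("PCL", 1, ref, strain_caps = caps)
  tr <- toy_trace(strain = 0.02)
  expect_equal(as.numeric(objective_from_trace(tr, spec)), 0)
  tr$strain[4, "LCL"] <- 0.03   # exceeds its cap (not even an objective variable)
  val <- objective_from_trace(tr, spec)
  expect_equal(as.numeric(val), 1e3)
  expect_true(attr(val, "strain_penalty"))
})

test_that("traces on different grids are rejected", {
  spec <- objective_spec("ap", 1, toy_trace(t = 5))
  expect_error(objective_from_trace(toy_trace(t = 7), spec), "grid")
})

test_that("the five surgical targets have the specified structure", {
  pre <- default_pre_trace(); ma <- default_ma_trace()
  st1 <- make_target("ST1", ma, pre)
  expect_equal(st1$variables, c("ap", "lm", "pd", "ei", "vv"))
  expect_equal(unname(st1$weights), rep(1, 5))
  st2 <- make_target("ST2", ma, pre)
  expect_equal(st2$variables,
               c("PCL", "dMCL", "sMCL", "LCL", "ALL", "OPL", "PC"))
  expect_equal(unname(st2$weights), rep(1, 7))
  st3 <- make_target("ST3", ma, pre)
  expect_equal(unname(st3$weights[c("sMCL", "dMCL", "LCL")]), rep(8, 3))
  expect_equal(sum(st3$weights == 8), 3)
  expect_equal(sum(st3$weights == 1), 4)
  st4 <- make_target("ST4", ma, pre)
  expect_equal(st4$strain_caps,
               apply(pre$strain[, st4$variables], 2, max))
  st5 <- make_target("ST5", ma, pre)
  expect_equal(length(st5$variables), 12)
})

test_that("ST5 blocks contribute equally at the MA baseline by construction", {
  pre <- default_pre_trace(); ma <- default_ma_trace()
  st5 <- make_target("ST5", ma, pre)
  kin_part <- sum(vapply(tkaplan:::KIN_VARS, function(v)
    st5$weights[[v]] * mean((ma$pose[[v]] - pre$pose[[v]])^2), numeric(1)))
  str_part <- sum(vapply(tkaplan:::STRAIN_VARS, function(v)
    st5$weights[[v]] * mean((ma$strain[, v] - pre$strain[, v])^2), numeric(1)))
  expect_equal(kin_part, 0.5, tolerance = 1e-9)
  expect_equal(str_part, 0.5, tolerance = 1e-9)
})

test_that("CMA-ES recovers the minimizer of a bowl to 1e-3", {
  x_true <- c(0.3, -1.2, 2.0, 0.7)
  fn <- function(x) sum((x - x_true)^2) + 1
  res <- cmaes(fn, x0 = rep(0, 4), sigma0 = 1, popsize = 12,
               max_evals = 1500, seed = 3)
  expect_equal(res$x_best, x_true, tolerance = 1e-3)
  expect_equal(res$f_best, 1, tolerance = 1e-6)
  # reproducibility
  res2 <- cmaes(fn, x0 = rep(0, 4), sigma0 = 1, popsize = 12,
                max_evals = 1500, seed = 3)
  expect_identical(res$fs, res2$fs)
})

test_that("optimization never returns worse than the MA start", {
  ht <- fixture("ht_smoke", function()
    make_hidden_truth(patient_spec(seed = 2),
                      implant_placement(fem_pd = 1.5, tib_fe = 2)))
  st1 <- make_target("ST1", ht$ma_trace, ht$reference)
  sim <- placement_simulator(ht$ma_model)
  opt <- fixture("opt_smoke", function()
    optimize_placement(st1, sim, seed = 5, max_evals = 300))
  expect_lte(opt$best_objective, opt$ma_objective)
  expect_true(all(opt$candidates$objective >= opt$best_objective))
  # every stored candidate respects the bounds
  b <- placement_bounds()
  X <- as.matrix(opt$candidates[tkaplan:::PLACEMENT_NAMES])
  expect_true(all(sweep(X, 2, as.numeric(b$lower), ">=") &
                  sweep(X, 2, as.numeric(b$upper), "<=")))
})

test_that("select_clinical matches a brute-force scan of the candidates", {
  set.seed(9)
  n <- 400
  cand <- as.data.frame(matrix(stats::runif(9 * n, -6, 6), n, 9))
  names(cand) <- tkaplan:::PLACEMENT_NAMES
  cand$fem_fe <- cand$fem_fe / 2         # respect the tighter FE bound
  cand$objective <- stats::runif(n, 1, 2)
  cand$feasible <- TRUE
  cand$eval <- seq_len(n)
  b <- placement_bounds()
  res <- structure(list(candidates = cand, bounds = b, tol_rel = 0.05),
                   class = "placement_opt")
  for (tol_rel in c(0, 0.05, 0.3)) {
    sel <- select_clinical(res, tol_rel)
    # brute force: filter, normalize, minimize
    fbest <- min(cand$objective)
    near <- cand[cand$objective <= (1 + tol_rel) * fbest, ]
    half <- (as.numeric(b$upper) - as.numeric(b$lower)) / 2
    dev <- apply(near[, 1:9], 1, function(r) sqrt(sum((r / half)^2)))
    expect_equal(as.numeric(sel),
                 as.numeric(near[which.min(dev), 1:9, drop = TRUE]))
  }
  # tol_rel = 0 returns the best candidate
  sel0 <- select_clinical(res, 0)
  expect_equal(as.numeric(sel0),
               as.numeric(cand[which.min(cand$objective), 1:9]))
})

test_that("a near-optimal MA candidate is always preferred", {
  cand <- data.frame(matrix(c(rep(0, 9), rep(2, 9)), 2, 9, byrow = TRUE))
  names(cand) <- tkaplan:::PLACEMENT_NAMES
  cand$objective <- c(1.02, 1.0)
  cand$feasible <- TRUE
  cand$eval <- 1:2
  res <- structure(list(candidates = cand, bounds = placement_bounds(),
                        tol_rel = 0.05), class = "placement_opt")
  expect_equal(as.numeric(select_clinical(res, 0.05)), rep(0, 9))
})

test_that("the peak-capped optimum respects every pre-diseased strain peak", {
  pre <- default_pre_trace(); ma <- default_ma_trace()
  st4 <- make_target("ST4", ma, pre)
  sim <- placement_simulator(default_ma_model())
  opt <- optimize_placement(st4, sim, seed = 11, max_evals = 600)
  expect_lt(opt$best_objective, st4$penalty)   # a penalty-free solution exists
  tr <- sim(opt$selected)
  for (lg in names(st4$strain_caps))
    expect_true(all(tr$strain[, lg] <= st4$strain_caps[[lg]] + 1e-9))
})
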
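test_that("sum of squared deviations matches hand computation", {
  sim <- tibble::tibble(
    subset = rep(c("T3", "mature"), each = 2),
    time_days = rep(c(1, 2), 2),
    labeled = c(10, 20, 30, 40)
  )
  # data identical to the simulation: SS = 0
  data0 <- sim |> dplyr::rename(labeled_count = labeled) |>
    dplyr::mutate(mouse_id = 1L)
  expect_equal(sum_squared_deviations(sim, data0), 0)

  # two points with residuals 3 and 4: SS = 25
  data1 <- data0
  data1$labeled_count <- c(13, 20, 34, 40)
  expect_equal(sum_squared_deviations(sim, data1), 25)

  # replicate observations each contribute a term
  data2 <- dplyr::bind_rows(data0, data1)
  expect_equal(sum_squared_deviations(sim, data2), 25)

  # 3 subsets x 4 times vs a constant simulation, summed by hand
  sim3 <- tidyr::crossing(subset = c("T12", "T3", "mature"),
                          time_days = 1:4) |>
    dplyr::mutate(labeled = 100)
  data3 <- sim3 |> dplyr::rename(labeled_count = labeled) |>
    dplyr::mutate(labeled_count = 100 + seq(-6, 5), mouse_id = 1L)
  hand <- sum(seq(-6, 5)^2)  # 146
  expect_equal(sum_squared_deviations(sim3, data3,
                                      subsets = c("T12", "T3", "mature")),
               hand)

  # a data point with no simulated counterpart is an alignment error
  data4 <- data0
  data4$time_days[1] <- 1.5
  expect_error(sum_squared_deviations(sim, data4),
               class = "bk_alignment_error")
})

test_that("parameter grids validate and report cardinality", {
  expect_error(parameter_grid(toy_spleen(), vary = list()),
               class = "bk_invalid_grid")
  expect_error(parameter_grid(toy_spleen(), vary = list(bogus = 1:3)),
               class = "bk_invalid_grid")
  expect_error(parameter_grid(toy_spleen(), vary = list(mu_3 = c(-1, 0))),
               class = "bk_invalid_grid")
  g <- parameter_grid(toy_spleen(), vary = list(mu_3 = c(0.1, 0.2, 0.3),
                                                delta_23 = c(0, 0.1)))
  expect_equal(g$cardinality, 6)
  expect_equal(grid_seq(0, 0.05, 0.01), seq(0, 0.05, 0.01))
  # upper bound is kept even when the step does not divide the range
  expect_equal(max(grid_seq(0, 0.055, 0.01)), 0.055)
  d <- default_spleen_grid()
  expect_true(all(c("f1", "mu_3", "delta_m3") %in% names(d$vary)))
  # edge-absence hypothesis: ranges reaching zero include zero
  expect_true(0 %in% d$vary$f3)
  expect_true(0 %in% d$vary$mu_m)
})

test_that("constraint screening passes/fails for the stated reasons", {
  p <- toy_bm()
  q <- toy_spleen()
  # unbounded windows on everything: always pass
  free <- constraint_set(
    totals = tibble::tibble(subset = splenic_subsets(), lower = -Inf,
                            upper = Inf),
    composition = tibble::tibble(subset = splenic_subsets(), lower = 0,
                                 upper = 1),
    max_steady_days = Inf
  )
  expect_true(passes_constraints(p, q, m2t3(), free)$pass)

  # time limit zero: always fails on the time criterion
  t0 <- constraint_set(max_steady_days = 0)
  sc <- passes_constraints(p, q, m2t3(), t0)
  expect_false(sc$pass)
  bad <- sc$diagnostics[!sc$diagnostics$pass, ]
  expect_equal(bad$criterion, "time_to_steady")

  # violated totals window is named in the diagnostics
  sp <- spleen_steady_state(q, m2t3(), attr(bm_steady_state(p), "influx"))
  tight <- constraint_set(
    totals = tibble::tibble(subset = "T3",
                            lower = sp$count[sp$subset == "T3"] * 2,
                            upper = sp$count[sp$subset == "T3"] * 3),
    max_steady_days = Inf
  )
  sc2 <- passes_constraints(p, q, m2t3(), tight)
  expect_false(sc2$pass)
  expect_true(any(sc2$diagnostics$criterion == "total" &
                    !sc2$diagnostics$pass))

  # fast toy dynamics do arrive within a generous window
  ok <- passes_constraints(p, q, m2t3(), constraint_set(max_steady_days = 30,
                                                        time_subsets = splenic_subsets()))
  expect_true(ok$pass)
})

test_that("screening is self-consistent for the best-fit reference model", {
  setup <- best_fit_setup()
  ds <- generate_dataset(setup$p, setup$q, setup$topo,
                         design = quick_design(), noise = noise_model(0.10),
                         seed = 5)
  cons <- dataset_to_constraints(ds, padding = 0.1, max_steady_days = 365,
                                 time_subsets = c("T12", "T3"))
  expect_true(passes_constraints(setup$p, setup$q, setup$topo, cons)$pass)
})

test_that("grid search enumerates lexicographically and is deterministic", {
  setup <- best_fit_setup()
  ds <- generate_dataset(setup$p, setup$q, setup$topo,
                         design = quick_design(1), noise = noise_model(0),
                         seed = 1)
  g <- parameter_grid(setup$q, vary = list(delta_23 = c(0.09, 0.1),
                                           mu_3 = c(0.16, 0.17)))
  cons <- constraint_set(max_steady_days = Inf)
  fit <- grid_search(g, ds, cons, setup$topo, bm = setup$p, bands = NULL)
  expect_equal(fit$evaluations$delta_23, c(0.09, 0.09, 0.1, 0.1))
  expect_equal(fit$evaluations$mu_3, c(0.16, 0.17, 0.16, 0.17))
  fit2 <- grid_search(g, ds, cons, setup$topo, bm = setup$p, bands = NULL)
  expect_identical(fit$evaluations, fit2$evaluations)
  expect_identical(unclass(fit$best), unclass(fit2$best))
})

test_that("the constrained minimum lands on the grid point nearest the optimum", {
  setup <- best_fit_setup()
  ds <- generate_dataset(setup$p, setup$q, setup$topo,
                         design = quick_design(1), noise = noise_model(0),
                         seed = 1)
  # truth delta_23 = 0.1 lies off-grid; 0.105 is closest on a smooth SS profile
  g <- parameter_grid(setup$q, vary = list(delta_23 = c(0.07, 0.09, 0.105,
                                                        0.13)))
  fit <- grid_search(g, ds, constraint_set(max_steady_days = Inf), setup$topo,
                     bm = setup$p, bands = NULL)
  expect_equal(fit$best$delta_23, 0.105)
  # SS grows away from the optimum on either side
  ss_of <- function(v) fit$evaluations$ss[fit$evaluations$delta_23 == v]
  expect_lt(ss_of(0.105), ss_of(0.13))
  expect_lt(ss_of(0.105), ss_of(0.09))
  expect_lt(ss_of(0.09), ss_of(0.07))
})

test_that("zero-noise on-grid truth is recovered exactly", {
  setup <- best_fit_setup()
  ds <- generate_dataset(setup$p, setup$q, setup$topo,
                         design = quick_design(1), noise = noise_model(0),
                         seed = 1)
  g <- parameter_grid(setup$q,
                      vary = list(delta_23 = grid_seq(0.08, 0.12, 0.01),
                                  mu_3 = grid_seq(0.15, 0.19, 0.01)))
  fit <- grid_search(g, ds, constraint_set(max_steady_days = Inf), setup$topo,
                     bm = setup$p, bands = NULL)
  expect_equal(fit$best$delta_23, 0.1)
  expect_equal(fit$best$mu_3, 0.17)
  expect_lt(fit$ss, 1)  # residual is only engine-path round-off
})

test_that("grid search equals an independent brute-force loop", {
  setup <- best_fit_setup()
  ds <- generate_dataset(setup$p, setup$q, setup$topo,
                         design = quick_design(2), noise = noise_model(0.1),
                         seed = 8)
  cons <- dataset_to_constraints(ds, max_steady_days = Inf)
  g <- parameter_grid(setup$q,
                      vary = list(delta_23 = c(0.08, 0.1, 0.12),
                                  mu_3 = c(0.15, 0.17, 0.19)))
  fit <- grid_search(g, ds, cons, setup$topo, bm = setup$p, bands = NULL)
  # oracle: public scalar screen + fully coupled simulation per point
  bf <- brute_force_search(
    g, ds, cons, setup$topo,
    sim_fun = function(qi) simulate_brdu(setup$p, qi, setup$topo,
                                         sample_days = unique(ds$time_days)),
    bm = setup$p
  )
  expect_equal(fit$n_passing, bf$n_passing)
  expect_equal(fit$best$delta_23, bf$best$delta_23)
  expect_equal(fit$best$mu_3, bf$best$mu_3)
  expect_equal(fit$ss, bf$ss, tolerance = 1e-4)
})

test_that("enlarging a grid never increases the minimal SS", {
  setup <- best_fit_setup()
  ds <- generate_dataset(setup$p, setup$q, setup$topo,
                         design = quick_design(2), noise = noise_model(0.1),
                         seed = 21)
  cons <- constraint_set(max_steady_days = Inf)
  g_small <- parameter_grid(setup$q, vary = list(mu_3 = c(0.15, 0.19)))
  g_big <- parameter_grid(setup$q, vary = list(mu_3 = c(0.15, 0.16, 0.17,
                                                        0.19)))
  f_small <- grid_search(g_small, ds, cons, setup$topo, bm = setup$p,
                         bands = NULL)
  f_big <- grid_search(g_big, ds, cons, setup$topo, bm = setup$p,
                       bands = NULL)
  expect_lte(f_big$ss, f_small$ss)
})

test_that("oversized grids are refused with the computed cardinality", {
  g <- parameter_grid(toy_spleen(), vary = list(mu_3 = seq(0.1, 0.3, 0.01)))
  err <- expect_error(
    grid_search(g, tibble::tibble(), constraint_set(), m2t3(),
                max_points = 10),
    class = "bk_grid_too_large"
  )
  expect_match(conditionMessage(err), "21")
})

test_that("varying a topologically absent edge is refused", {
  setup <- best_fit_setup()
  ds <- generate_dataset(setup$p, setup$q, setup$topo,
                         design = quick_design(1), noise = noise_model(0),
                         seed = 1)
  g <- parameter_grid(setup$q, vary = list(delta_3m = c(0, 0.004)))
  expect_error(
    grid_search(g, ds, constraint_set(), setup$topo, bm = setup$p),
    class = "bk_topology_mismatch"
  )
})

test_that("an empty feasible set is a result, not an error", {
  setup <- best_fit_setup()
  ds <- generate_dataset(setup$p, setup$q, setup$topo,
                         design = quick_design(1), noise = noise_model(0),
                         seed = 1)
  cons <- constraint_set(
    totals = tibble::tibble(subset = "T3", lower = 1, upper = 2),
    max_steady_days = Inf
  )
  g <- parameter_grid(setup$q, vary = list(mu_3 = c(0.15, 0.17)))
  fit <- grid_search(g, ds, cons, setup$topo, bm = setup$p, bands = NULL)
  expect_null(fit$best)
  expect_equal(fit$ss, Inf)
  expect_equal(fit$n_passing, 0)
  expect_equal(nrow(fit$ranges), 0)  # empty-range report
})

test_that("acceptable ranges respond to the error bands as documented", {
  setup <- best_fit_setup()
  days <- quick_design(1)$sample_days
  ds <- generate_dataset(setup$p, setup$q, setup$topo,
                         design = quick_design(1), noise = noise_model(0),
                         seed = 1)
  g <- parameter_grid(setup$q,
                      vary = list(mu_3 = grid_seq(0.15, 0.19, 0.01)))
  cons <- constraint_set(max_steady_days = Inf)
  sim_truth <- simulate_brdu(setup$p, setup$q, setup$topo, sample_days = days)
  sim_truth <- sim_truth[sim_truth$subset %in% c("T3", "mature"), ]

  # bands a single cell wide admit only the generating point
  tight <- tibble::tibble(subset = sim_truth$subset,
                          time_days = sim_truth$time_days,
                          lower = sim_truth$labeled - 1,
                          upper = sim_truth$labeled + 1)
  fit_tight <- grid_search(g, ds, cons, setup$topo, bm = setup$p,
                           bands = tight)
  expect_equal(fit_tight$ranges$lower, 0.17)
  expect_equal(fit_tight$ranges$upper, 0.17)
  expect_equal(attr(fit_tight$ranges, "n_accepted"), 1L)

  # bands admitting everything: the range spans the whole grid
  wide <- tight |> dplyr::mutate(lower = 0, upper = Inf)
  fit_wide <- grid_search(g, ds, cons, setup$topo, bm = setup$p,
                          bands = wide)
  expect_equal(fit_wide$ranges$lower, 0.15)
  expect_equal(fit_wide$ranges$upper, 0.19)
  # re-thresholding an existing fit against new bands matches a fresh search
  re <- acceptable_ranges(fit_tight, bands = wide)
  expect_equal(re$lower, fit_wide$ranges$lower)
  expect_equal(re$upper, fit_wide$ranges$upper)
})

test_that("fitting all three subsets is supported", {
  setup <- best_fit_setup()
  ds <- generate_dataset(setup$p, setup$q, setup$topo,
                         design = quick_design(2), noise = noise_model(0.1),
                         seed = 31)
  g <- parameter_grid(setup$q, vary = list(mu_3 = c(0.15, 0.17, 0.19)))
  fit <- grid_search(g, ds, constraint_set(max_steady_days = Inf), setup$topo,
                     bm = setup$p, subsets = c("T12", "T3", "mature"),
                     bands = NULL)
  expect_equal(fit$n_obs, nrow(ds))
  expect_equal(fit$best$mu_3, 0.17)
})

test_that("tidy and glance summarise a fit", {
  setup <- best_fit_setup()
  ds <- generate_dataset(setup$p, setup$q, setup$topo,
                         design = quick_design(3), noise = noise_model(0.1),
                         seed = 41)
  g <- parameter_grid(setup$q, vary = list(mu_3 = grid_seq(0.15, 0.19, 0.01),
                                           delta_23 = grid_seq(0.08, 0.12, 0.01)))
  fit <- grid_search(g, ds, dataset_to_constraints(ds, max_steady_days = Inf),
                     setup$topo, bm = setup$p)
  td <- tidy(fit)
  expect_equal(td$parameter, c("mu_3", "delta_23"))
  expect_true(all(td$lower <= td$estimate & td$estimate <= td$upper))
  gl <- glance(fit)
  expect_equal(gl$n_obs, sum(ds$subset %in% c("T3", "mature")))
  expect_equal(gl$n_params, 2)
  expect_true(gl$feasible)
  expect_gt(gl$ss, 0)
})
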
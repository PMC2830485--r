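test_that("bone-marrow derivatives match a term-by-term hand evaluation", {
  # empty marrow: only the source term is active
  p <- toy_bm(s = 100)
  d <- bm_derivatives(population_state(), p)
  expect_equal(d$d_total[d$compartment == "B_or"], 100)
  expect_equal(d$d_total[d$compartment != "B_or"], rep(0, 4))

  # logistic proliferation vanishes exactly at carrying capacity
  p2 <- toy_bm(K_o = 100)
  st2 <- population_state(B_or = 40, B_oc = 60)  # B_or + B_oc = K_o
  d2 <- bm_derivatives(st2, p2)
  # cycling pro-B: inflow + 0 proliferation - outflow
  expect_equal(d2$d_total[d2$compartment == "B_oc"],
               p2$d_or_oc * 40 - p2$d_oc_ec * 60)

  # fully specified state, hand-picked parameters, every flux written out
  p3 <- bm_parameters(s = 7, gamma_o = 0.5, gamma_e = 0.4, K_o = 100,
                      K_e = 200, d_or_oc = 0.1, d_oc_ec = 0.2,
                      d_ec_er = 0.3, d_er_i = 0.25, mu_o = 0.05,
                      mu_e = 0.06, mu_i = 0.07, delta_i = 0.15)
  st3 <- population_state(B_or = 10, B_oc = 20, B_ec = 30, B_er = 40,
                          B_i = 50)
  d3 <- bm_derivatives(st3, p3)
  g_o <- 0.5 * (1 - (10 + 20) / 100)
  g_e <- 0.4 * (1 - (30 + 40) / 200)
  expect_equal(d3$d_total, c(
    7 - (0.1 + 0.05) * 10,                    # B_or: source - diff - death
    0.1 * 10 + g_o * 20 - 0.2 * 20,           # B_oc: in + logistic - out
    0.2 * 20 + g_e * 30 - 0.3 * 30,           # B_ec
    0.3 * 30 - (0.25 + 0.06) * 40,            # B_er: in - diff - death
    0.25 * 40 - (0.07 + 0.15) * 50            # B_i: in - death - emigration
  ))
})

test_that("splenic derivatives match hand evaluation under best-fit rates", {
  q0 <- spleen_parameters()
  st <- population_state(T12 = 123, T3 = 45, mature = 678)
  d0 <- spleen_derivatives(st, q0, m2t3(), influx = 0)
  expect_equal(d0$d_total, rep(0, 3))

  q <- reference_parameters("table2_best_fit")
  st2 <- population_state(T12 = 1e6, T3 = 5e5, mature = 2e7)
  d <- spleen_derivatives(st2, q, m2t3(), influx = 1.5e6)
  expect_equal(d$d_total, c(
    0.15 * 1.5e6 - (0.05 + 0.1 + 0.05) * 1e6,        # T1/2
    0 * 1.5e6 + 0.1 * 1e6 + 0.004 * 2e7 - 0.17 * 5e5, # T3 (+ recursion)
    0.004 * 1.5e6 + 0.05 * 1e6 - (0 + 0.004) * 2e7    # mature (- recursion)
  ))
})

test_that("flipping the T3<->mature edge mirrors the transfer flux", {
  d <- 0.07
  qa <- spleen_parameters(delta_m3 = d)
  qb <- spleen_parameters(delta_3m = d)
  a <- spleen_derivatives(population_state(T3 = 11, mature = 29), qa, m2t3(),
                          influx = 0)
  b <- spleen_derivatives(population_state(T3 = 29, mature = 11), qb, t3m(),
                          influx = 0)
  # same contents on the source side of the edge: fluxes swap compartments
  expect_equal(a$d_total[a$compartment == "T3"],
               -b$d_total[b$compartment == "T3"])
  expect_equal(a$d_total[a$compartment == "mature"],
               -b$d_total[b$compartment == "mature"])
  expect_equal(a$d_total[a$compartment == "T3"], d * 29)
})

test_that("splenic flux conservation: transfer terms cancel in the sum", {
  withr::with_seed(99, {
    for (i in 1:20) {
      vals <- stats::runif(8, 0, 0.5)
      q <- spleen_parameters(f1 = 0.3, f3 = 0.2, fm = 0.1,
                             delta_23 = vals[1], delta_2m = vals[2],
                             delta_m3 = vals[3], mu_12 = vals[4],
                             mu_3 = vals[5], mu_m = vals[6])
      st <- population_state(T12 = 1e4 * vals[7] + 1, T3 = 5e3 * vals[8] + 1,
                             mature = 2e4 * vals[1] + 1)
      R <- 1e3 * vals[2]
      dd <- spleen_derivatives(st, q, m2t3(), influx = R)
      t12 <- st$total[st$compartment == "T12"]
      t3 <- st$total[st$compartment == "T3"]
      bm <- st$total[st$compartment == "mature"]
      expect_equal(sum(dd$d_total),
                   (q$f1 + q$f3 + q$fm) * R - q$mu_12 * t12 - q$mu_3 * t3 -
                     q$mu_m * bm,
                   tolerance = 1e-12)
    }
  })
})

test_that("integration from an empty state without source stays at zero", {
  tc <- integrate_model(toy_bm(s = 0), toy_spleen(), m2t3(),
                        horizon_days = 3, record_every_days = 1)
  expect_equal(unique(tc$total), 0)
})

test_that("a pure-decay pool follows the exponential closed form", {
  # all inflows absent; a seeded T3 pool decays at exp(-mu_3 t)
  q <- spleen_parameters(mu_3 = 0.3)
  init <- population_state(T3 = 1000)
  tc <- integrate_model(toy_bm(s = 0), q, m2t3(), horizon_days = 5,
                        init = init, record_every_days = 0.5)
  t3 <- tc[tc$compartment == "T3", ]
  expect_equal(t3$total, 1000 * exp(-0.3 * t3$time_days * 4),
               tolerance = 1e-7)
})

test_that("halving the substep changes stored counts by far less than 0.1%", {
  setup <- best_fit_setup()
  tc1 <- integrate_model(setup$p, setup$q, setup$topo, horizon_days = 30,
                         dt = 0.1, record_every_days = 5)
  tc2 <- integrate_model(setup$p, setup$q, setup$topo, horizon_days = 30,
                         dt = 0.05, record_every_days = 5)
  big <- tc1$total > 1  # relative comparison meaningful above one cell
  expect_lt(max(abs(tc1$total[big] - tc2$total[big]) / tc2$total[big]), 1e-3)
})

test_that("integration agrees with an independent deSolve rk4 run", {
  skip_if_not_installed("deSolve")
  p <- toy_bm()
  q <- toy_spleen()
  rhs <- function(t, y, parms) {
    g_o <- p$gamma_o * (1 - (y[1] + y[2]) / p$K_o)
    g_e <- p$gamma_e * (1 - (y[3] + y[4]) / p$K_e)
    R <- p$delta_i * y[5]
    list(c(
      p$s - (p$d_or_oc + p$mu_o) * y[1],
      p$d_or_oc * y[1] + g_o * y[2] - p$d_oc_ec * y[2],
      p$d_oc_ec * y[2] + g_e * y[3] - p$d_ec_er * y[3],
      p$d_ec_er * y[3] - (p$d_er_i + p$mu_e) * y[4],
      p$d_er_i * y[4] - (p$mu_i + p$delta_i) * y[5],
      q$f1 * R - (q$mu_12 + q$delta_23 + q$delta_2m) * y[6],
      q$f3 * R + q$delta_23 * y[6] + q$delta_m3 * y[8] - q$mu_3 * y[7],
      q$fm * R + q$delta_2m * y[6] - (q$mu_m + q$delta_m3) * y[8]
    ))
  }
  times <- seq(0, 40, by = 0.1)  # 6-h units
  ref <- deSolve::ode(y = rep(0, 8), times = times, func = rhs, parms = NULL,
                      method = "rk4")
  tc <- integrate_model(p, q, m2t3(), horizon_days = 10, dt = 0.1,
                        record_every_days = 2.5)
  for (d in unique(tc$time_days)) {
    ours <- tc$total[tc$time_days == d]
    theirs <- ref[abs(ref[, "time"] - d * 4) < 1e-9, 2:9]
    expect_equal(ours, as.numeric(theirs), tolerance = 1e-8)
  }
})

test_that("non-negativity holds along trajectories from empty state", {
  sets <- random_acceptable_spleen(5, seed = 3)
  for (q in sets) {
    tc <- integrate_model(toy_bm(), q, m2t3(), horizon_days = 10,
                          record_every_days = 1)
    expect_true(all(tc$total >= 0))
    expect_true(all(tc$unlabeled >= 0))
    expect_true(all(tc$labeled >= 0))
  }
})

test_that("steady-state search honours its contracts", {
  # no source, no rates: the empty state is a fixed point at t = 0
  p0 <- bm_parameters(s = 0, gamma_o = 0, gamma_e = 0, K_o = 1, K_e = 1,
                      d_or_oc = 0, d_oc_ec = 0, d_ec_er = 0, d_er_i = 0,
                      mu_o = 0, mu_e = 0, mu_i = 0, delta_i = 0)
  st0 <- steady_state(p0, spleen_parameters(), m2t3())
  expect_true(st0$converged)
  expect_equal(st0$time_days, 0)
  expect_equal(st0$state$count, rep(0, 8))

  # single pool with inflow and death: steady count c / mu
  p1 <- bm_parameters(s = 120, gamma_o = 0, gamma_e = 0, K_o = 1, K_e = 1,
                      d_or_oc = 0, d_oc_ec = 0, d_ec_er = 0, d_er_i = 0,
                      mu_o = 0.4, mu_e = 0, mu_i = 0, delta_i = 0)
  st1 <- steady_state(p1, spleen_parameters(), m2t3(), tol = 1e-10)
  expect_equal(st1$state$count[st1$state$compartment == "B_or"], 120 / 0.4,
               tolerance = 1e-6)

  # fast toy model converges and matches the analytic cascade
  st2 <- steady_state(toy_bm(), toy_spleen(), m2t3(), tol = 1e-9,
                      max_days = 200)
  expect_true(st2$converged)
  bm_exp <- bm_steady_state(toy_bm())
  expect_equal(st2$state$count[1:5], bm_exp$count, tolerance = 1e-6)

  # non-convergence is signalled, not silently returned
  expect_warning(
    steady_state(toy_bm(), toy_spleen(mu_m = 1e-4), m2t3(), tol = 1e-10,
                 max_days = 5),
    class = "bk_no_convergence"
  )
})

test_that("analytic splenic steady state solves the balance equations", {
  q <- toy_spleen()
  # zero influx: empty spleen
  s0 <- spleen_steady_state(q, m2t3(), influx = 0)
  expect_equal(s0$count, rep(0, 3))

  # algebraic identity at mu_m = 0: recursion carries all mature outflow
  qm <- toy_spleen(mu_m = 0)
  R <- 5e4
  sm <- spleen_steady_state(qm, m2t3(), influx = R)
  t12 <- sm$count[sm$subset == "T12"]
  bm <- sm$count[sm$subset == "mature"]
  expect_equal(bm, (qm$fm * R + qm$delta_2m * t12) / qm$delta_m3,
               tolerance = 1e-12)

  # best-fit: T12* from the hand-solved balance f1 R = out * T12
  qb <- reference_parameters("table2_best_fit")
  sb <- spleen_steady_state(qb, m2t3(), influx = 1.56e6)
  expect_equal(sb$count[sb$subset == "T12"],
               0.15 * 1.56e6 / (0.05 + 0.1 + 0.05), tolerance = 1e-12)
  expect_equal(sb$count[sb$subset == "T12"], 1.17e6, tolerance = 1e-9)

  # unbounded mature pool is reported, not fabricated
  expect_warning(
    s_un <- spleen_steady_state(toy_spleen(mu_m = 0, delta_m3 = 0), m2t3(),
                                influx = 100),
    class = "bk_unbounded"
  )
  expect_true(is.infinite(s_un$count[s_un$subset == "mature"]))
})

test_that("long-horizon integration converges to the analytic steady state", {
  # reduced version of the oracle-equivalence acceptance check
  sets <- random_acceptable_spleen(10, seed = 17)
  setup <- best_fit_setup()
  for (q in sets) {
    sp <- spleen_steady_state(q, m2t3(), influx = 1.56e6)
    horizon_units <- min(log(2000) / min(q$mu_12 + q$delta_23 + q$delta_2m,
                                         q$mu_3, q$mu_m + q$delta_m3), 1e4)
    tc <- integrate_model(setup$p, q, m2t3(),
                          horizon_days = ceiling(horizon_units / 4),
                          dt = 0.25, init = "zero",
                          record_every_days = ceiling(horizon_units / 4))
    fin <- tc[tc$time_days == max(tc$time_days), ]
    for (s in splenic_subsets()) {
      expect_equal(fin$total[fin$compartment == s],
                   sp$count[sp$subset == s],
                   tolerance = 5e-3)
    }
  }
})

test_that("the recursion flux calculator is delta_m3 times the pool", {
  expect_identical(mature_to_t3_flux(0.004, 2.5e7), 1e5)
  expect_equal(mature_to_t3_flux(0.003, c(1e6, 2e6)), c(3e3, 6e3))
  tc <- integrate_model(toy_bm(), toy_spleen(), m2t3(), horizon_days = 2,
                        record_every_days = 1)
  fl <- flux_series(tc, toy_spleen())
  expect_equal(fl$flux,
               0.2 * tc$total[tc$compartment == "mature"])
})
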
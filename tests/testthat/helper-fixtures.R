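# Shared fixtures and independent oracles for the test suite. Everything here
# is deliberately plain, scalar code so it cannot share bugs with the
# package's batched engine.

# Fast-relaxing toy parameter sets: all turnover hazards >= ~0.1 per 6 h so
# steady states and labeling saturation are reached within simulated days.
toy_bm <- function(...) {
  p <- list(s = 200, gamma_o = 0.3, gamma_e = 0.3, K_o = 5e4, K_e = 8e4,
            d_or_oc = 0.2, d_oc_ec = 0.3, d_ec_er = 0.3, d_er_i = 0.2,
            mu_o = 0.05, mu_e = 0.05, mu_i = 0.1, delta_i = 0.3)
  do.call(bm_parameters, utils::modifyList(p, list(...)))
}

toy_spleen <- function(...) {
  q <- list(f1 = 0.3, f3 = 0.1, fm = 0.2, delta_23 = 0.3, delta_2m = 0.2,
            delta_m3 = 0.2, delta_3m = 0, mu_12 = 0.2, mu_3 = 0.3, mu_m = 0.1)
  do.call(spleen_parameters, utils::modifyList(q, list(...)))
}

m2t3 <- function() model_topology("mature_to_t3")
t3m <- function() model_topology("t3_to_mature")

best_fit_setup <- function() {
  q <- reference_parameters("table2_best_fit")
  topo <- m2t3()
  p <- calibrate_source(reference_parameters("bm_default"), q, topo)$p
  list(p = p, q = q, topo = topo)
}

# Draw spleen parameter sets uniformly within the published acceptable
# ranges (marginal); every draw has positive outflow from each compartment.
random_acceptable_spleen <- function(n, seed = 1) {
  tab <- acceptable_range_table()
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      vals <- stats::runif(nrow(tab), tab$lower, tab$upper)
      names(vals) <- tab$parameter
      do.call(spleen_parameters, as.list(vals))
    })
  })
}

# Independent scalar RK4 for the splenic labeled subsystem driven by a
# labeled-influx trace sampled at half-substep resolution. Plain loop,
# equations written out term by term.
naive_spleen_labeled <- function(q, direction, RL, n_steps, h, sample_steps) {
  x12 <- 0; x3 <- 0; xm <- 0
  a12 <- q$mu_12 + q$delta_23 + q$delta_2m
  m2 <- direction == "mature_to_t3"
  derivs <- function(x12, x3, xm, r) {
    d12 <- q$f1 * r - a12 * x12
    if (m2) {
      d3 <- q$f3 * r + q$delta_23 * x12 + q$delta_m3 * xm - q$mu_3 * x3
      dm <- q$fm * r + q$delta_2m * x12 - (q$mu_m + q$delta_m3) * xm
    } else {
      d3 <- q$f3 * r + q$delta_23 * x12 - (q$mu_3 + q$delta_3m) * x3
      dm <- q$fm * r + q$delta_2m * x12 + q$delta_3m * x3 - q$mu_m * xm
    }
    c(d12, d3, dm)
  }
  out <- matrix(NA_real_, length(sample_steps), 3)
  if (0 %in% sample_steps) out[match(0, sample_steps), ] <- c(x12, x3, xm)
  for (i in seq_len(n_steps)) {
    r1 <- RL[2 * i - 1]; r2 <- RL[2 * i]; r3 <- RL[2 * i + 1]
    k1 <- derivs(x12, x3, xm, r1)
    k2 <- derivs(x12 + h / 2 * k1[1], x3 + h / 2 * k1[2], xm + h / 2 * k1[3], r2)
    k3 <- derivs(x12 + h / 2 * k2[1], x3 + h / 2 * k2[2], xm + h / 2 * k2[3], r2)
    k4 <- derivs(x12 + h * k3[1], x3 + h * k3[2], xm + h * k3[3], r3)
    x12 <- max(x12 + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]), 0)
    x3 <- max(x3 + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]), 0)
    xm <- max(xm + h / 6 * (k1[3] + 2 * k2[3] + 2 * k3[3] + k4[3]), 0)
    j <- match(i, sample_steps)
    if (!is.na(j)) out[j, ] <- c(x12, x3, xm)
  }
  colnames(out) <- c("T12", "T3", "mature")
  out
}

# Brute-force constrained grid minimisation: a literal loop over every grid
# point, re-screening with the public scalar screen and re-computing SS from
# an independently simulated curve. `sim_fun(q)` must return a tibble with
# subset / time_days / labeled.
brute_force_search <- function(grid, data, constraints, topo, sim_fun,
                               subsets = c("T3", "mature"), dt = 0.1,
                               bm = NULL) {
  vary <- grid$vary
  cand <- expand.grid(rev(vary), KEEP.OUT.ATTRS = FALSE)
  cand <- cand[, rev(seq_along(cand)), drop = FALSE]
  names(cand) <- names(vary)
  best_ss <- Inf
  best_row <- NULL
  n_passing <- 0L
  for (i in seq_len(nrow(cand))) {
    qi <- utils::modifyList(unclass(grid$base), as.list(cand[i, , drop = FALSE]))
    qi <- do.call(spleen_parameters,
                  qi[names(formals(spleen_parameters))])
    ok <- if (is.null(bm)) TRUE else {
      passes_constraints(bm, qi, topo, constraints, dt = dt)$pass
    }
    if (!ok) next
    n_passing <- n_passing + 1L
    sim <- sim_fun(qi)
    ss <- sum_squared_deviations(sim, data, subsets = subsets)
    if (ss < best_ss) {
      best_ss <- ss
      best_row <- cand[i, , drop = FALSE]
    }
  }
  list(ss = best_ss, best = best_row, n_passing = n_passing)
}

quick_design <- function(n_mice = 3) {
  experiment_design(sample_days = c(1, 2, 4, 6, 8, 10, 12, 14),
                    n_mice = n_mice)
}
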
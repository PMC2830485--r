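# Internal fixed-step RK4 propagation engine.
#
# States are a pair of matrices U, L (unlabeled / labeled), one row per
# parameter set, columns in ALL_COMPARTMENTS order:
#   1 B_or, 2 B_oc, 3 B_ec, 4 B_er, 5 B_i, 6 T12, 7 T3, 8 mature
# Parameter list elements may be scalars or length-nrow vectors, so the same
# code serves single runs and batched grid evaluation. All rates are hazards
# per 6-h unit; the RK4 substep h is a fraction of that unit.

# Derivatives of (U, L). BrdU bookkeeping: while labeling is active, a
# division of an unlabeled cycling cell removes the parent from U and adds
# two daughters to L with probability `eff` (else two unlabeled daughters);
# the per-capita division rate equals the logistic net growth rate g when
# g > 0. When g < 0 (above carrying capacity) the decline is applied
# proportionally to both streams. Summing the U and L derivatives always
# reproduces the totals-only dynamics exactly.
model_derivs <- function(U, L, p, q, m2t3, lab_active, eff, lab_src) {
  tot12 <- U[, 1] + L[, 1] + U[, 2] + L[, 2]
  tot34 <- U[, 3] + L[, 3] + U[, 4] + L[, 4]
  g_o <- p$gamma_o * (1 - tot12 / p$K_o)
  g_e <- p$gamma_e * (1 - tot34 / p$K_e)

  dU <- U * 0
  dL <- L * 0

  sl <- if (lab_active) eff * lab_src else 0
  out_or <- p$d_or_oc + p$mu_o
  dU[, 1] <- p$s * (1 - sl) - out_or * U[, 1]
  dL[, 1] <- p$s * sl - out_or * L[, 1]

  prolif <- function(g, u, l) {
    if (lab_active && eff > 0) {
      gp <- pmax(g, 0)
      gn <- pmin(g, 0)
      list(du = gp * u * (1 - 2 * eff) + gn * u,
           dl = gp * (l + 2 * eff * u) + gn * l)
    } else {
      list(du = g * u, dl = g * l)
    }
  }

  pr_o <- prolif(g_o, U[, 2], L[, 2])
  dU[, 2] <- p$d_or_oc * U[, 1] + pr_o$du - p$d_oc_ec * U[, 2]
  dL[, 2] <- p$d_or_oc * L[, 1] + pr_o$dl - p$d_oc_ec * L[, 2]

  pr_e <- prolif(g_e, U[, 3], L[, 3])
  dU[, 3] <- p$d_oc_ec * U[, 2] + pr_e$du - p$d_ec_er * U[, 3]
  dL[, 3] <- p$d_oc_ec * L[, 2] + pr_e$dl - p$d_ec_er * L[, 3]

  out_er <- p$d_er_i + p$mu_e
  dU[, 4] <- p$d_ec_er * U[, 3] - out_er * U[, 4]
  dL[, 4] <- p$d_ec_er * L[, 3] - out_er * L[, 4]

  out_i <- p$mu_i + p$delta_i
  dU[, 5] <- p$d_er_i * U[, 4] - out_i * U[, 5]
  dL[, 5] <- p$d_er_i * L[, 4] - out_i * L[, 5]

  RU <- p$delta_i * U[, 5]
  RL <- p$delta_i * L[, 5]

  c_m3 <- if (m2t3) q$delta_m3 else 0  # mature -> T3 transfer hazard
  c_3m <- if (m2t3) 0 else q$delta_3m  # T3 -> mature transfer hazard
  out_12 <- q$mu_12 + q$delta_23 + q$delta_2m
  out_3 <- q$mu_3 + c_3m
  out_m <- q$mu_m + c_m3

  dU[, 6] <- q$f1 * RU - out_12 * U[, 6]
  dL[, 6] <- q$f1 * RL - out_12 * L[, 6]
  dU[, 7] <- q$f3 * RU + q$delta_23 * U[, 6] + c_m3 * U[, 8] - out_3 * U[, 7]
  dL[, 7] <- q$f3 * RL + q$delta_23 * L[, 6] + c_m3 * L[, 8] - out_3 * L[, 7]
  dU[, 8] <- q$fm * RU + q$delta_2m * U[, 6] + c_3m * U[, 7] - out_m * U[, 8]
  dL[, 8] <- q$fm * RL + q$delta_2m * L[, 6] + c_3m * L[, 7] - out_m * L[, 8]

  list(dU = dU, dL = dL)
}

# One classical RK4 step of size h for the full (U, L) system.
rk4_step <- function(U, L, h, p, q, m2t3, lab_active, eff, lab_src) {
  k1 <- model_derivs(U, L, p, q, m2t3, lab_active, eff, lab_src)
  k2 <- model_derivs(U + h / 2 * k1$dU, L + h / 2 * k1$dL,
                     p, q, m2t3, lab_active, eff, lab_src)
  k3 <- model_derivs(U + h / 2 * k2$dU, L + h / 2 * k2$dL,
                     p, q, m2t3, lab_active, eff, lab_src)
  k4 <- model_derivs(U + h * k3$dU, L + h * k3$dL,
                     p, q, m2t3, lab_active, eff, lab_src)
  Un <- U + h / 6 * (k1$dU + 2 * k2$dU + 2 * k3$dU + k4$dU)
  Ln <- L + h / 6 * (k1$dL + 2 * k2$dL + 2 * k3$dL + k4$dL)
  # RK4 can undershoot zero by round-off near empty compartments; project back
  Un[Un < 0] <- 0
  Ln[Ln < 0] <- 0
  list(U = Un, L = Ln)
}

# Propagate n_steps substeps of size h, recording (U, L) at the requested
# step indices (0 = initial state). `lab_active` is a logical vector of
# length n_steps (active during that substep). Errors on non-finite states.
run_engine <- function(U0, L0, p, q, m2t3, n_steps, h,
                       lab_active = rep(FALSE, n_steps),
                       eff = 1, lab_src = 1,
                       record_steps = n_steps) {
  U <- U0
  L <- L0
  rec <- vector("list", length(record_steps))
  names(rec) <- as.character(record_steps)
  ri <- match(0L, record_steps)
  if (!is.na(ri)) rec[[ri]] <- list(U = U, L = L)
  for (i in seq_len(n_steps)) {
    st <- rk4_step(U, L, h, p, q, m2t3, lab_active[i], eff, lab_src)
    U <- st$U
    L <- st$L
    if (!all(is.finite(U)) || !all(is.finite(L))) {
      abort(sprintf("non-finite state at step %d (t = %.3f units)", i, i * h),
            class = "bk_numerical_failure")
    }
    ri <- match(i, record_steps)
    if (!is.na(ri)) rec[[ri]] <- list(U = U, L = L)
  }
  list(records = rec, U = U, L = L)
}

# ---- analytic steady states -------------------------------------------------

# Positive root of the quadratic balance  in + g(B)*B - out*B = 0 with
# g(B) = gamma * (1 - (B + other)/K); `other` is the co-resident pool size
# expressed as rho * B (rho >= 0) plus a fixed amount `fixed`.
logistic_balance_root <- function(inflow, gamma, K, out, rho = 0, fixed = 0) {
  if (gamma == 0) {
    if (out <= 0) return(if (inflow > 0) Inf else 0)
    return(inflow / out)
  }
  a <- -gamma * (1 + rho) / K
  b <- gamma * (1 - fixed / K) - out
  if (inflow == 0) {
    # the attractor reached from the empty state: without inflow the pool
    # stays empty (a self-sustaining pool, gamma > out, has a second fixed
    # point that from-zero dynamics never reach)
    return(0)
  }
  disc <- b^2 - 4 * a * inflow
  # stable form of the positive root (a < 0, c > 0): avoids cancellation in
  # b + sqrt(disc) when b is large and negative
  if (b <= 0) {
    2 * inflow / (sqrt(disc) - b)
  } else {
    (b + sqrt(disc)) / (2 * gamma * (1 + rho) / K)
  }
}

# Cascade closed form for the bone-marrow steady state (feed-forward chain).
bm_steady_vec <- function(p) {
  B_or <- if (p$d_or_oc + p$mu_o > 0) p$s / (p$d_or_oc + p$mu_o)
          else if (p$s > 0) Inf else 0
  B_oc <- logistic_balance_root(p$d_or_oc * B_or, p$gamma_o, p$K_o,
                                p$d_oc_ec, rho = 0, fixed = B_or)
  rho_e <- if (p$d_er_i + p$mu_e > 0) p$d_ec_er / (p$d_er_i + p$mu_e) else 0
  B_ec <- logistic_balance_root(p$d_oc_ec * B_oc, p$gamma_e, p$K_e,
                                p$d_ec_er, rho = rho_e, fixed = 0)
  B_er <- rho_e * B_ec
  B_i <- if (p$mu_i + p$delta_i > 0) p$d_er_i * B_er / (p$mu_i + p$delta_i)
         else if (p$d_er_i * B_er > 0) Inf else 0
  c(B_or = B_or, B_oc = B_oc, B_ec = B_ec, B_er = B_er, B_i = B_i)
}

# Linear balance solve for the splenic subsystem at constant influx R.
# Vectorised over parameter vectors; returns a list of three vectors which
# are Inf for unbounded compartments (zero outflow with nonzero inflow).
spleen_steady_vec <- function(q, m2t3, R) {
  safe_div <- function(num, den) {
    out <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
    out
  }
  out_12 <- q$mu_12 + q$delta_23 + q$delta_2m
  T12 <- safe_div(q$f1 * R, out_12)
  if (m2t3) {
    Bm <- safe_div(q$fm * R + q$delta_2m * T12, q$mu_m + q$delta_m3)
    T3 <- safe_div(q$f3 * R + q$delta_23 * T12 + q$delta_m3 * Bm, q$mu_3)
  } else {
    T3 <- safe_div(q$f3 * R + q$delta_23 * T12, q$mu_3 + q$delta_3m)
    Bm <- safe_div(q$fm * R + q$delta_2m * T12 + q$delta_3m * T3, q$mu_m)
  }
  list(T12 = T12, T3 = T3, mature = Bm)
}

# ---- bone-marrow outflux traces --------------------------------------------

# Emigration flux traces delta_i * B_i at half-substep resolution (needed for
# the RK4 stages of the trace-driven splenic propagator). Integrates the full
# model at substep h/2 (splenic feedback on the BM is absent, so splenic
# columns are ignored). Returns unlabeled and labeled flux vectors of length
# 2 * n_steps + 1 covering t = 0 .. n_steps * h.
bm_flux_trace <- function(p, n_steps, h, labeling = FALSE, eff = 1,
                          lab_src = 1, U0 = NULL, L0 = NULL) {
  nh <- 2L * n_steps
  hh <- h / 2
  if (is.null(U0)) U0 <- matrix(0, 1, 8)
  if (is.null(L0)) L0 <- matrix(0, 1, 8)
  q0 <- spleen_parameters()  # spleen irrelevant to the BM chain
  RU <- numeric(nh + 1L)
  RL <- numeric(nh + 1L)
  U <- U0
  L <- L0
  RU[1] <- p$delta_i * U[, 5]
  RL[1] <- p$delta_i * L[, 5]
  for (i in seq_len(nh)) {
    st <- rk4_step(U, L, hh, p, q0, TRUE, labeling, eff, lab_src)
    U <- st$U
    L <- st$L
    RU[i + 1L] <- p$delta_i * U[, 5]
    RL[i + 1L] <- p$delta_i * L[, 5]
  }
  list(RU = RU, RL = RL)
}

# ---- trace-driven splenic propagators --------------------------------------

# Splenic rate coefficients for a batch of candidates (vectors length n).
spleen_coefs <- function(q, m2t3) {
  c_m3 <- if (m2t3) q$delta_m3 else 0
  c_3m <- if (m2t3) 0 else q$delta_3m
  list(
    f1 = q$f1, f3 = q$f3, fm = q$fm,
    d23 = q$delta_23, d2m = q$delta_2m,
    c_m3 = c_m3, c_3m = c_3m,
    a12 = q$mu_12 + q$delta_23 + q$delta_2m,
    a3 = q$mu_3 + c_3m,
    am = q$mu_m + c_m3
  )
}

spleen_state_derivs <- function(x12, x3, xm, R, cf) {
  list(
    d12 = cf$f1 * R - cf$a12 * x12,
    d3 = cf$f3 * R + cf$d23 * x12 + cf$c_m3 * xm - cf$a3 * x3,
    dm = cf$fm * R + cf$d2m * x12 + cf$c_3m * x3 - cf$am * xm
  )
}

# RK4 for the linear splenic subsystem driven by an influx trace `R` sampled
# at half-substep resolution (length 2*n_steps+1). States are vectors of
# length n (one entry per candidate). Records states at `record_steps`.
spleen_trace_rk4 <- function(cf, x12, x3, xm, R, n_steps, h,
                             record_steps = integer(0),
                             track_arrival = NULL) {
  nrec <- length(record_steps)
  rec12 <- if (nrec) matrix(NA_real_, length(x12), nrec) else NULL
  rec3 <- rec12
  recm <- rec12
  arr <- NULL
  if (!is.null(track_arrival)) {
    # track_arrival: list(asym12, asym3, asymm, frac) with NULL entries for
    # untracked subsets; records the last step at which any tracked subset
    # was outside frac of its asymptote, per candidate
    arr <- list(last_out = integer(length(x12)))
  }
  store <- function(i) {
    ri <- match(i, record_steps)
    if (!is.na(ri)) {
      rec12[, ri] <<- x12
      rec3[, ri] <<- x3
      recm[, ri] <<- xm
    }
  }
  store(0L)
  for (i in seq_len(n_steps)) {
    r1 <- R[2L * i - 1L]
    r2 <- R[2L * i]
    r3 <- R[2L * i + 1L]
    k1 <- spleen_state_derivs(x12, x3, xm, r1, cf)
    k2 <- spleen_state_derivs(x12 + h / 2 * k1$d12, x3 + h / 2 * k1$d3,
                              xm + h / 2 * k1$dm, r2, cf)
    k3 <- spleen_state_derivs(x12 + h / 2 * k2$d12, x3 + h / 2 * k2$d3,
                              xm + h / 2 * k2$dm, r2, cf)
    k4 <- spleen_state_derivs(x12 + h * k3$d12, x3 + h * k3$d3,
                              xm + h * k3$dm, r3, cf)
    x12 <- pmax(x12 + h / 6 * (k1$d12 + 2 * k2$d12 + 2 * k3$d12 + k4$d12), 0)
    x3 <- pmax(x3 + h / 6 * (k1$d3 + 2 * k2$d3 + 2 * k3$d3 + k4$d3), 0)
    xm <- pmax(xm + h / 6 * (k1$dm + 2 * k2$dm + 2 * k3$dm + k4$dm), 0)
    if (!is.null(arr)) {
      ta <- track_arrival
      out <- rep(FALSE, length(x12))
      if (!is.null(ta$asym12)) {
        out <- out | abs(x12 - ta$asym12) > ta$frac * pmax(ta$asym12, 1e-300)
      }
      if (!is.null(ta$asym3)) {
        out <- out | abs(x3 - ta$asym3) > ta$frac * pmax(ta$asym3, 1e-300)
      }
      if (!is.null(ta$asymm)) {
        out <- out | abs(xm - ta$asymm) > ta$frac * pmax(ta$asymm, 1e-300)
      }
      arr$last_out[out] <- i
    }
    store(i)
  }
  list(x12 = x12, x3 = x3, xm = xm,
       rec12 = rec12, rec3 = rec3, recm = recm, arrival = arr)
}

# convert parameter list (possibly classed) to plain list of vectors
plain <- function(x) {
  x <- unclass(x)
  x[!vapply(x, is.null, logical(1))]
}
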
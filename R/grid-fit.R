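SPLEEN_PARAM_NAMES <- c("f1", "f3", "fm", "delta_23", "delta_2m",
                        "delta_m3", "delta_3m", "mu_12", "mu_3", "mu_m")

#' Define an exhaustive parameter grid
#'
#' A grid is a base splenic parameter set plus, for each varied parameter,
#' the explicit vector of values to enumerate; the search evaluates the full
#' Cartesian product. Grids that encode an edge-absence hypothesis should
#' include 0 among the values of the corresponding rate, so "edge absent" is
#' one of the candidates.
#'
#' @param base A [spleen_parameters()] object supplying every non-varied
#'   value.
#' @param vary A named list of numeric vectors, one per varied parameter
#'   (names among the splenic parameter names). [grid_seq()] is a convenience
#'   for lower/upper/step specifications.
#' @return A `bk_grid` object with elements `base`, `vary`, `cardinality`.
#' @export
#' @examples
#' g <- parameter_grid(reference_parameters("table2_best_fit"),
#'                     vary = list(delta_23 = grid_seq(0.06, 0.14, 0.01),
#'                                 mu_3 = grid_seq(0.12, 0.22, 0.01)))
#' g$cardinality
parameter_grid <- function(base, vary) {
  base <- as_spleen_parameters(base)
  if (!length(vary) || is.null(names(vary)) || any(names(vary) == "")) {
    abort("vary must be a non-empty named list", class = "bk_invalid_grid")
  }
  bad <- setdiff(names(vary), SPLEEN_PARAM_NAMES)
  if (length(bad)) {
    abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")),
          class = "bk_invalid_grid")
  }
  vary <- lapply(vary, function(v) {
    v <- sort(unique(as.numeric(v)))
    if (!length(v) || any(!is.finite(v)) || any(v < 0)) {
      abort("grid values must be finite and non-negative",
            class = "bk_invalid_grid")
    }
    v
  })
  structure(
    list(base = base, vary = vary,
         cardinality = prod(vapply(vary, length, numeric(1)))),
    class = "bk_grid"
  )
}

#' @rdname parameter_grid
#' @param lower,upper,step Range and step of a regular grid; `lower` and
#'   `upper` are always included (the last interval may be short).
#' @export
grid_seq <- function(lower, upper, step = 0.01) {
  if (lower > upper || step <= 0) {
    abort("need lower <= upper and step > 0", class = "bk_invalid_grid")
  }
  v <- seq(lower, upper, by = step)
  if (upper - v[length(v)] > 1e-12) v <- c(v, upper)
  round(v, 12)
}

#' @export
print.bk_grid <- function(x, ...) {
  cat("<bk_grid> ", format(x$cardinality, big.mark = ","), " points over ",
      length(x$vary), " parameter(s)\n", sep = "")
  for (nm in names(x$vary)) {
    v <- x$vary[[nm]]
    cat(sprintf("  %-9s %d values in [%g, %g]\n", nm, length(v), min(v), max(v)))
  }
  invisible(x)
}

#' Default shipped grid for the splenic parameters
#'
#' The published per-parameter acceptable ranges padded on each side by a
#' fraction of their half-width, stepped at 0.01 (or finer where a range is
#' too narrow for that step to resolve it), clamped at zero. Parameters whose
#' range includes zero keep zero on the grid, so edge absence stays testable.
#'
#' @param topo A [model_topology()]; under the legacy direction the
#'   mature-to-T3 rate values are assigned to `delta_3m` instead.
#' @param pad Padding fraction of each range's half-width (default 0.5).
#' @param step Default grid step (default 0.01).
#' @param base Base parameter set for non-varied values.
#' @return A `bk_grid`.
#' @export
default_spleen_grid <- function(topo = model_topology("mature_to_t3"),
                                pad = 0.5, step = 0.01,
                                base = reference_parameters("table2_best_fit")) {
  tab <- acceptable_range_table()
  vary <- list()
  for (i in seq_len(nrow(tab))) {
    nm <- tab$parameter[i]
    half <- (tab$upper[i] - tab$lower[i]) / 2
    lo <- max(0, tab$lower[i] - pad * half)
    hi <- tab$upper[i] + pad * half
    st <- if ((hi - lo) / step < 4) max((hi - lo) / 4, 1e-6) else step
    v <- grid_seq(lo, hi, st)
    if (tab$lower[i] == 0 && !0 %in% v) v <- c(0, v)
    vary[[nm]] <- v
  }
  if (topo$direction == "t3_to_mature") {
    names(vary)[names(vary) == "delta_m3"] <- "delta_3m"
    base <- as_spleen_parameters(modifyList(plain(base),
                                            list(delta_m3 = 0, delta_3m = 0.004,
                                                 mu_m = 0.0025)))
  }
  # drop varied entries for edges switched off in the topology
  for (nm in names(topo$edges)) {
    if (!topo$edges[[nm]] && nm %in% names(vary)) vary[[nm]] <- NULL
  }
  parameter_grid(base, vary)
}

#' Sum of squared deviations between simulation and data
#'
#' The least-squares objective: the sum over fitted subsets and time points
#' of the squared deviation between each observed labeled-cell number and
#' the simulated labeled-cell number. Replicate observations (one per mouse)
#' each contribute their own term. A data point with no simulated
#' counterpart at the same subset and time is an alignment error — no silent
#' interpolation.
#'
#' @param sim A `bk_labeled_timecourse` (or tibble with `subset`,
#'   `time_days`, `labeled`).
#' @param data A labeling dataset (tibble with `subset`, `time_days`,
#'   `labeled_count`).
#' @param subsets Subsets entering the objective (default T3 and mature).
#' @return The scalar SS (cells^2).
#' @export
sum_squared_deviations <- function(sim, data, subsets = c("T3", "mature")) {
  d <- data |>
    filter(.data$subset %in% subsets) |>
    mutate(.t = round(.data$time_days, 9))
  if (!nrow(d)) abort("no data rows in the selected subsets",
                      class = "bk_invalid_argument")
  s <- sim |>
    filter(.data$subset %in% subsets) |>
    mutate(.t = round(.data$time_days, 9)) |>
    select("subset", ".t", "labeled")
  j <- left_join(d, s, by = c("subset", ".t"))
  if (anyNA(j$labeled)) {
    miss <- j |> filter(is.na(.data$labeled)) |> distinct(.data$subset, .data$.t)
    abort(paste0("no simulated counterpart for ",
                 paste(paste0(miss$subset, "@", miss$.t, "d"), collapse = ", ")),
          class = "bk_alignment_error")
  }
  sum((j$labeled_count - j$labeled)^2)
}

#' Screening constraints on steady-state behaviour
#'
#' Candidate parameter sets are screened before fitting: the steady-state
#' total of each subset must lie in its observed range, the subset
#' composition (fraction of all splenic B cells) must lie in its observed
#' range, and the time to reach steady state from empty compartments must
#' not exceed a biological bound (default 2 months, the growth window of a
#' mouse). Arrival at steady state is defined as every tracked subset being
#' within `steady_frac` of its analytic asymptote. The time rule is applied
#' to `time_subsets` (default the transitional pools; the mature pool's
#' passive turnover can be slower than the bound for any acceptable
#' mature-to-T3 rate, so its equilibration time is reported in diagnostics
#' rather than screened). Note that under the death-niche topology the T3
#' pool inherits the mature pool's slow time scale through the recursion
#' inflow, so the 60-day default rejects the reference best-fit model
#' itself; widen the bound (or set it to `Inf`) when fitting that topology
#' — see the methods vignette.
#'
#' @param totals Tibble with columns `subset`, `lower`, `upper` (cells), or
#'   `NULL` to skip.
#' @param composition Tibble with columns `subset`, `lower`, `upper`
#'   (fractions of total splenic B cells), or `NULL` to skip.
#' @param max_steady_days Time-to-steady-state bound, days (default 60).
#' @param steady_frac Relative distance from the asymptote counted as
#'   "arrived" (default 0.01).
#' @param time_subsets Subsets the time bound applies to.
#' @return A `bk_constraints` object.
#' @export
constraint_set <- function(totals = NULL, composition = NULL,
                           max_steady_days = 60, steady_frac = 0.01,
                           time_subsets = c("T12", "T3")) {
  chk <- function(x, what) {
    if (is.null(x)) return(NULL)
    stopifnot(all(c("subset", "lower", "upper") %in% names(x)))
    if (any(x$lower > x$upper)) {
      abort(paste0("empty ", what, " range"), class = "bk_invalid_argument")
    }
    as_tibble(x[, c("subset", "lower", "upper")])
  }
  if (max_steady_days < 0 || steady_frac <= 0) {
    abort("need max_steady_days >= 0 and steady_frac > 0",
          class = "bk_invalid_argument")
  }
  structure(
    list(totals = chk(totals, "total"), composition = chk(composition, "composition"),
         max_steady_days = max_steady_days, steady_frac = steady_frac,
         time_subsets = match.arg(time_subsets, SPLENIC_SUBSETS,
                                  several.ok = TRUE)),
    class = "bk_constraints"
  )
}

#' Per-observation experimental error bands
#'
#' Builds, for each (subset, time point), the band of labeled-cell numbers
#' compatible with the replicate scatter: mean plus/minus `k` standard
#' deviations across mice (degenerate band if a single mouse). Grid points
#' whose simulated curves stay within every band are the "acceptable models"
#' whose marginal parameter spans form the acceptable ranges.
#'
#' @param data A labeling dataset (tibble with `subset`, `time_days`,
#'   `labeled_count`, replicates as rows).
#' @param k Band half-width in replicate standard deviations (default 2).
#' @return A tibble with columns `subset`, `time_days`, `lower`, `upper`.
#' @export
experimental_error_bands <- function(data, k = 2) {
  stopifnot(k >= 0)
  data |>
    group_by(.data$subset, .data$time_days) |>
    summarise(
      m = mean(.data$labeled_count),
      s = if (dplyr::n() > 1) stats::sd(.data$labeled_count) else 0,
      .groups = "drop"
    ) |>
    mutate(lower = pmax(0, .data$m - k * .data$s),
           upper = .data$m + k * .data$s) |>
    select("subset", "time_days", "lower", "upper")
}

# ---- shared evaluation machinery -------------------------------------------

# Precompute everything that does not depend on splenic candidates: the BM
# steady state, the labeled/total emigration flux trace during labeling, and
# the from-zero ramp trace used by the time screen.
build_bm_context <- function(p, dt, label_units = 0, screen_units = 0,
                             schedule = labeling_schedule()) {
  p <- as_bm_parameters(p)
  bm <- bm_steady_vec(plain(p))
  if (any(!is.finite(bm))) {
    abort("bone-marrow steady state is unbounded", class = "bk_unbounded")
  }
  R_ss <- p$delta_i * bm[["B_i"]]
  ctx <- list(p = p, bm_steady = bm, R_ss = R_ss, dt = dt)
  if (label_units > 0) {
    n <- max(1L, ceiling(round(label_units / dt, 9)))
    U0 <- matrix(0, 1, 8)
    U0[1, 1:5] <- bm
    tr <- bm_flux_trace(plain(p), n, dt, labeling = TRUE,
                        eff = schedule$efficiency,
                        lab_src = as.numeric(schedule$label_source), U0 = U0)
    ctx$label_steps <- n
    ctx$RL_trace <- tr$RL
    ctx$Rtot_trace_label <- tr$RU + tr$RL
  }
  if (screen_units > 0) {
    n <- max(1L, ceiling(round(screen_units / dt, 9)))
    tr <- bm_flux_trace(plain(p), n, dt, labeling = FALSE)
    ctx$screen_steps <- n
    ctx$Rramp_trace <- tr$RU + tr$RL
  }
  ctx
}

# Evaluate a batch of splenic candidates (data frame with all ten parameter
# columns, one row per candidate) against constraints and, optionally, data
# sufficient statistics. Returns per-candidate vectors.
evaluate_spleen_batch <- function(cand, m2t3, ctx, constraints = NULL,
                                  ss_stats = NULL, sample_steps = NULL,
                                  bands_mat = NULL) {
  n <- nrow(cand)
  qv <- as.list(cand)
  steady <- spleen_steady_vec(qv, m2t3, ctx$R_ss)
  asym <- cbind(T12 = steady$T12, T3 = steady$T3, mature = steady$mature)
  bounded <- is.finite(asym[, 1]) & is.finite(asym[, 2]) & is.finite(asym[, 3])
  pass <- bounded
  arrival <- rep(NA_real_, n)

  if (!is.null(constraints)) {
    if (!is.null(constraints$totals)) {
      for (i in seq_len(nrow(constraints$totals))) {
        sset <- constraints$totals$subset[i]
        v <- asym[, sset]
        pass <- pass & v >= constraints$totals$lower[i] &
          v <= constraints$totals$upper[i]
      }
    }
    if (!is.null(constraints$composition)) {
      tot <- rowSums(asym)
      for (i in seq_len(nrow(constraints$composition))) {
        sset <- constraints$composition$subset[i]
        fr <- ifelse(tot > 0, asym[, sset] / tot, 0)
        pass <- pass & fr >= constraints$composition$lower[i] &
          fr <= constraints$composition$upper[i]
      }
    }
    if (is.finite(constraints$max_steady_days)) {
      ts <- constraints$time_subsets
      n_screen <- ctx$screen_steps
      if (is.null(n_screen) || n_screen < 1) {
        tracked0 <- rowSums(asym[, ts, drop = FALSE]) == 0
        arrival <- ifelse(tracked0, 0, Inf)
      } else {
        cf <- spleen_coefs(qv, m2t3)
        z <- numeric(n)
        track <- list(
          asym12 = if ("T12" %in% ts) steady$T12 else NULL,
          asym3 = if ("T3" %in% ts) steady$T3 else NULL,
          asymm = if ("mature" %in% ts) steady$mature else NULL,
          frac = constraints$steady_frac
        )
        sim <- spleen_trace_rk4(cf, z, z, z, ctx$Rramp_trace,
                                n_screen, ctx$dt, track_arrival = track)
        last_out <- sim$arrival$last_out
        arrival <- ifelse(last_out < n_screen,
                          (last_out + 1) * ctx$dt / UNITS_PER_DAY, Inf)
        arrival[last_out == 0] <- 0
        pass <- pass & is.finite(arrival) &
          arrival <= constraints$max_steady_days
      }
    }
  }

  ss <- rep(NA_real_, n)
  within <- rep(NA, n)
  if (!is.null(ss_stats)) {
    cf <- spleen_coefs(qv, m2t3)
    z <- numeric(n)
    sim <- spleen_trace_rk4(cf, z, z, z, ctx$RL_trace, ctx$label_steps,
                            ctx$dt, record_steps = sample_steps)
    # sim$rec* are n x n_samples labeled counts per subset
    f_by_subset <- list(T12 = sim$rec12, T3 = sim$rec3, mature = sim$recm)
    ss <- numeric(n)
    # centered form avoids cancellation: sum (Y - f)^2 = ssw + n (ybar - f)^2
    for (i in seq_len(nrow(ss_stats))) {
      f <- f_by_subset[[ss_stats$subset[i]]][, ss_stats$col[i]]
      ss <- ss + ss_stats$ssw[i] + ss_stats$n[i] * (ss_stats$ybar[i] - f)^2
    }
    if (!is.null(bands_mat)) {
      within <- rep(TRUE, n)
      for (i in seq_len(nrow(bands_mat))) {
        f <- f_by_subset[[bands_mat$subset[i]]][, bands_mat$col[i]]
        within <- within & f >= bands_mat$lower[i] & f <= bands_mat$upper[i]
      }
    }
  }
  list(pass = pass, arrival_days = arrival, ss = ss, within = within,
       steady = asym)
}

#' Screen one parameter set against the constraints
#'
#' Checks whether a single (bone-marrow, spleen, topology) model passes the
#' screening used by the grid search: steady-state totals and composition
#' within their observed ranges, and arrival at steady state from empty
#' compartments within the time bound. Diagnostics name every criterion with
#' its value and limits; a non-convergent (unbounded) model fails with a
#' `convergence` tag.
#'
#' @inheritParams integrate_model
#' @param constraints A [constraint_set()].
#' @return A list of class `bk_screen` with elements `pass` (logical) and
#'   `diagnostics` (tibble `criterion`, `subset`, `value`, `lower`, `upper`,
#'   `pass`).
#' @export
passes_constraints <- function(p, q, topo, constraints, dt = 0.1) {
  p <- as_bm_parameters(p)
  q <- check_topology(as_spleen_parameters(q), topo)
  stopifnot(inherits(constraints, "bk_constraints"))
  m2t3 <- topo$direction == "mature_to_t3"
  screen_units <- if (is.finite(constraints$max_steady_days)) {
    constraints$max_steady_days * UNITS_PER_DAY
  } else 0
  ctx <- build_bm_context(p, dt, screen_units = screen_units)
  cand <- as.data.frame(plain(q))
  ev <- evaluate_spleen_batch(cand, m2t3, ctx, constraints = constraints)

  diag <- list()
  bounded <- all(is.finite(ev$steady[1, ]))
  diag[[1]] <- tibble(criterion = "convergence", subset = NA_character_,
                      value = as.numeric(bounded), lower = 1, upper = 1,
                      pass = bounded)
  if (!is.null(constraints$totals)) {
    ct <- constraints$totals
    diag[[length(diag) + 1]] <- tibble(
      criterion = "total", subset = ct$subset,
      value = ev$steady[1, ct$subset],
      lower = ct$lower, upper = ct$upper,
      pass = ev$steady[1, ct$subset] >= ct$lower &
        ev$steady[1, ct$subset] <= ct$upper
    )
  }
  if (!is.null(constraints$composition)) {
    cc <- constraints$composition
    tot <- sum(ev$steady[1, ])
    fr <- if (tot > 0) ev$steady[1, cc$subset] / tot else rep(0, nrow(cc))
    diag[[length(diag) + 1]] <- tibble(
      criterion = "composition", subset = cc$subset, value = fr,
      lower = cc$lower, upper = cc$upper,
      pass = fr >= cc$lower & fr <= cc$upper
    )
  }
  if (is.finite(constraints$max_steady_days)) {
    diag[[length(diag) + 1]] <- tibble(
      criterion = "time_to_steady", subset = paste(constraints$time_subsets,
                                                   collapse = "+"),
      value = ev$arrival_days[1], lower = 0,
      upper = constraints$max_steady_days,
      pass = is.finite(ev$arrival_days[1]) &&
        ev$arrival_days[1] <= constraints$max_steady_days
    )
  }
  diag <- bind_rows(diag)
  structure(list(pass = all(diag$pass), diagnostics = diag),
            class = "bk_screen")
}

#' @export
print.bk_screen <- function(x, ...) {
  cat("<bk_screen> ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  print(x$diagnostics)
  invisible(x)
}

#' Exhaustive constrained grid search
#'
#' Enumerates every point of the grid, discards points failing the
#' steady-state screening constraints, computes the least-squares objective
#' ([sum_squared_deviations()]) for the rest against the labeled-cell data,
#' and returns the constrained global minimum. The search is deterministic;
#' ties are broken lexicographically in the order the varied parameters were
#' given (the first listed parameter is most significant, smaller values
#' first).
#'
#' Evaluation exploits the model's feed-forward structure: bone-marrow
#' dynamics do not depend on splenic parameters, so the emigration flux
#' (total and labeled) is integrated once and every candidate's splenic
#' subsystem is propagated against that trace, batched across the grid.
#'
#' @param grid A [parameter_grid()].
#' @param data A labeling dataset (tibble with `subset`, `time_days`,
#'   `mouse_id`, `labeled_count`), e.g. from [generate_dataset()] or
#'   [read_labeling_dataset()]. All data times must lie on the integration
#'   substep grid.
#' @param constraints A [constraint_set()], e.g. from
#'   [dataset_to_constraints()].
#' @param topo A [model_topology()].
#' @param bm Bone-marrow parameters (fixed during the fit).
#' @param subsets Subsets entering the objective; default `c("T3",
#'   "mature")`, alternatively all three splenic subsets.
#' @param schedule Labeling schedule assumed for the simulated curves.
#' @param dt RK4 substep in 6-h units.
#' @param max_points Refuse grids larger than this (guard against accidental
#'   enormous enumerations); the error reports the computed cardinality.
#' @param bands Error bands for acceptable-range extraction (default
#'   [experimental_error_bands()] of the data); `NULL` disables.
#' @return A `bk_fit` object; see [tidy.bk_fit()] and [glance.bk_fit()].
#'   With an empty feasible set the fit has `ss = Inf` and no best point.
#' @export
grid_search <- function(grid, data, constraints, topo,
                        bm = reference_parameters("bm_default"),
                        subsets = c("T3", "mature"),
                        schedule = labeling_schedule(), dt = 0.1,
                        max_points = 1e6,
                        bands = experimental_error_bands(data)) {
  stopifnot(inherits(grid, "bk_grid"))
  if (grid$cardinality > max_points) {
    abort(sprintf("grid cardinality %.0f exceeds max_points %.0f",
                  grid$cardinality, max_points),
          class = "bk_grid_too_large")
  }
  subsets <- match.arg(subsets, SPLENIC_SUBSETS, several.ok = TRUE)
  base <- check_topology(grid$base, topo, zap = TRUE)
  m2t3 <- topo$direction == "mature_to_t3"
  # varying a rate that the topology forbids is a configuration error
  for (nm in names(grid$vary)) {
    forbidden <- (nm %in% names(topo$edges) && !topo$edges[[nm]]) ||
      (m2t3 && nm == "delta_3m") || (!m2t3 && nm == "delta_m3")
    if (forbidden && any(grid$vary[[nm]] > 0)) {
      abort(paste0("grid varies '", nm, "' but that edge is absent from the topology"),
            class = "bk_topology_mismatch")
    }
  }

  varied <- names(grid$vary)
  cand_var <- expand.grid(rev(grid$vary), KEEP.OUT.ATTRS = FALSE)
  cand_var <- cand_var[, rev(seq_along(cand_var)), drop = FALSE]
  names(cand_var) <- varied
  n <- nrow(cand_var)
  cand <- as.data.frame(plain(base))[rep(1, n), , drop = FALSE]
  for (nm in varied) cand[[nm]] <- cand_var[[nm]]
  rownames(cand) <- NULL

  d <- data |>
    filter(.data$subset %in% subsets) |>
    mutate(.t = round(.data$time_days, 9))
  if (!nrow(d)) abort("no data rows in the fitted subsets",
                      class = "bk_invalid_argument")
  sample_days <- sort(unique(d$.t))
  sample_steps <- round(sample_days * UNITS_PER_DAY / dt)
  if (max(abs(sample_steps * dt - sample_days * UNITS_PER_DAY)) > 1e-6) {
    abort("data times must fall on the integration substep grid",
          class = "bk_alignment_error")
  }
  stats_tbl <- d |>
    group_by(.data$subset, .data$.t) |>
    summarise(n = dplyr::n(), ybar = mean(.data$labeled_count),
              ssw = sum((.data$labeled_count - mean(.data$labeled_count))^2),
              .groups = "drop") |>
    mutate(col = match(.data$.t, sample_days))

  bands_mat <- NULL
  if (!is.null(bands)) {
    bands_mat <- bands |>
      filter(.data$subset %in% subsets) |>
      mutate(col = match(round(.data$time_days, 9), sample_days)) |>
      filter(!is.na(.data$col))
  }

  label_units <- max(sample_days) * UNITS_PER_DAY
  screen_units <- if (is.finite(constraints$max_steady_days)) {
    constraints$max_steady_days * UNITS_PER_DAY
  } else 0
  ctx <- build_bm_context(bm, dt, label_units = label_units,
                          screen_units = screen_units, schedule = schedule)

  ev <- evaluate_spleen_batch(cand, m2t3, ctx, constraints = constraints,
                              ss_stats = stats_tbl,
                              sample_steps = sample_steps,
                              bands_mat = bands_mat)

  evaluations <- as_tibble(cand_var)
  evaluations$ss <- ev$ss
  evaluations$passes <- ev$pass
  evaluations$within_bands <- if (is.null(bands_mat)) NA else ev$within
  evaluations$arrival_days <- ev$arrival_days

  feasible <- which(ev$pass)
  if (length(feasible)) {
    best_i <- feasible[which.min(ev$ss[feasible])]
    best_q <- as_spleen_parameters(as.list(cand[best_i, ]))
    ss_min <- ev$ss[best_i]
  } else {
    best_i <- NA_integer_
    best_q <- NULL
    ss_min <- Inf
  }

  fit <- structure(
    list(
      best = best_q, best_index = best_i, ss = ss_min,
      varied = varied, evaluations = evaluations,
      n_evaluated = n, n_passing = sum(ev$pass),
      n_obs = nrow(d), n_params = length(varied),
      topo = topo, bm = bm, base = base, subsets = subsets,
      schedule = schedule, dt = dt, bands = bands,
      sample_days = sample_days
    ),
    class = "bk_fit"
  )
  fit$ranges <- acceptable_ranges(fit)
  fit
}

#' Marginal acceptable parameter ranges
#'
#' For each varied parameter, the minimum and maximum value over all
#' accepted grid points — points that pass the screening constraints and
#' whose simulated curves lie within every experimental error band. The
#' ranges are marginal: combinations of in-range values are not themselves
#' guaranteed acceptable.
#'
#' @param fit A `bk_fit` from [grid_search()].
#' @param bands Optional replacement error bands (tibble `subset`,
#'   `time_days`, `lower`, `upper`); default: the acceptance flags already
#'   stored in the fit.
#' @return A tibble with columns `parameter`, `lower`, `upper`, `best` and
#'   attribute `n_accepted`; zero rows if no point is accepted
#'   (empty-range report). The best-fit point always counts as accepted, so
#'   each range contains the best-fit value.
#' @export
acceptable_ranges <- function(fit, bands = NULL) {
  stopifnot(inherits(fit, "bk_fit"))
  ev <- fit$evaluations
  if (!is.null(bands)) {
    bands_keyed <- bands |> mutate(.t = round(.data$time_days, 9))
    off_grid <- setdiff(round(bands_keyed$.t, 9), round(fit$sample_days, 9))
    if (length(off_grid)) {
      abort("replacement bands must use the fitted sample times",
            class = "bk_alignment_error")
    }
    # re-thresholding against new bands needs the simulated curves back
    ctx <- build_bm_context(fit$bm, fit$dt,
                            label_units = max(fit$sample_days) * UNITS_PER_DAY,
                            schedule = fit$schedule)
    cand <- as.data.frame(plain(fit$base))[rep(1, nrow(ev)), , drop = FALSE]
    for (nm in fit$varied) cand[[nm]] <- ev[[nm]]
    sample_steps <- round(fit$sample_days * UNITS_PER_DAY / fit$dt)
    bm_mat <- bands_keyed |>
      filter(.data$subset %in% fit$subsets) |>
      mutate(col = match(.data$.t, round(fit$sample_days, 9)))
    stats0 <- tibble(subset = bm_mat$subset[1], col = 1, n = 0, ybar = 0,
                     ssw = 0)
    ev2 <- evaluate_spleen_batch(cand, fit$topo$direction == "mature_to_t3",
                                 ctx, ss_stats = stats0,
                                 sample_steps = sample_steps,
                                 bands_mat = bm_mat)
    accepted <- ev$passes & ev2$within
  } else if (all(is.na(ev$within_bands))) {
    accepted <- ev$passes
  } else {
    accepted <- ev$passes & ev$within_bands
  }
  # the best-fit point is an acceptable model by construction, so every
  # marginal range contains the best-fit value
  if (!is.na(fit$best_index)) accepted[fit$best_index] <- TRUE
  if (!any(accepted)) {
    out <- tibble(parameter = character(0), lower = numeric(0),
                  upper = numeric(0), best = numeric(0))
    attr(out, "n_accepted") <- 0L
    return(out)
  }
  acc <- ev[accepted, fit$varied, drop = FALSE]
  best <- if (!is.null(fit$best)) unlist(plain(fit$best)[fit$varied]) else
    rep(NA_real_, length(fit$varied))
  out <- tibble(
    parameter = fit$varied,
    lower = unname(vapply(acc, min, numeric(1))),
    upper = unname(vapply(acc, max, numeric(1))),
    best = unname(best)
  )
  attr(out, "n_accepted") <- sum(accepted)
  out
}

#' @export
print.bk_fit <- function(x, ...) {
  cat("<bk_fit> ", x$topo$direction, " | ",
      format(x$n_evaluated, big.mark = ","), " grid points, ",
      x$n_passing, " passing constraints\n", sep = "")
  if (is.null(x$best)) {
    cat("  empty feasible set (no point passed the constraints)\n")
  } else {
    cat(sprintf("  SS = %.6g over %d observations (%s), M = %d\n",
                x$ss, x$n_obs, paste(x$subsets, collapse = "+"), x$n_params))
    print(x$ranges)
  }
  invisible(x)
}
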
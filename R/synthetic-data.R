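#' Design of a continuous-labeling experiment
#'
#' Sampling plan emulating an in vivo BrdU continuous-labeling study: the
#' days (since labeling start) at which spleens are analysed, the number of
#' mice sacrificed per time point, and the subsets measured. The default is
#' eight time points over two weeks with four mice each.
#'
#' @param sample_days Sampling times, days since labeling start (>= 0).
#' @param n_mice Mice per time point (>= 1).
#' @param subsets Measured splenic subsets.
#' @return A `bk_design` object.
#' @export
experiment_design <- function(sample_days = c(1, 2, 4, 6, 8, 10, 12, 14),
                              n_mice = 4, subsets = splenic_subsets()) {
  if (!is.numeric(sample_days) || any(sample_days < 0)) {
    abort("sample_days must be >= 0", class = "bk_invalid_argument")
  }
  if (!is.numeric(n_mice) || n_mice < 1) {
    abort("n_mice must be >= 1", class = "bk_invalid_argument")
  }
  subsets <- match.arg(subsets, SPLENIC_SUBSETS, several.ok = TRUE)
  structure(
    list(sample_days = sort(unique(sample_days)), n_mice = as.integer(n_mice),
         subsets = subsets),
    class = "bk_design"
  )
}

#' Measurement noise model for labeled-cell counts
#'
#' Multiplicative log-normal noise with a given coefficient of variation:
#' each observed labeled count is the simulated truth times a mean-1
#' log-normal deviate (cell-count measurements are positive with roughly
#' constant CV). An optional additive floor models the detection limit.
#'
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.10).
#' @param floor Detection floor in cells (observations are truncated below
#'   at this value; default 0).
#' @return A `bk_noise` object.
#' @export
noise_model <- function(cv = 0.10, floor = 0) {
  if (!is.numeric(cv) || cv < 0 || !is.numeric(floor) || floor < 0) {
    abort("need cv >= 0 and floor >= 0", class = "bk_invalid_argument")
  }
  structure(list(cv = cv, floor = floor), class = "bk_noise")
}

# mean-1 log-normal deviates with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic BrdU labeling dataset
#'
#' Simulates the labeling kinetics of a known ("truth") model and overlays
#' per-mouse measurement noise, producing a dataset with the structure of
#' the original experiments: one labeled-cell number per (subset, time,
#' mouse), plus the observed total-number and composition ranges used to
#' build screening constraints. Each mouse's labeled count is the simulated
#' count times an independent mean-1 log-normal deviate (truncated at the
#' detection floor); the per-mouse implied total is the observed labeled
#' count divided by the true labeled fraction. Deterministic for a fixed
#' seed.
#'
#' @inheritParams integrate_model
#' @param design An [experiment_design()].
#' @param noise A [noise_model()].
#' @param seed Integer seed (recorded in the provenance).
#' @param schedule A [labeling_schedule()].
#' @return A `bk_dataset` tibble with columns `subset`, `time_days`,
#'   `mouse_id`, `labeled_count`, `total_count`, plus attributes `ranges`
#'   (per-subset total and composition ranges) and `provenance` (true
#'   parameters, topology, design, noise, seed).
#' @export
#' @examples
#' ds <- generate_dataset(reference_parameters("bm_default"),
#'                        reference_parameters("table2_best_fit"),
#'                        model_topology("mature_to_t3"),
#'                        design = experiment_design(n_mice = 2), seed = 1)
#' head(ds)
generate_dataset <- function(p, q, topo, design = experiment_design(),
                             noise = noise_model(), seed = 1,
                             schedule = labeling_schedule(), dt = 0.1) {
  stopifnot(inherits(design, "bk_design"), inherits(noise, "bk_noise"))
  p <- as_bm_parameters(p)
  q <- check_topology(as_spleen_parameters(q), topo)
  sim <- simulate_brdu(p, q, topo, sample_days = design$sample_days,
                       schedule = schedule, dt = dt,
                       subsets = design$subsets)
  if (any(!is.finite(sim$total))) {
    abort("truth model does not reach a bounded steady state; generation refused",
          class = "bk_unbounded")
  }
  obs <- withr::with_seed(seed, {
    sim |>
      tidyr::crossing(mouse_id = seq_len(design$n_mice)) |>
      arrange(.data$subset, .data$time_days, .data$mouse_id) |>
      mutate(
        deviate = rlnorm_cv(dplyr::n(), noise$cv),
        labeled_count = pmax(.data$labeled * .data$deviate, noise$floor),
        total_count = ifelse(.data$fraction > 0,
                             .data$labeled_count / .data$fraction,
                             .data$total)
      )
  })
  ranges <- obs |>
    group_by(.data$subset) |>
    summarise(total_lower = min(.data$total_count),
              total_upper = max(.data$total_count), .groups = "drop")
  comp <- obs |>
    group_by(.data$time_days, .data$mouse_id) |>
    mutate(comp_frac = .data$total_count / sum(.data$total_count)) |>
    ungroup() |>
    group_by(.data$subset) |>
    summarise(comp_lower = min(.data$comp_frac),
              comp_upper = max(.data$comp_frac), .groups = "drop")
  ranges <- left_join(ranges, comp, by = "subset")
  out <- obs |>
    select("subset", "time_days", "mouse_id", "labeled_count", "total_count")
  structure(out,
            class = c("bk_dataset", class(tibble())),
            ranges = ranges,
            provenance = list(
              synthetic = TRUE,
              true_bm = plain(p), true_spleen = plain(q),
              topology = list(direction = topo$direction,
                              edges = as.list(topo$edges)),
              design = list(sample_days = design$sample_days,
                            n_mice = design$n_mice,
                            subsets = design$subsets),
              noise = list(cv = noise$cv, floor = noise$floor),
              seed = seed, dt = dt
            ))
}

#' Build screening constraints from a dataset
#'
#' Converts the observed total-number and composition ranges of a dataset
#' into the [constraint_set()] used to screen grid points: each range is the
#' observed min/max widened symmetrically by `padding` (a fraction of the
#' half-width), and the time-to-steady-state bound defaults to the 2-month
#' growth window.
#'
#' @param data A `bk_dataset` (or any tibble carrying a `ranges` attribute
#'   with per-subset total and composition ranges).
#' @param padding Fractional widening of each range's half-width
#'   (default 0.1).
#' @inheritParams constraint_set
#' @return A `bk_constraints` object.
#' @export
dataset_to_constraints <- function(data, padding = 0.1, max_steady_days = 60,
                                   steady_frac = 0.01,
                                   time_subsets = c("T12", "T3")) {
  if (!nrow(data)) abort("empty dataset", class = "bk_invalid_argument")
  if (padding < 0) abort("padding must be >= 0", class = "bk_invalid_argument")
  ranges <- attr(data, "ranges")
  if (is.null(ranges)) {
    if (!"total_count" %in% names(data)) {
      abort("dataset carries no totals information",
            class = "bk_invalid_argument")
    }
    ranges <- data |>
      group_by(.data$subset) |>
      summarise(total_lower = min(.data$total_count),
                total_upper = max(.data$total_count), .groups = "drop")
  }
  pad <- function(lo, hi) {
    half <- (hi - lo) / 2
    mid <- (hi + lo) / 2
    list(lower = mid - (1 + padding) * half, upper = mid + (1 + padding) * half)
  }
  tp <- pad(ranges$total_lower, ranges$total_upper)
  totals <- tibble(subset = ranges$subset,
                   lower = pmax(0, tp$lower), upper = tp$upper)
  composition <- NULL
  if (all(c("comp_lower", "comp_upper") %in% names(ranges))) {
    cp <- pad(ranges$comp_lower, ranges$comp_upper)
    composition <- tibble(subset = ranges$subset,
                          lower = pmax(0, cp$lower),
                          upper = pmin(1, cp$upper))
  }
  constraint_set(totals = totals, composition = composition,
                 max_steady_days = max_steady_days,
                 steady_frac = steady_frac, time_subsets = time_subsets)
}
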
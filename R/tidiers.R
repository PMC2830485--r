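#' Tidy a grid-search fit
#'
#' One row per varied parameter: the best-fit value and the marginal
#' acceptable range (span over all accepted grid points).
#'
#' @param x A `bk_fit` from [grid_search()].
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `estimate`, `lower`, `upper`.
#' @exportS3Method generics::tidy
tidy.bk_fit <- function(x, ...) {
  est <- if (!is.null(x$best)) unlist(plain(x$best)[x$varied]) else
    rep(NA_real_, length(x$varied))
  rng <- x$ranges
  tibble(parameter = x$varied, estimate = unname(est)) |>
    left_join(rng |> select("parameter", "lower", "upper"), by = "parameter")
}

#' Glance at a grid-search fit
#'
#' @param x A `bk_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `ss` (minimal sum of squared deviations),
#'   `n_obs`, `n_params`, `aicc`, `n_evaluated`, `n_passing`, `n_accepted`,
#'   `feasible`.
#' @exportS3Method generics::glance
glance.bk_fit <- function(x, ...) {
  score <- if (!is.null(x$best) && x$ss > 0 && x$n_obs > x$n_params + 1) {
    aicc(x$ss, x$n_obs, x$n_params)
  } else NA_real_
  tibble(
    ss = x$ss, n_obs = x$n_obs, n_params = x$n_params, aicc = score,
    n_evaluated = x$n_evaluated, n_passing = x$n_passing,
    n_accepted = attr(x$ranges, "n_accepted") %||% NA_integer_,
    feasible = !is.null(x$best)
  )
}

#' Tidy a topology comparison
#'
#' @param x A `bk_model_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A tibble with one row per model (`model`, `ss`, `n`, `m`,
#'   `aicc`, `preferred`).
#' @exportS3Method generics::tidy
tidy.bk_model_comparison <- function(x, ...) {
  x$models |> mutate(preferred = .data$model == x$preferred)
}

#' Glance at a topology comparison
#'
#' @param x A `bk_model_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: `preferred`, `delta_aicc`, `probability`.
#' @exportS3Method generics::glance
glance.bk_model_comparison <- function(x, ...) {
  tibble(preferred = x$preferred, delta_aicc = x$delta,
         probability = x$probability)
}
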
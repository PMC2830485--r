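#' Small-sample-corrected Akaike score from a least-squares fit
#'
#' The AICc score used to compare competing topologies, with the sum of
#' squared deviations standing in for the maximised likelihood:
#' `N * log(SS / N) + 2 * M + 2 * M * (M + 1) / (N - M - 1)`, where `N` is
#' the number of data points and `M` the number of parameters actually
#' varied by the fit (rates fixed at zero by the topology do not count).
#' The score is monotone increasing in SS at fixed N and M; lower is better.
#'
#' @param ss Minimal sum of squared deviations of the fit (> 0).
#' @param n Number of data points (must exceed `m + 1` for the correction to
#'   be defined).
#' @param m Number of fitted parameters.
#' @return The AICc score (dimensionless).
#' @export
#' @examples
#' aicc(12.5, n = 20, m = 6)
aicc <- function(ss, n, m) {
  if (any(ss <= 0)) {
    abort("ss must be > 0 (a zero-deviation fit has no defined score)",
          class = "bk_invalid_argument")
  }
  if (any(n <= m + 1)) {
    abort("need n > m + 1 for the small-sample correction",
          class = "bk_invalid_argument")
  }
  n * log(ss / n) + 2 * m + 2 * m * (m + 1) / (n - m - 1)
}

#' Difference between two AICc scores
#'
#' `delta_aicc(a, b) = a - b`: negative when model A (the lower-scoring,
#' better-fitting model) is compared against model B.
#'
#' @param score_a,score_b Finite AICc scores.
#' @return The signed difference.
#' @export
delta_aicc <- function(score_a, score_b) {
  if (any(!is.finite(c(score_a, score_b)))) {
    abort("both scores must be finite", class = "bk_invalid_argument")
  }
  score_a - score_b
}

#' Probability that the better-scoring model is the correct one
#'
#' The two-model Akaike weight of the lower-scoring model,
#' `1 / (1 + exp(-|delta| / 2))`: 0.5 when the scores tie, approaching 1 as
#' the score gap grows. Because the sum of squared deviations approximates
#' the maximised likelihood, this probability is itself an approximation.
#' A weight of 0.86 corresponds to a score gap of about 3.63.
#'
#' @param delta AICc score difference (sign irrelevant).
#' @return Probability in `(0.5, 1]` (exactly 0.5 at `delta = 0`).
#' @export
#' @examples
#' model_probability(0)      # 0.5
#' model_probability(-3.63)  # ~0.86
model_probability <- function(delta) {
  if (any(!is.finite(delta))) {
    abort("delta must be finite", class = "bk_invalid_argument")
  }
  1 / (1 + exp(-abs(delta) / 2))
}

#' Compare two fitted topologies by AICc
#'
#' Scores two [grid_search()] fits of the same dataset (identical
#' observation count) and reports which topology the data prefer and with
#' what approximate probability.
#'
#' @param fit_a,fit_b `bk_fit` objects fitted to the same data.
#' @param labels Length-2 character labels; default the topology directions.
#' @return A `bk_model_comparison` object with elements `models` (tibble of
#'   per-model SS, N, M, AICc), `delta` (better minus worse, negative),
#'   `preferred` (label) and `probability`.
#' @seealso [tidy.bk_model_comparison()], [glance.bk_model_comparison()]
#' @export
compare_models <- function(fit_a, fit_b,
                           labels = c(fit_a$topo$direction,
                                      fit_b$topo$direction)) {
  stopifnot(inherits(fit_a, "bk_fit"), inherits(fit_b, "bk_fit"))
  if (fit_a$n_obs != fit_b$n_obs) {
    abort("fits use different numbers of data points; not comparable",
          class = "bk_invalid_argument")
  }
  if (is.null(fit_a$best) || is.null(fit_b$best)) {
    abort("cannot compare a fit with an empty feasible set",
          class = "bk_invalid_argument")
  }
  score_a <- aicc(fit_a$ss, fit_a$n_obs, fit_a$n_params)
  score_b <- aicc(fit_b$ss, fit_b$n_obs, fit_b$n_params)
  better <- if (score_a <= score_b) 1L else 2L
  delta <- if (better == 1L) delta_aicc(score_a, score_b) else
    delta_aicc(score_b, score_a)
  structure(
    list(
      models = tibble(
        model = labels,
        ss = c(fit_a$ss, fit_b$ss),
        n = c(fit_a$n_obs, fit_b$n_obs),
        m = c(fit_a$n_params, fit_b$n_params),
        aicc = c(score_a, score_b)
      ),
      delta = delta,
      preferred = labels[better],
      probability = model_probability(delta)
    ),
    class = "bk_model_comparison"
  )
}

#' @export
print.bk_model_comparison <- function(x, ...) {
  cat("<bk_model_comparison>\n")
  print(x$models)
  cat(sprintf("preferred: %s (delta AICc = %.3f, probability %.1f%%)\n",
              x$preferred, x$delta, 100 * x$probability))
  invisible(x)
}
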
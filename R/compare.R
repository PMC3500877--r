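#' Rank competing topologies by fit residual
#'
#' Fits each candidate model to the same dataset with the two-stage
#' procedure and ranks candidates by `total_epsilon` (ascending mean of the
#' per-observable normalized residuals). Per-observable residuals are
#' reported so split verdicts — one observable favouring one topology,
#' another the competitor — remain visible. A candidate whose fit fails is
#' marked failed and ranked last; the others are still ranked.
#'
#' @param data a `gr_dataset`.
#' @param candidate_ids two or more model ids (or catalogue names).
#' @inheritParams fit_model
#' @return A `gr_comparison`: list with `table` (model_id, name,
#'   total_epsilon, rank, failed), `by_observable` (long table of
#'   per-observable epsilons), and `fits` (named list of `gr_fit`s).
#' @export
compare_models <- function(data, candidate_ids, n_starts = 24, seed = 1,
                           refine = TRUE) {
  if (length(candidate_ids) < 2)
    stop_validation("need at least 2 candidate models to compare")
  data <- as_timecourse(data)
  specs <- lapply(candidate_ids, as_gr_model)
  fits <- vector("list", length(specs))
  names(fits) <- vapply(specs, function(s) as.character(s$model_id),
                        character(1))
  eps <- rep(NA_real_, length(specs))
  for (i in seq_along(specs)) {
    f <- try(fit_model(specs[[i]], data, n_starts = n_starts, seed = seed,
                       refine = refine), silent = TRUE)
    if (!inherits(f, "try-error")) {
      fits[[i]] <- f
      eps[i] <- f$total_epsilon
    }
  }
  if (all(is.na(eps)))
    stop_numerical("every candidate fit failed")
  ord <- order(eps, na.last = TRUE)
  tab <- data.frame(
    model_id = vapply(specs, `[[`, integer(1), "model_id"),
    name = vapply(specs, `[[`, character(1), "name"),
    total_epsilon = eps,
    failed = is.na(eps),
    stringsAsFactors = FALSE)
  tab$rank <- match(seq_along(eps), ord)
  tab <- tab[order(tab$rank), c("rank", "model_id", "name",
                                "total_epsilon", "failed")]
  rownames(tab) <- NULL
  by_obs <- do.call(rbind, lapply(fits[!vapply(fits, is.null, logical(1))],
    function(f) data.frame(model_id = f$model$model_id,
                           observable = names(f$epsilon_by_observable),
                           epsilon = unname(f$epsilon_by_observable),
                           stringsAsFactors = FALSE)))
  rownames(by_obs) <- NULL
  structure(list(table = tab, by_observable = by_obs, fits = fits),
            class = "gr_comparison")
}

#' @export
print.gr_comparison <- function(x, ...) {
  cat("Model comparison (ascending total epsilon):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Classify a trajectory as linear or logarithmic
#'
#' Direct transcription-factor targets respond without upstream delay and
#' tend to rise roughly linearly, while indirect targets — driven through an
#' intermediate that must itself be synthesised — tend toward a logarithmic
#' shape. The classifier least-squares fits both two-parameter families,
#' `y = a*t + b` and `y = a*ln(1+t) + b` (the `1+t` keeps the logarithm
#' finite at the t = 0 control), and returns the family with the smaller sum
#' of squared errors. The verdict is invariant to positive affine rescaling
#' of the values. Ties (relative SSE difference below 1e-9) go to
#' `"linear"`.
#'
#' @param times sampling times in hours (>= 4 points).
#' @param values trajectory values at `times`; must not be constant.
#' @return `"linear"` or `"logarithmic"`.
#' @examples
#' t <- c(0, 2, 10, 24)
#' classify_trend(t, 2 * t + 1)            # "linear"
#' classify_trend(t, 3 * log(1 + t) + 1)   # "logarithmic"
#' @export
classify_trend <- function(times, values) {
  if (length(times) < 4 || length(values) != length(times))
    stop_validation("need >= 4 (time, value) pairs")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop_validation("non-finite trajectory input")
  if (diff(range(values)) <= 1e-12 * max(abs(values), 1))
    stop_validation("trend undefined for a constant trajectory")
  sse <- function(x) sum(lm(values ~ x)$residuals^2)
  sse_lin <- sse(times)
  sse_log <- sse(log1p(times))
  if (abs(sse_lin - sse_log) < 1e-9 * max(sse_lin, sse_log, 1e-300))
    return("linear")
  if (sse_lin <= sse_log) "linear" else "logarithmic"
}

#' Trend label of a simulated observable
#'
#' Convenience wrapper: simulates a model and classifies one observable's
#' trajectory with [classify_trend()].
#'
#' @inheritParams simulate_model
#' @param species observable name, `"<gene>_<level>"`.
#' @param classify_times times at which the trajectory is sampled for
#'   classification.
#' @export
trend_of <- function(spec, params = default_params(spec),
                     species, classify_times = seq(0, 24, by = 0.5)) {
  sim <- simulate_model(spec, params,
                        times = sort(unique(c(0, classify_times))),
                        stimulus_on = TRUE)
  classify_trend(classify_times,
                 fold_change_at(sim, species, classify_times))
}
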
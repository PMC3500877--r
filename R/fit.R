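#' Normalized least-squares residual
#'
#' The fit statistic used to score agreement between observed and simulated
#' fold changes:
#' \deqn{\epsilon = \frac{1}{n}\sum_{i=1}^n \left(\frac{y_i - Y_i}{Y_i}\right)^2}
#' where \eqn{y_i} are observed values, \eqn{Y_i} simulated values at the
#' same times, and \eqn{n} the number of data points. Note the denominator is
#' the *simulated* value; trajectories are normalized to 1 at baseline so the
#' denominator never vanishes for well-posed models.
#'
#' @param y observed values.
#' @param Y simulated values, same length, all bounded away from zero.
#' @return non-negative scalar; 0 iff `y == Y`.
#' @examples
#' residual_epsilon(c(2, 3), c(1, 2))  # 0.625
#' @export
residual_epsilon <- function(y, Y) {
  if (length(y) != length(Y) || length(y) < 1)
    stop_validation("y and Y must have equal length >= 1")
  if (any(!is.finite(y)) || any(!is.finite(Y)))
    stop_validation("non-finite values in residual input")
  if (any(abs(Y) < 1e-9))
    stop_numerical("residual undefined at near-zero simulated value")
  mean(((y - Y) / Y)^2)
}

# Simulated observable values at exactly the data's sample times.
sim_at_times <- function(spec, params, times, clamp_basal = FALSE) {
  grid <- sort(unique(c(0, times)))
  if (length(grid) < 2) grid <- c(0, max(grid, 1e-6) + 1e-6)
  sim <- simulate_model(spec, params, times = grid, stimulus_on = TRUE,
                        clamp_basal = clamp_basal)
  sim$trajectories[match(times, grid), , drop = FALSE]
}

# Build the optimizer objective once per fit: a function from the full
# named parameter vector to the residual vector — normalized deviations
# (y - Y)/Y over the replicate means, plus a smooth penalty when the
# baseline-balance constraint (derived basal synthesis >= 0) is violated.
# All indexing is precomputed; evaluation is purely numeric.
make_objective <- function(spec, means) {
  eng <- compile_engine(spec)
  grid <- sort(unique(c(0, means$time_h)))
  tidx <- match(means$time_h, grid)
  cidx <- match(paste0(means$gene, "_", means$level),
                paste0(eng$obs$gene, "_", eng$obs$level))
  if (any(is.na(cidx)))
    stop_validation("dataset contains observables absent from model %d: %s",
                    spec$model_id,
                    paste(unique(paste0(means$gene, "_",
                                        means$level)[is.na(cidx)]),
                          collapse = ", "))
  ybar <- means$mean_fold
  nr <- length(ybar) + length(spec$genes)   # constant length for nls.lm
  function(full) {
    states <- try(eng$solve_states(full, grid, D = 1, clamp = TRUE),
                  silent = TRUE)
    if (inherits(states, "try-error")) return(rep(1e6, nr))
    Y <- eng$observe(states)[cbind(tidx, cidx)]
    r <- (ybar - Y) / pmax(abs(Y), 1e-9)
    # weight chosen so the penalty dominates at convergence yet stays
    # shallow enough for the optimizer to traverse the infeasible region
    c(r, 10 * attr(states, "deficit"))
  }
}

# Multi-start bounded Levenberg-Marquardt over the named free parameters.
# Starts: the supplied base point plus seeded log-scale Latin-hypercube
# points. Later starts are skipped once a start reaches machine-precision
# deviance (the data are interpolated; nothing better exists).
multistart_fit <- function(spec, free, start_base, means, n_starts, seed,
                           extra_starts = NULL) {
  lower <- rep(RATE_LOWER, length(free))
  upper <- rep(RATE_UPPER, length(free))
  obj <- make_objective(spec, means)
  fidx <- match(free, names(start_base))
  p_work <- start_base
  fn <- function(theta) {
    p_work[fidx] <- theta
    obj(p_work)
  }
  starts <- c(list(pmin(pmax(start_base[free], RATE_LOWER), RATE_UPPER)),
              extra_starts)
  if (n_starts > length(starts)) {
    u <- with_seed(seed, lhs::randomLHS(n_starts - length(starts),
                                        length(free)))
    lo <- log(RATE_LOWER); hi <- log(RATE_UPPER)
    for (i in seq_len(nrow(u)))
      starts[[length(starts) + 1]] <- setNames(exp(lo + (hi - lo) * u[i, ]),
                                               free)
  }
  best <- NULL
  for (st in starts) {
    res <- try(minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper, fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = 200,
                                           ftol = 1e-12, ptol = 1e-12)),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    dev <- res$deviance
    if (is.null(best) || dev < best$deviance * (1 - 1e-12) ||
        (abs(dev - best$deviance) <= 1e-12 * max(dev, 1) &&
         sum(res$par^2) < sum(best$par^2)))
      best <- list(par = setNames(res$par, free), deviance = dev,
                   info = res$info)
    if (best$deviance < 1e-20) break
  }
  if (is.null(best))
    stop_numerical("all %d optimizer starts failed for model %d",
                   n_starts, spec$model_id)
  best
}

# An observable is uninformative when its replicate means are flat at 1.
flat_observables <- function(means) {
  keys <- unique(paste(means$gene, means$level))
  keys[vapply(keys, function(k) {
    v <- means$mean_fold[paste(means$gene, means$level) == k]
    all(abs(v - 1) < 1e-6) || length(v) < 2
  }, logical(1))]
}

#' Stage 1: fit the GR submodel
#'
#' Estimates the GR rates (`dm_GR`, `dp_GR`, and the autoregulation rate
#' `a_GR_GR` where present) from the GR observables alone, using a GR-only
#' submodel with inputs from other genes removed. This mirrors the two-part
#' estimation strategy: GR parameters first, the rest afterwards with GR
#' frozen. Bounded `[0.01, 1]` multi-start Levenberg-Marquardt on the
#' normalized deviations of the replicate means.
#'
#' Flat GR data (structural in Models 5-6, where nothing acts upstream of
#' GR) are non-identifiable: the fit is flagged and the defaults returned.
#'
#' @inheritParams param_names
#' @param data a `gr_dataset` containing GR observables.
#' @param n_starts number of multi-start initial points (first start is the
#'   default parameter vector, the rest a seeded Latin hypercube).
#' @param seed integer seed controlling the start points.
#' @return list with `params` (named GR rates), `nonidentifiable`
#'   (character vector of flagged observables), `deviance`, `n_starts`,
#'   `seed`; class `gr_stage1`.
#' @export
fit_stage1_gr <- function(spec, data, n_starts = 24, seed = 1) {
  spec <- as_gr_model(spec)
  data <- as_timecourse(data)
  gr <- data[data$gene == "GR", , drop = FALSE]
  if (nrow(gr) == 0)
    stop_validation("no GR observables in dataset; stage-1 requires GR protein and/or mRNA series")
  sub <- gr_submodel(spec)
  free <- param_names(sub)               # dm_GR, dp_GR (+ a_GR_GR)
  means <- dataset_means(gr)
  flat <- flat_observables(means)
  defaults <- default_params(sub)
  if (length(flat) == nrow(dataset_observables(gr))) {
    return(structure(list(params = defaults, nonidentifiable = flat,
                          deviance = 0, n_starts = 0, seed = seed),
                     class = "gr_stage1"))
  }
  best <- multistart_fit(sub, free, defaults, means, n_starts, seed)
  structure(list(params = best$par, nonidentifiable = flat,
                 deviance = best$deviance, n_starts = n_starts, seed = seed),
            class = "gr_stage1")
}

#' Stage 2: fit the remaining rates with GR frozen
#'
#' Estimates all rates not fixed by stage 1 (downstream degradation rates and
#' edge activation/repression rates) against the full dataset, with the
#' stage-1 GR rates frozen. Residuals are normalized deviations of the
#' replicate means over every observable present in the data; the reported
#' per-observable residual is [residual_epsilon()] at the data's sample
#' times and `total_epsilon` its arithmetic mean across observables. The
#' latent intermediate X is never scored (it is unobserved).
#'
#' @inheritParams fit_stage1_gr
#' @param stage1 a `gr_stage1` result (or a named vector of GR rates).
#' @return a `gr_fit` object; see [fit_model()].
#' @export
fit_stage2 <- function(spec, stage1, data, n_starts = 24, seed = 1) {
  spec <- as_gr_model(spec)
  data <- as_timecourse(data)
  s1par <- if (inherits(stage1, "gr_stage1")) stage1$params else stage1
  s1flags <- if (inherits(stage1, "gr_stage1")) stage1$nonidentifiable
             else character(0)
  free <- setdiff(param_names(spec), names(s1par))
  base <- default_params(spec)
  base[names(s1par)] <- s1par
  means <- dataset_means(data)
  flat <- flat_observables(means)
  if (length(free)) {
    best <- multistart_fit(spec, free, base, means, n_starts, seed)
    base[free] <- best$par
    deviance <- best$deviance
  } else deviance <- sum(make_objective(spec, means)(base)^2)
  finish_fit(spec, base, s1par, free, data, means,
             nonident = union(s1flags, flat), n_starts, seed, deviance)
}

#' Two-stage fit of a model to time-course data
#'
#' Runs the full estimation pipeline: stage 1 (GR submodel), stage 2
#' (remaining rates with GR frozen), and by default a joint refinement — a
#' bounded multi-start Levenberg-Marquardt pass over *all* estimable rates,
#' started from the two-stage optimum and from seeded Latin-hypercube
#' points. The refinement corrects the stage-1 bias that arises when other
#' genes feed back on GR (Model 4) and escapes basins the staged
#' initialisation can fall into, while the two-stage structure still
#' provides the primary start.
#'
#' @inheritParams fit_stage1_gr
#' @param refine logical; run the joint polish (default `TRUE`).
#' @return A `gr_fit` object: `params` (all estimable rates, in bounds),
#'   `stage1_params`, `stage2_params`, `epsilon_by_observable` (named
#'   vector, `<gene>_<level>`), `total_epsilon`, `nonidentifiable`,
#'   `converged`, `n_starts`, `seed`.
#' @examples
#' \donttest{
#' m <- build_model(5)
#' d <- generate_dataset(synthetic_config(5, noise_cv = 0, seed = 7))$dataset
#' fit <- fit_model(m, d, n_starts = 4, seed = 1)
#' fit$total_epsilon
#' }
#' @export
fit_model <- function(spec, data, n_starts = 24, seed = 1, refine = TRUE) {
  spec <- as_gr_model(spec)
  data <- as_timecourse(data)
  s1 <- fit_stage1_gr(spec, data, n_starts = n_starts, seed = seed)
  fit <- fit_stage2(spec, s1, data, n_starts = n_starts, seed = seed + 1)
  if (refine) {
    means <- dataset_means(data)
    all_free <- param_names(spec)
    best <- multistart_fit(spec, all_free, fit$params, means,
                           n_starts = n_starts, seed = seed + 2)
    params <- fit$params
    params[all_free] <- best$par
    fit <- finish_fit(spec, params, s1$params,
                      setdiff(all_free, names(s1$params)), data, means,
                      nonident = fit$nonidentifiable, n_starts, seed,
                      best$deviance)
  }
  fit
}

# Project onto the baseline-feasible set: an activating edge sourced by a
# baseline-1 protein may not exceed the target's mRNA degradation rate
# (derived basal synthesis >= 0). The soft penalty lets the optimizer graze
# the boundary; the returned parameters are snapped back onto it.
project_feasible <- function(spec, params) {
  en <- edge_rate_names(spec)
  for (i in seq_len(nrow(spec$edges))) {
    if (spec$edges$sign[i] == "activation" &&
        source_baseline(spec, spec$edges$source[i]) > 0) {
      dm_t <- params[paste0("dm_", spec$edges$target[i])]
      params[en[i]] <- min(params[en[i]], dm_t)
    }
  }
  params
}

# Assemble a gr_fit: epsilons from replicate means at the data's times.
finish_fit <- function(spec, params, s1names_or_par, stage2_names, data,
                       means, nonident, n_starts, seed, deviance) {
  params <- project_feasible(spec, params)
  check_bounds(params)
  Y <- sim_at_times(spec, params, sort(unique(means$time_h)))
  tgrid <- sort(unique(means$time_h))
  obs <- dataset_observables(data)
  eps <- setNames(numeric(nrow(obs)), paste0(obs$gene, "_", obs$level))
  for (i in seq_len(nrow(obs))) {
    sel <- means$gene == obs$gene[i] & means$level == obs$level[i]
    y <- means$mean_fold[sel]
    Yv <- Y[match(means$time_h[sel], tgrid),
            paste0(obs$gene[i], "_", obs$level[i])]
    eps[i] <- residual_epsilon(y, Yv)
  }
  s1n <- if (is.character(s1names_or_par)) s1names_or_par
         else names(s1names_or_par)
  structure(list(model = spec,
                 params = params,
                 stage1_params = params[intersect(s1n, names(params))],
                 stage2_params = params[stage2_names],
                 epsilon_by_observable = eps,
                 total_epsilon = mean(eps),
                 nonidentifiable = nonident,
                 converged = TRUE,
                 deviance = deviance,
                 n_starts = n_starts,
                 seed = seed),
            class = "gr_fit")
}

#' @export
print.gr_fit <- function(x, ...) {
  cat(sprintf("Fit of model %d (%s): total epsilon = %.4g\n",
              x$model$model_id, x$model$name, x$total_epsilon))
  for (nm in names(x$epsilon_by_observable))
    cat(sprintf("  epsilon %-14s %.4g\n", nm, x$epsilon_by_observable[nm]))
  cat("  rates:", paste(sprintf("%s=%.4g", names(x$params), x$params),
                        collapse = ", "), "\n")
  if (length(x$nonidentifiable))
    cat("  non-identifiable:", paste(x$nonidentifiable, collapse = ", "),
        "\n")
  invisible(x)
}

#' Machine-readable fit report
#'
#' @param fit a `gr_fit`.
#' @param path optional file; if given, the JSON report is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
fit_report <- function(fit, path = NULL) {
  rep <- list(model_id = fit$model$model_id, model_name = fit$model$name,
              params = as.list(fit$params),
              epsilon_by_observable = as.list(fit$epsilon_by_observable),
              total_epsilon = fit$total_epsilon,
              nonidentifiable = fit$nonidentifiable,
              bounds = c(RATE_LOWER, RATE_UPPER),
              n_starts = fit$n_starts, seed = fit$seed,
              converged = fit$converged)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
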
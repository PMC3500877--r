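#' Convert a protein half-life to a first-order rate constant
#'
#' `k = ln(2) / t_half`. GR protein half-lives of 27-42 h give rate constants
#' of 0.0257-0.0165 h^-1, which motivates the estimation bounds
#' `[0.01, 1]` used throughout the package.
#'
#' @param t_half half-life in hours; must be positive.
#' @return rate constant in h^-1.
#' @examples
#' half_life_to_rate(42)   # 0.0165
#' half_life_to_rate(27)   # 0.0257
#' @export
half_life_to_rate <- function(t_half) {
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half <= 0))
    stop_validation("half-life must be a positive finite number of hours")
  log(2) / t_half
}

edge_rate_names <- function(spec) {
  if (nrow(spec$edges) == 0) return(character(0))
  paste0("a_", spec$edges$source, "_", spec$edges$target)
}

#' Estimable rate constants of a model
#'
#' Names the free kinetic parameters of a topology: per observable gene an
#' mRNA degradation rate `dm_<gene>` and a protein degradation rate
#' `dp_<gene>`, plus one rate `a_<source>_<target>` per regulatory edge
#' (including GR autoregulation `a_GR_GR`). Basal mRNA synthesis and
#' translation rates are derived from the baseline-balance constraint (see
#' [resolve_rates()]); the stimulus-activation rate `k_act` and the latent
#' intermediate's turnover rates are fixed structural constants.
#'
#' @param spec a `gr_model` or a model id.
#' @return character vector of parameter names.
#' @export
param_names <- function(spec) {
  spec <- as_gr_model(spec)
  g <- observable_genes(spec)
  c(paste0("dm_", g), paste0("dp_", g), edge_rate_names(spec))
}

#' Default rate constants
#'
#' mRNA degradation defaults to 0.2 h^-1 (half-life ~3.5 h), protein
#' degradation to 0.1 h^-1 except GR, whose slow turnover (half-life
#' 27-42 h) gives 0.02 h^-1; every edge rate defaults to 0.1 h^-1. All
#' defaults lie inside the estimation bounds `[0.01, 1]`.
#'
#' @inheritParams param_names
#' @return named numeric vector over [param_names()].
#' @export
default_params <- function(spec) {
  spec <- as_gr_model(spec)
  nm <- param_names(spec)
  p <- setNames(numeric(length(nm)), nm)
  p[startsWith(nm, "dm_")] <- 0.2
  p[startsWith(nm, "dp_")] <- 0.1
  p["dp_GR"] <- 0.02
  p[startsWith(nm, "a_")] <- 0.1
  p
}

# Fixed structural constants (not estimated).
fixed_params <- function(spec) {
  spec <- as_gr_model(spec)
  f <- c(k_act = K_ACT_DEFAULT)
  if (length(spec$latent_species))
    f <- c(f, dm_X = X_RATE, dp_X = X_RATE, tl_X = X_RATE)
  f
}

check_bounds <- function(params) {
  bad <- names(params)[params < RATE_LOWER - 1e-12 |
                       params > RATE_UPPER + 1e-12 | !is.finite(params)]
  if (length(bad))
    stop_validation("rate constants outside bounds [%g, %g]: %s",
                    RATE_LOWER, RATE_UPPER, paste(bad, collapse = ", "))
  invisible(params)
}

# Baseline protein level of an edge source: active GR and the latent X are
# absent before the stimulus; every other protein sits at fold-change 1.
source_baseline <- function(spec, source) {
  ifelse(source == "GR" | source %in% spec$latent_species, 0, 1)
}

#' Resolve free rates into the full kinetic rate set
#'
#' Completes a vector of estimable rates into the full mass-action rate set
#' under the baseline-balance convention: the pre-stimulus state (every
#' observable species at fold-change 1, active GR and latent X at 0) is an
#' exact steady state. Translation rates equal protein degradation rates and
#' basal mRNA synthesis is `s_g = dm_g - sum(a_e * source_baseline)` over
#' activating edges into the gene. Edges from a baseline-1 protein (e.g.
#' c-Jun -> Bim) therefore require `a_e < dm_target`.
#'
#' @inheritParams param_names
#' @param params named numeric vector over [param_names()]; missing entries
#'   are filled from [default_params()].
#' @param k_act optional override of the stimulus-activation constant.
#' @param clamp_basal if `TRUE`, a negative derived basal synthesis rate is
#'   clamped to 0 and returned in `$basal_deficit` instead of raising an
#'   error (used internally for penalised fitting).
#' @return list with per-gene vectors `s`, `dm`, `tl`, `dp` (including the
#'   latent intermediate), `edges` (edge table with rates), `k_act`, and
#'   `basal_deficit`.
#' @export
resolve_rates <- function(spec, params = default_params(spec), k_act = NULL,
                          clamp_basal = FALSE) {
  spec <- as_gr_model(spec)
  full <- default_params(spec)
  params <- params[names(params) %in% names(full)]
  full[names(params)] <- params
  check_bounds(full)
  fx <- fixed_params(spec)
  if (is.null(k_act)) k_act <- unname(fx["k_act"])

  genes <- spec$genes
  dm <- dp <- tl <- s <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    if (g %in% spec$latent_species) {
      dm[g] <- fx["dm_X"]; dp[g] <- fx["dp_X"]; tl[g] <- fx["tl_X"]
      s[g] <- 0
    } else {
      dm[g] <- full[paste0("dm_", g)]
      dp[g] <- full[paste0("dp_", g)]
      tl[g] <- dp[g]                       # unit baseline: translation = decay
      act <- spec$edges$sign == "activation" & spec$edges$target == g
      s[g] <- dm[g] - sum(full[edge_rate_names(spec)[act]] *
                            source_baseline(spec, spec$edges$source[act]))
    }
  }
  deficit <- pmax(-s, 0)
  if (any(deficit > 0)) {
    if (!clamp_basal)
      stop_validation(
        "activation into %s exceeds its mRNA degradation at baseline (derived basal synthesis < 0)",
        paste(names(deficit)[deficit > 0], collapse = ", "))
    s <- pmax(s, 0)
  }
  edges <- spec$edges
  edges$rate <- unname(full[edge_rate_names(spec)])
  list(s = s, dm = dm, tl = tl, dp = dp, edges = edges,
       k_act = k_act, basal_deficit = deficit, params = full)
}

#' Identifiable rate constants of each topology
#'
#' From fold-change time courses of the observable genes, not every rate is
#' structurally identifiable: rates acting only on flat trajectories carry no
#' information (GR in Models 5-6, which have nothing upstream of GR; Erg in
#' Model 3), and the two activation rates of a chain through the latent
#' intermediate X (Models 2 and 6) enter the observables only through their
#' product, because X's own turnover is fixed.
#'
#' @inheritParams param_names
#' @return list with `single` (names of individually identifiable rates) and
#'   `products` (list of name pairs identifiable as a product).
#' @export
identifiable_rates <- function(spec) {
  spec <- as_gr_model(spec)
  single <- switch(spec$model_id,
    c("dm_GR", "dp_GR", "a_GR_GR", "dm_cJun", "dp_cJun", "a_GR_cJun",
      "dm_Bim", "dp_Bim", "a_cJun_Bim"),
    c("dm_GR", "dp_GR", "a_GR_GR", "dm_cJun", "dp_cJun",
      "dm_Bim", "dp_Bim", "a_cJun_Bim"),
    c("dm_GR", "dp_GR", "a_GR_GR"),
    c("dm_GR", "dp_GR", "a_GR_GR", "dm_Erg", "dp_Erg",
      "a_Erg_GR", "a_GR_Erg"),
    c("dm_Erg", "dp_Erg", "a_GR_Erg"),
    c("dm_Erg", "dp_Erg"))
  products <- switch(spec$model_id,
    NULL,
    list(c("a_GR_X", "a_X_cJun")),
    NULL, NULL, NULL,
    list(c("a_GR_X", "a_X_Erg")))
  list(single = single, products = products %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw random interior rate constants
#'
#' Samples estimable rates log-uniformly from the interior `[0.05, 0.8]` of
#' the estimation bounds, respecting baseline feasibility: the rate of an
#' activating edge sourced by a baseline-1 protein is drawn as a fraction
#' (0.1-0.9) of the target's mRNA degradation rate so the derived basal
#' synthesis stays positive. Rates not in `which` keep their defaults, which
#' is how non-identifiable rates are pinned in recovery experiments.
#'
#' @inheritParams param_names
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param which names of rates to randomize; default all estimable rates.
#' @return named numeric vector over [param_names()].
#' @export
random_params <- function(spec, seed, which = NULL) {
  spec <- as_gr_model(spec)
  p <- default_params(spec)
  which <- which %||% names(p)
  with_seed(seed, {
    draw <- function(n) exp(runif(n, log(0.05), log(0.8)))
    p[which] <- draw(length(which))
    # re-draw constrained edges as a fraction of the target's dm
    en <- edge_rate_names(spec)
    for (i in seq_len(nrow(spec$edges))) {
      if (!(en[i] %in% which)) next
      if (spec$edges$sign[i] == "activation" &&
          source_baseline(spec, spec$edges$source[i]) > 0) {
        dm_t <- p[paste0("dm_", spec$edges$target[i])]
        p[en[i]] <- max(RATE_LOWER, runif(1, 0.1, 0.9) * dm_t)
      }
    }
    p
  })
}
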
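# State layout: for each gene g (model order, latent included):
#   <g>_mrna, <g>_protein; followed by "GRa" (active, hormone-bound GR).
state_names <- function(spec) {
  c(as.vector(rbind(paste0(spec$genes, "_mrna"),
                    paste0(spec$genes, "_protein"))), "GRa")
}

# Pre-stimulus steady state: observables at fold-change 1, latent X and
# active GR absent.
initial_state <- function(spec) {
  y <- setNames(rep(1, 2 * length(spec$genes) + 1), state_names(spec))
  y["GRa"] <- 0
  for (g in spec$latent_species) {
    y[paste0(g, "_mrna")] <- 0
    y[paste0(g, "_protein")] <- 0
  }
  y
}

#' Mass-action ODE right-hand side of a model
#'
#' First-order mass-action transcription/translation/degradation scheme. For
#' each gene `g`:
#' \deqn{d m_g/dt = s_g + \sum_{act} a_e P_{src} - dm_g m_g -
#'       \sum_{rep} a_e P_{src} m_g}
#' \deqn{d p_g/dt = tl_g m_g - dp_g p_g}
#' Edges sourced by GR act through the active pool `GRa`, produced by a
#' first-order conversion of inactive GR protein under the stimulus:
#' \deqn{d GRa/dt = k_{act} D\, p_{GR} - dp_{GR}\, GRa,}
#' with the matching removal term `-k_act D p_GR` in the inactive GR protein
#' equation (the conversion conserves total GR). `D` is the dexamethasone
#' step stimulus (0 or 1).
#'
#' @inheritParams resolve_rates
#' @param state named state vector as produced by the simulator; must be
#'   non-negative.
#' @param t time in hours (unused: the system is autonomous given `D`).
#' @param D stimulus indicator, 0 or 1.
#' @return named vector of time derivatives.
#' @examples
#' m <- build_model(1)
#' odes(m, default_params(m), D = 0)  # balanced baseline: all zero
#' @export
odes <- function(spec, params = default_params(spec), state = NULL, t = 0,
                 D = 1, clamp_basal = FALSE) {
  spec <- as_gr_model(spec)
  if (is.null(state)) state <- initial_state(spec)
  if (any(state < 0))
    stop_numerical("negative state component(s): %s",
                   paste(names(state)[state < 0], collapse = ", "))
  rhs <- make_rhs(spec, resolve_rates(spec, params,
                                      clamp_basal = clamp_basal), D = D)
  setNames(rhs(t, unname(state)[match(state_names(spec), names(state))],
               NULL)[[1]], state_names(spec))
}

# Compile the RHS into an index-based closure for deSolve.
make_rhs <- function(spec, rates, D) {
  sn <- state_names(spec)
  genes <- spec$genes
  im <- match(paste0(genes, "_mrna"), sn)
  ip <- match(paste0(genes, "_protein"), sn)
  ia <- match("GRa", sn)
  igr <- match("GR", genes)
  # per-edge source state index: GR-sourced edges read the active pool
  src_idx <- ifelse(rates$edges$source == "GR", ia,
                    ip[match(rates$edges$source, genes)])
  tgt_idx <- match(rates$edges$target, genes)
  act <- rates$edges$sign == "activation"
  erate <- rates$edges$rate
  s <- unname(rates$s); dm <- unname(rates$dm)
  tl <- unname(rates$tl); dp <- unname(rates$dp)
  kact <- rates$k_act * D

  function(t, y, parms) {
    dm_dt <- s - dm * y[im]
    if (length(erate)) {
      drive <- erate * y[src_idx]
      for (j in seq_along(erate)) {
        k <- tgt_idx[j]
        dm_dt[k] <- dm_dt[k] +
          if (act[j]) drive[j] else -drive[j] * y[im[k]]
      }
    }
    dp_dt <- tl * y[im] - dp * y[ip]
    conv <- kact * y[ip[igr]]
    dp_dt[igr] <- dp_dt[igr] - conv
    da <- conv - dp[igr] * y[ia]
    dy <- numeric(length(y))
    dy[im] <- dm_dt
    dy[ip] <- dp_dt
    dy[ia] <- da
    list(dy)
  }
}

# Precompiled per-topology machinery for repeated simulation inside the
# optimizer: all index arithmetic and name handling done once, evaluation
# afterwards purely numeric.
compile_engine <- function(spec) {
  sn <- state_names(spec)
  genes <- spec$genes
  im <- match(paste0(genes, "_mrna"), sn)
  ip <- match(paste0(genes, "_protein"), sn)
  ia <- match("GRa", sn)
  igr <- match("GR", genes)
  latent <- genes %in% spec$latent_species

  tmpl <- default_params(spec)
  dm_pos <- match(paste0("dm_", genes), names(tmpl))   # NA for latent
  dp_pos <- match(paste0("dp_", genes), names(tmpl))
  e_pos <- match(edge_rate_names(spec), names(tmpl))
  e_src <- ifelse(spec$edges$source == "GR", ia,
                  ip[match(spec$edges$source, genes)])
  e_tgt <- match(spec$edges$target, genes)
  e_act <- spec$edges$sign == "activation"
  e_src0 <- source_baseline(spec, spec$edges$source)
  k_act <- unname(fixed_params(spec)["k_act"])
  y0 <- unname(initial_state(spec))

  # full named parameter vector -> numeric rate blocks and baseline deficit
  resolve_num <- function(full, clamp = FALSE) {
    dm <- unname(ifelse(latent, X_RATE, full[dm_pos]))
    dp <- unname(ifelse(latent, X_RATE, full[dp_pos]))
    er <- if (length(e_pos)) unname(full[e_pos]) else numeric(0)
    s <- ifelse(latent, 0, dm)
    for (j in seq_along(er))
      if (e_act[j] && e_src0[j] > 0)
        s[e_tgt[j]] <- s[e_tgt[j]] - er[j] * e_src0[j]
    deficit <- pmax(-s, 0)
    if (any(deficit > 0)) {
      if (!clamp)
        stop_validation(
          "activation into %s exceeds its mRNA degradation at baseline (derived basal synthesis < 0)",
          paste(genes[deficit > 0], collapse = ", "))
      s <- pmax(s, 0)
    }
    list(s = s, dm = dm, tl = dp, dp = dp, er = er, k_act = k_act,
         deficit = deficit)
  }

  ng <- length(genes)
  ne <- nrow(spec$edges)
  pad <- 128  # must match GRKIN_PARMS_LEN in src/grkin_rhs.c
  edge_quads <- as.vector(rbind(e_src, e_tgt, as.numeric(e_act),
                                numeric(ne)))

  solve_states <- function(full, times, D, clamp = FALSE,
                           rtol = 1e-8, atol = 1e-10, k_act = NULL) {
    pr <- resolve_num(full, clamp = clamp)
    pr$kD <- (k_act %||% pr$k_act) * D
    pk <- numeric(pad)
    quads <- edge_quads
    if (ne) quads[seq(4, 4 * ne, by = 4)] <- pr$er
    pk[seq_len(4 + 4 * ng + 4 * ne)] <-
      c(ng, ne, igr, pr$kD, pr$s, pr$dm, pr$tl, pr$dp, quads)
    out <- try(suppressWarnings(
      deSolve::lsoda(y0, times, func = "grkin_rhs", parms = pk,
                     dllname = "grkin", initfunc = "grkin_init",
                     rtol = rtol, atol = atol)), silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < length(times) ||
        any(!is.finite(out[, -1])))
      stop_numerical(
        "integration failed for model %d (%s); params: %s",
        spec$model_id, spec$name,
        paste(sprintf("%s=%.4g", names(full), full), collapse = ", "))
    states <- out[, -1, drop = FALSE]
    if (any(states < -1e-8))
      stop_numerical("negative trajectory values in model %d", spec$model_id)
    states[states < 0] <- 0
    attr(states, "deficit") <- pr$deficit
    states
  }

  obs <- observables(spec)
  obs_col <- ifelse(obs$level == "protein",
                    ip[match(obs$gene, genes)], im[match(obs$gene, genes)])
  gr_prot <- which(obs$gene == "GR" & obs$level == "protein")

  observe <- function(states) {
    traj <- states[, obs_col, drop = FALSE]
    if (length(gr_prot))
      traj[, gr_prot] <- traj[, gr_prot] + states[, ia]
    traj <- sweep(traj, 2, traj[1, ], "/")
    colnames(traj) <- paste0(obs$gene, "_", obs$level)
    traj
  }

  list(spec = spec, state_names = sn, y0 = y0,
       resolve_num = resolve_num, solve_states = solve_states,
       observe = observe, obs = obs)
}
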
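# Independent oracles used across the test files.

# Brute-force normalized residual, coded as a plain loop over the formula
# eps = (1/n) * sum(((y_i - Y_i)/Y_i)^2); kept deliberately independent of
# residual_epsilon().
eps_brute <- function(y, Y) {
  stopifnot(length(y) == length(Y))
  total <- 0
  for (i in seq_along(y)) total <- total + ((y[i] - Y[i]) / Y[i])^2
  total / length(y)
}

# Matrix-exponential solution of a repression-free (hence linear) topology:
# y' = A y + b solved exactly through the augmented matrix exponential.
# The matrix is assembled here from the model description, independently of
# the package's integrator.
oracle_linear_traj <- function(spec, params, times, stimulus_on = TRUE) {
  rates <- resolve_rates(spec, params)
  stopifnot(all(rates$edges$sign == "activation"))
  sn <- grkin:::state_names(spec)
  n <- length(sn)
  A <- matrix(0, n, n, dimnames = list(sn, sn))
  b <- setNames(numeric(n), sn)
  for (g in spec$genes) {
    m <- paste0(g, "_mrna"); p <- paste0(g, "_protein")
    A[m, m] <- A[m, m] - rates$dm[[g]]
    A[p, m] <- A[p, m] + rates$tl[[g]]
    A[p, p] <- A[p, p] - rates$dp[[g]]
    b[m] <- rates$s[[g]]
  }
  for (i in seq_len(nrow(rates$edges))) {
    src <- rates$edges$source[i]
    src_state <- if (src == "GR") "GRa" else paste0(src, "_protein")
    tgt_m <- paste0(rates$edges$target[i], "_mrna")
    A[tgt_m, src_state] <- A[tgt_m, src_state] + rates$edges$rate[i]
  }
  kD <- rates$k_act * as.numeric(stimulus_on)
  A["GR_protein", "GR_protein"] <- A["GR_protein", "GR_protein"] - kD
  A["GRa", "GR_protein"] <- A["GRa", "GR_protein"] + kD
  A["GRa", "GRa"] <- -rates$dp[["GR"]]

  y0 <- grkin:::initial_state(spec)
  aug <- rbind(cbind(A, b), 0)
  states <- t(vapply(times, function(t) {
    if (t == 0) return(unname(y0))
    v <- as.numeric(Matrix::expm(aug * t) %*% c(unname(y0), 1))
    v[seq_len(n)]
  }, numeric(n)))
  colnames(states) <- sn

  obs <- grkin:::observables(spec)
  traj <- matrix(0, length(times), nrow(obs),
                 dimnames = list(NULL, paste0(obs$gene, "_", obs$level)))
  for (i in seq_len(nrow(obs))) {
    v <- if (obs$gene[i] == "GR" && obs$level[i] == "protein")
      states[, "GR_protein"] + states[, "GRa"]
    else states[, paste0(obs$gene[i], "_", obs$level[i])]
    traj[, i] <- v / v[1]
  }
  traj
}

# Random interior truth for a model, restricted to its identifiable rates.
draw_truth <- function(spec, seed) {
  idf <- identifiable_rates(spec)
  random_params(spec, seed = seed,
                which = unique(c(idf$single, unlist(idf$products))))
}

# Worst relative error of a fit against its generating truth, over the
# identifiable single rates and rate products.
recovery_error <- function(fit, truth, spec) {
  idf <- identifiable_rates(spec)
  errs <- abs(fit$params[idf$single] - truth[idf$single]) / truth[idf$single]
  perr <- vapply(idf$products, function(pp)
    abs(prod(fit$params[pp]) - prod(truth[pp])) / prod(truth[pp]),
    numeric(1))
  max(c(errs, perr))
}
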
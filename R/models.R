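#' The six GR signalling network topologies
#'
#' Builds one of the six competing mass-action network models of
#' glucocorticoid receptor (GR) signalling. Models 1-4 describe the
#' GC-sensitive CEM-C7-14 line and carry positive GR autoregulation; Models
#' 5-6 describe the GC-resistant CEM-C1-15 line without autoregulation.
#'
#' * **Model 1** (`c7_jun_direct`): GR directly activates c-Jun, c-Jun
#'   activates Bim.
#' * **Model 2** (`c7_jun_indirect`): GR induces a latent de novo protein X
#'   which activates c-Jun; c-Jun activates Bim.
#' * **Model 3** (`c7_erg_auto`): GR autoregulation only; Erg is carried as a
#'   basally expressed species with no incoming edge.
#' * **Model 4** (`c7_erg_crosstalk`): GR autoregulation plus Erg/GR
#'   crosstalk. By default Erg protein activates GR transcription and active
#'   GR represses Erg transcription; both signs are configurable.
#' * **Model 5** (`c1_erg_direct`): GR directly activates Erg; no
#'   autoregulation.
#' * **Model 6** (`c1_erg_indirect`): GR induces latent protein X which
#'   activates Erg; no autoregulation.
#'
#' Every edge acts through the source's protein; edges whose source is GR act
#' through the active (hormone-bound) GR pool, which is zero before the
#' stimulus. Repression is mass-action removal of the target's mRNA
#' (rate `a * [repressor protein] * [target mRNA]`).
#'
#' @param model_id integer 1-6, or one of the catalogue names listed above.
#' @param erg_gr_sign sign of the Erg -> GR edge in Model 4
#'   (`"activation"` or `"repression"`).
#' @param gr_erg_sign sign of the GR -> Erg edge in Model 4.
#' @return A `gr_model` object: list with `model_id`, `name`, `cell_line`,
#'   `genes`, `edges` (data frame `source`, `target`, `sign`),
#'   `gr_autoregulation`, `latent_species`.
#' @examples
#' m <- build_model(1)
#' m$edges
#' build_model("c1_erg_indirect")$latent_species
#' @export
build_model <- function(model_id,
                        erg_gr_sign = "activation",
                        gr_erg_sign = "repression") {
  if (is.character(model_id)) {
    if (length(model_id) == 1 && grepl("^[0-9]+$", model_id)) {
      model_id <- as.integer(model_id)
    } else {
      idx <- match(model_id, MODEL_NAMES)
      if (is.na(idx))
        stop_validation("unknown model '%s' (names: %s)", model_id,
                        paste(MODEL_NAMES, collapse = ", "))
      model_id <- idx
    }
  }
  if (length(model_id) != 1 || is.na(model_id) ||
      model_id != as.integer(model_id) || !(model_id %in% 1:6))
    stop_validation("unknown model id '%s': must be an integer in 1..6",
                    paste(model_id, collapse = ","))
  model_id <- as.integer(model_id)
  erg_gr_sign <- match.arg(erg_gr_sign, c("activation", "repression"))
  gr_erg_sign <- match.arg(gr_erg_sign, c("activation", "repression"))

  edge <- function(source, target, sign = "activation")
    data.frame(source = source, target = target, sign = sign,
               stringsAsFactors = FALSE)
  auto <- edge("GR", "GR")

  spec <- switch(model_id,
    list(genes = c("GR", "cJun", "Bim"),
         edges = rbind(auto, edge("GR", "cJun"), edge("cJun", "Bim")),
         latent = character(0), autoreg = TRUE, cell = "C7_sensitive"),
    list(genes = c("GR", "X", "cJun", "Bim"),
         edges = rbind(auto, edge("GR", "X"), edge("X", "cJun"),
                       edge("cJun", "Bim")),
         latent = "X", autoreg = TRUE, cell = "C7_sensitive"),
    list(genes = c("GR", "Erg"),
         edges = auto,
         latent = character(0), autoreg = TRUE, cell = "C7_sensitive"),
    list(genes = c("GR", "Erg"),
         edges = rbind(auto, edge("Erg", "GR", erg_gr_sign),
                       edge("GR", "Erg", gr_erg_sign)),
         latent = character(0), autoreg = TRUE, cell = "C7_sensitive"),
    list(genes = c("GR", "Erg"),
         edges = edge("GR", "Erg"),
         latent = character(0), autoreg = FALSE, cell = "C1_resistant"),
    list(genes = c("GR", "X", "Erg"),
         edges = rbind(edge("GR", "X"), edge("X", "Erg")),
         latent = "X", autoreg = FALSE, cell = "C1_resistant"))

  structure(list(model_id = model_id,
                 name = MODEL_NAMES[model_id],
                 cell_line = spec$cell,
                 genes = spec$genes,
                 edges = spec$edges,
                 gr_autoregulation = spec$autoreg,
                 latent_species = spec$latent),
            class = "gr_model")
}

#' @rdname build_model
#' @format `MODEL_NAMES` is the character vector of the six catalogue names,
#'   in model-id order.
#' @export
MODEL_NAMES <- c("c7_jun_direct", "c7_jun_indirect", "c7_erg_auto",
                 "c7_erg_crosstalk", "c1_erg_direct", "c1_erg_indirect")

#' @export
print.gr_model <- function(x, ...) {
  cat(sprintf("Model %d (%s), cell line %s\n", x$model_id, x$name,
              x$cell_line))
  cat(sprintf("  genes: %s%s\n", paste(x$genes, collapse = ", "),
              if (length(x$latent_species))
                sprintf("  (latent: %s)",
                        paste(x$latent_species, collapse = ", ")) else ""))
  cat(sprintf("  GR autoregulation: %s\n", x$gr_autoregulation))
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %s %s %s\n", x$edges$source[i],
                if (x$edges$sign[i] == "activation") "->" else "-|",
                x$edges$target[i]))
  invisible(x)
}

# Genes whose mRNA and protein are experimentally observable.
observable_genes <- function(spec) setdiff(spec$genes, spec$latent_species)

# Observable (gene, level) pairs in canonical order.
observables <- function(spec) {
  g <- observable_genes(spec)
  data.frame(gene = rep(g, each = 2),
             level = rep(c("mrna", "protein"), length(g)),
             stringsAsFactors = FALSE)
}

is_gr_model <- function(x) inherits(x, "gr_model")

as_gr_model <- function(x, ...) {
  if (is_gr_model(x)) x else build_model(x, ...)
}

# GR-only submodel used for stage-1 estimation: GR plus its autoregulation
# loop if present, with any input from other genes dropped.
gr_submodel <- function(spec) {
  sub <- build_model(if (spec$gr_autoregulation) 3L else 5L)
  sub$genes <- "GR"
  sub$edges <- sub$edges[sub$edges$source == "GR" & sub$edges$target == "GR", ,
                         drop = FALSE]
  sub$model_id <- spec$model_id
  sub$name <- paste0(spec$name, "_gr_submodel")
  sub$cell_line <- spec$cell_line
  sub
}
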
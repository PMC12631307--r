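#' Endpoint names in the fixed released-model column order
#'
#' The four assay endpoints handled by the package, in the column order used
#' for every wide table and every prediction matrix: Caco-2 efflux ratio,
#' Caco-2 apparent permeability, MDCK-MDR1 efflux ratio and NIH MDCK-MDR1
#' efflux ratio. Permeability values are expressed in 1e-6 cm/s before
#' log-transformation; efflux ratios are dimensionless.
#'
#' @return Character vector of the four endpoint names.
#' @export
endpoint_names <- function() {
  c("Caco2ER", "Caco2Papp", "MDCKER", "NIHMDCKER")
}

#' Modality labels recognised by the package
#' @return Character vector of modality labels.
#' @export
modality_names <- function() {
  c("small_molecule", "macrocycle", "peptide", "PROTAC", "unknown")
}

.qualifier_levels <- c("none", "lower_bound", "upper_bound")

# run expr with a private RNG stream; NULL seed = use current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
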
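#' Nearest-neighbor RNA energy model
#'
#' Returns the package's folding energy model: a 6 x 6 stacking table over
#' the pair alphabet CG/GC/GU/UG/AU/UA (kcal/mol, negative = stabilising)
#' plus linear loop penalties (hairpin, bulge, internal, multiloop) and the
#' compensatory-column bonus used by the consensus fold. The constants ship
#' as plain-text files under `inst/extdata` and are cached after first load.
#'
#' The model is deliberately simple: no dangling ends, no coaxial stacking,
#' no tetraloop bonuses, hairpin loops of at least 3 nt. It is the single
#' energy definition used by MFE folding, terminator hairpin scoring and
#' duplex hybridization, so all stages share one thermodynamic currency.
#'
#' @return list with elements `stack` (6 x 6 matrix, dimnames are pair
#'   names), `params` (named numeric vector of loop constants) and
#'   `pair_names`.
#' @export
energy_model <- function() {
  if (!is.null(.pkg_env$energy_model)) return(.pkg_env$energy_model)
  sf <- system.file("extdata", "stack_energies.tsv", package = "srnascout")
  lf <- system.file("extdata", "loop_params.tsv", package = "srnascout")
  stack <- as.matrix(utils::read.delim(sf, row.names = 1, check.names = FALSE))
  lp <- utils::read.delim(lf)
  params <- stats::setNames(lp$value, lp$name)
  model <- list(stack = stack, params = params, pair_names = rownames(stack))
  .pkg_env$energy_model <- model
  model
}

# stacking energy (kcal/mol) for outer pair type p1 over inner pair type p2
stack_energy <- function(p1, p2, model = energy_model()) {
  model$stack[cbind(p1, p2)]
}

hairpin_penalty <- function(loop_len, model = energy_model()) {
  unname(model$params["hairpin_a"] + model$params["hairpin_c"] * (loop_len - 3))
}
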
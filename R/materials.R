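## Material cards ------------------------------------------------------------

#' Isotropic linear-elastic material card
#'
#' @param density mass density in kg/m^3 (> 0).
#' @param young_modulus Young's modulus in Pa (> 0).
#' @param poisson_ratio Poisson's ratio, in [0, 0.5).
#' @return an object of class `material_card`.
#' @export
material_card <- function(density, young_modulus, poisson_ratio) {
  if (!is.numeric(density) || density <= 0) stop2("density must be > 0")
  if (!is.numeric(young_modulus) || young_modulus <= 0)
    stop2("young_modulus must be > 0")
  if (!is.numeric(poisson_ratio) || poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop2("poisson_ratio must lie in [0, 0.5)")
  structure(list(density = density, young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio),
            class = "material_card")
}

#' @exportS3Method base::print
print.material_card <- function(x, ...) {
  cat(sprintf("material_card: rho = %g kg/m^3, E = %g Pa, nu = %g\n",
              x$density, x$young_modulus, x$poisson_ratio))
  invisible(x)
}

# Lame parameters
lame_lambda <- function(card)
  card$young_modulus * card$poisson_ratio /
    ((1 + card$poisson_ratio) * (1 - 2 * card$poisson_ratio))
lame_mu <- function(card) card$young_modulus / (2 * (1 + card$poisson_ratio))

#' Literature material grid for ear-bone models
#'
#' The values reported for dense (periotic/tympanic/ossicle) bone, the
#' flexible pedicle bone, and the two ligament classes: stiff bone density
#' 2300/2400/2500 kg/m^3 and E 10/15/20/25 GPa; flexible bone density
#' 2000 kg/m^3 and E 5/7/9 GPa; ligaments density 1200 kg/m^3, E 1 MPa, with
#' Poisson 0.3 everywhere except 0.45 for the flexible (annular) ligament.
#'
#' @return named list (one entry per region) of lists of [material_card()]s,
#'   suitable for [sweep_materials()].
#' @export
tpc_material_grid <- function() {
  list(
    stiff_bone = unlist(lapply(c(2300, 2400, 2500), function(rho)
      lapply(c(10e9, 15e9, 20e9, 25e9), function(E)
        material_card(rho, E, 0.3))), recursive = FALSE),
    flexible_bone = lapply(c(5e9, 7e9, 9e9), function(E)
      material_card(2000, E, 0.3)),
    stiff_ligament = list(material_card(1200, 1e6, 0.3)),
    flexible_ligament = list(material_card(1200, 1e6, 0.45))
  )
}

#' Reference material set (one card per region)
#'
#' The corner of the literature grid that best matched measured mode shapes:
#' stiff bone rho = 2400 kg/m^3, E = 25 GPa; flexible bone rho = 2000 kg/m^3,
#' E = 5 GPa; ligaments as in [tpc_material_grid()].
#'
#' @return named list of [material_card()]s keyed by region.
#' @export
tpc_reference_materials <- function() {
  list(stiff_bone = material_card(2400, 25e9, 0.3),
       flexible_bone = material_card(2000, 5e9, 0.3),
       stiff_ligament = material_card(1200, 1e6, 0.3),
       flexible_ligament = material_card(1200, 1e6, 0.45))
}

# validate a region -> card mapping against a mesh
check_materials <- function(mesh, materials) {
  regions <- unique(mesh$region)
  missing <- setdiff(regions, names(materials))
  if (length(missing))
    stop2("missing material card(s) for region(s): %s",
          paste(missing, collapse = ", "))
  for (r in regions)
    if (!inherits(materials[[r]], "material_card"))
      stop2("materials[['%s']] is not a material_card", r)
  invisible(TRUE)
}

#' Factorial material sweep
#'
#' Expands per-region card lists into the full factorial list of material
#' assignments, each a named list of one card per region.
#'
#' @param cards named list: region -> list of [material_card()]s.
#' @param max_combinations guard against accidental explosion (default 200).
#' @return list of named card lists, one per combination.
#' @export
expand_material_sweep <- function(cards, max_combinations = 200L) {
  if (!length(cards)) stop2("empty material sweep")
  counts <- vapply(cards, length, integer(1))
  if (any(counts == 0L))
    stop2("region(s) with no cards: %s",
          paste(names(cards)[counts == 0], collapse = ", "))
  ncomb <- prod(counts)
  if (ncomb > max_combinations)
    stop2("sweep has %d combinations, above the limit of %d",
          ncomb, max_combinations)
  grid <- expand.grid(lapply(counts, seq_len), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    stats::setNames(
      lapply(names(cards), function(r) cards[[r]][[grid[i, r]]]),
      names(cards))
  })
}
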
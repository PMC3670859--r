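# Hemispheric chamber: volume <-> radius <-> half-sarcomere length, and
# Laplace's law converting wall force per area into cavity pressure.

#' Radius of a hemispheric chamber from its volume
#'
#' Inverts `V = (2/3) pi R^3`.
#'
#' @param V Chamber volume (ml), > 0. Vectorised.
#' @return Radius (cm).
#' @seealso [volume_from_radius()]
#' @export
radius_from_volume <- function(V) {
  if (any(V <= 0)) stop("chamber volume must be positive", call. = FALSE)
  (3 * V / (2 * pi))^(1 / 3)
}

#' Volume of a hemispheric chamber from its radius
#'
#' @param R Radius (cm), > 0. Vectorised.
#' @return Volume (ml).
#' @export
volume_from_radius <- function(R) {
  if (any(R <= 0)) stop("radius must be positive", call. = FALSE)
  (2 / 3) * pi * R^3
}

#' Half-sarcomere length from chamber radius
#'
#' Radial deformation of the chamber equals deformation of the sarcomere:
#' `(R - R0)/R0 = (L - L0)/L0`, i.e. `L = L0 R / R0`. Only relative
#' deformations enter, so the um (sarcomere) and cm (chamber) scales need no
#' absolute conversion.
#'
#' @param R Chamber radius (cm), > 0.
#' @param R0 Unstressed chamber radius (cm), > 0.
#' @param L0 Unstressed half-sarcomere length (um), > 0.
#' @return Half-sarcomere length (um).
#' @export
sarcomere_length_from_radius <- function(R, R0, L0) {
  if (any(R <= 0) || R0 <= 0 || L0 <= 0) {
    stop("radii and lengths must be positive", call. = FALSE)
  }
  L0 * R / R0
}

#' Chamber pressure from wall force per area (Laplace's law)
#'
#' Thin-walled hemispheric shell: `P = 2 F t_wall / R`, with `F` in mN/mm^2
#' (= kPa) and `t_wall`, `R` in cm (only their ratio enters). The result is
#' converted to mmHg.
#'
#' @param F Wall force per unit area (mN/mm^2). May be negative (passive
#'   compression below the unstressed length).
#' @param R Chamber radius (cm), > 0.
#' @param t_wall Effective wall thickness (cm), > 0.
#' @return Cavity pressure (mmHg).
#' @export
pressure_from_force <- function(F, R, t_wall) {
  if (any(R <= 0) || t_wall <= 0) {
    stop("radius and wall thickness must be positive", call. = FALSE)
  }
  2 * F * t_wall / R / KPA_PER_MMHG
}
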
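# Microdosimetry: dose <-> fluence <-> per-nucleus traversal statistics.

# 1 Gy deposits 6.242 keV per um^3 in unit-density matter.
GY_TO_KEV_PER_UM3 <- 6.242
JOULE_PER_KEV <- 1.602e-16

#' Describe an ion beam
#'
#' @param species Ion species, `"Fe"` or `"C"`.
#' @param energy_per_nucleon Kinetic energy per nucleon at the cell contact
#'   point, MeV/n.
#' @param let Linear energy transfer in water, keV/um.
#' @param orientation Irradiation geometry: `"horizontal"` (beam roughly
#'   parallel to the slide, ~5 degree tilt ignored) or `"vertical"`.
#' @param purity Fraction of the fluence carried by the nominal species;
#'   carried as metadata only, contaminant fragments are not simulated.
#' @return An object of class `ion_beam`.
#' @examples
#' ion_beam("Fe", 416, 200)
#' @export
ion_beam <- function(species = c("Fe", "C"), energy_per_nucleon = 416,
                     let = 200, orientation = c("horizontal", "vertical"),
                     purity = 0.9) {
  species <- match.arg(species)
  orientation <- match.arg(orientation)
  if (!is.numeric(let) || length(let) != 1L || !is.finite(let) || let <= 0)
    stop("`let` must be a single positive number (keV/um)", call. = FALSE)
  if (!is.numeric(energy_per_nucleon) || energy_per_nucleon <= 0)
    stop("`energy_per_nucleon` must be positive (MeV/n)", call. = FALSE)
  if (!is.numeric(purity) || purity <= 0 || purity > 1)
    stop("`purity` must be in (0, 1]", call. = FALSE)
  structure(
    list(species = species, energy_per_nucleon = energy_per_nucleon,
         let = let, orientation = orientation, purity = purity),
    class = "ion_beam")
}

#' @export
print.ion_beam <- function(x, ...) {
  cat(sprintf("<ion_beam> %s %g MeV/n, LET %g keV/um, %s, purity %.2f\n",
              x$species, x$energy_per_nucleon, x$let, x$orientation, x$purity))
  invisible(x)
}

#' Ellipsoidal cell-nucleus geometry
#'
#' The nucleus is modelled as an oblate ellipsoid of the given diameter
#' (equatorial) and depth (polar axis), at unit density.
#'
#' @param diameter_um Nuclear diameter, um.
#' @param depth_um Nuclear depth, um; must be smaller than the diameter.
#' @return An object of class `nucleus_geometry` with derived `volume_um3`
#'   and `mass_kg`.
#' @examples
#' nucleus_geometry(12.67, 2.8)
#' @export
nucleus_geometry <- function(diameter_um = 12.67, depth_um = 2.8) {
  if (!is.numeric(diameter_um) || !is.numeric(depth_um) ||
      depth_um <= 0 || diameter_um <= depth_um)
    stop("need diameter_um > depth_um > 0", call. = FALSE)
  volume <- (4 / 3) * pi * (diameter_um / 2)^2 * (depth_um / 2)
  structure(
    list(diameter_um = diameter_um, depth_um = depth_um,
         volume_um3 = volume,
         mass_kg = volume * 1e-18 * 1e3),  # um^3 -> m^3, unit density water
    class = "nucleus_geometry")
}

#' @export
print.nucleus_geometry <- function(x, ...) {
  cat(sprintf("<nucleus_geometry> %g x %g um ellipsoid, V = %.1f um^3\n",
              x$diameter_um, x$depth_um, x$volume_um3))
  invisible(x)
}

#' Presented area of the nucleus for a beam orientation
#'
#' Horizontal (edge-on) irradiation uses the rectangular silhouette
#' diameter x depth; vertical irradiation the equatorial disc pi r^2.
#'
#' @param nucleus A [nucleus_geometry()].
#' @param orientation `"horizontal"` or `"vertical"`.
#' @return Area in um^2.
#' @export
presented_area <- function(nucleus, orientation = c("horizontal", "vertical")) {
  stopifnot(inherits(nucleus, "nucleus_geometry"))
  orientation <- match.arg(orientation)
  if (orientation == "horizontal")
    nucleus$diameter_um * nucleus$depth_um
  else
    pi * (nucleus$diameter_um / 2)^2
}

#' Particle fluence delivering a given dose
#'
#' Unit-density conversion: `fluence = dose * 6.242 / LET` particles/um^2.
#'
#' @param dose_gy Absorbed dose, Gy (>= 0).
#' @param let LET, keV/um (> 0).
#' @return Fluence in particles/um^2; exactly linear in dose.
#' @examples
#' fluence_from_dose(1, 200)   # ~0.0312 Fe ions/um^2
#' @export
fluence_from_dose <- function(dose_gy, let) {
  if (any(!is.finite(let)) || any(let <= 0))
    stop("`let` must be positive", call. = FALSE)
  if (any(!is.finite(dose_gy)) || any(dose_gy < 0))
    stop("`dose_gy` must be non-negative", call. = FALSE)
  dose_gy * GY_TO_KEV_PER_UM3 / let
}

#' Mean number of particle traversals per nucleus
#'
#' @param fluence Particles/um^2 (>= 0).
#' @param nucleus A [nucleus_geometry()].
#' @param orientation Beam orientation; see [presented_area()].
#' @return Expected traversal count (dimensionless).
#' @examples
#' nuc <- nucleus_geometry()
#' mean_traversals(fluence_from_dose(1, 200), nuc, "horizontal")  # ~1.1
#' @export
mean_traversals <- function(fluence, nucleus,
                            orientation = c("horizontal", "vertical")) {
  if (any(!is.finite(fluence)) || any(fluence < 0))
    stop("`fluence` must be non-negative", call. = FALSE)
  fluence * presented_area(nucleus, orientation)
}

#' Fraction of cells receiving at least one traversal
#'
#' Under Poisson traversal statistics, `1 - exp(-mean)`.
#'
#' @param mean Mean traversals per nucleus (>= 0).
#' @return Probability in `[0, 1)`.
#' @examples
#' traversal_fraction(1.1)  # ~0.667
#' @export
traversal_fraction <- function(mean) {
  if (any(!is.finite(mean)) || any(mean < 0))
    stop("`mean` must be non-negative", call. = FALSE)
  1 - exp(-mean)
}

#' Dose to one nucleus from a single traversal
#'
#' Energy LET x path_length deposited in the nuclear mass. Illustrates why
#' the per-cell dose in a heavy-ion exposure is quantised rather than the
#' nominal population dose.
#'
#' @param beam An [ion_beam()].
#' @param path_length_um Chord length through the nucleus, um; at most the
#'   nuclear diameter.
#' @param nucleus A [nucleus_geometry()].
#' @return Dose in Gy.
#' @examples
#' dose_per_traversal(ion_beam("Fe"), 12.67, nucleus_geometry())  # ~1.73 Gy
#' @export
dose_per_traversal <- function(beam, path_length_um, nucleus) {
  stopifnot(inherits(beam, "ion_beam"), inherits(nucleus, "nucleus_geometry"))
  if (any(path_length_um < 0) || any(path_length_um > nucleus$diameter_um))
    stop("`path_length_um` must lie in [0, diameter]", call. = FALSE)
  beam$let * path_length_um * JOULE_PER_KEV / nucleus$mass_kg
}

#' Summarise an exposure: dose, fluence and traversal statistics
#'
#' @param dose_gy Absorbed dose, Gy.
#' @param beam An [ion_beam()].
#' @param nucleus A [nucleus_geometry()].
#' @return A list of class `exposure_plan` with `fluence`, `mean_traversals`
#'   and `traversal_fraction`.
#' @export
exposure_plan <- function(dose_gy, beam, nucleus) {
  stopifnot(inherits(beam, "ion_beam"))
  fl <- fluence_from_dose(dose_gy, beam$let)
  mt <- mean_traversals(fl, nucleus, beam$orientation)
  structure(
    list(dose_gy = dose_gy, beam = beam, nucleus = nucleus,
         fluence = fl, mean_traversals = mt,
         traversal_fraction = traversal_fraction(mt)),
    class = "exposure_plan")
}

#' @export
print.exposure_plan <- function(x, ...) {
  cat(sprintf("<exposure_plan> %g Gy %s (%s)\n", x$dose_gy, x$beam$species,
              x$beam$orientation))
  cat(sprintf("  fluence            %.5f /um^2\n", x$fluence))
  cat(sprintf("  mean traversals    %.3f\n", x$mean_traversals))
  cat(sprintf("  traversal fraction %.3f\n", x$traversal_fraction))
  invisible(x)
}
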
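# Closed-form calculators for designing spherical supported lipid bilayer
# (SSLB) curvature-sensing experiments: membrane curvature presented by a
# bead of given diameter, and bead masses that equalize total membrane
# surface area across sizes.

#' Membrane curvature of a spherical bead
#'
#' Curvature is defined as the inverse radius, kappa = 1/r = 2/d, expressed
#' in µm^-1 (a 30 nm bead presents |kappa| ~ 66.7 µm^-1; a 2000 nm bead,
#' 1 µm^-1). Note that under this convention a 1000 nm bead presents
#' 2 µm^-1, not the ~0.5 µm^-1 sometimes quoted for micron-scale beads;
#' this package uses 2/d throughout.
#'
#' @param diameter_nm bead diameter in nanometres (> 0); vectorized.
#' @return curvature in µm^-1.
#' @export
sphere_curvature <- function(diameter_nm) {
  if (!is.numeric(diameter_nm) || any(diameter_nm <= 0)) {
    stop_config("diameter must be positive")
  }
  2 / (diameter_nm / 1000)
}

#' Bead specification
#'
#' @param diameter_nm bead diameter (nm, > 0).
#' @param mass_ug bead mass (µg, > 0).
#' @return a `bead_spec` list.
#' @export
bead_spec <- function(diameter_nm, mass_ug) {
  if (diameter_nm <= 0 || mass_ug <= 0) {
    stop_config("bead diameter and mass must be positive")
  }
  structure(list(diameter_nm = diameter_nm, mass_ug = mass_ug),
            class = "bead_spec")
}

#' Bead mass giving equal total surface area
#'
#' For uniform spheres of equal material density, total surface area per unit
#' mass scales as 1/diameter, so the mass of target beads with the same total
#' area as a reference preparation is
#' `ref$mass_ug * target_diameter_nm / ref$diameter_nm`. With a 2 mg /
#' 1000 nm reference this yields 200 µg at 100 nm, 100 µg at 50 nm and
#' 60 µg at 30 nm.
#'
#' @param ref a [bead_spec()] (reference diameter and mass).
#' @param target_diameter_nm target bead diameter (nm, > 0); vectorized.
#' @return mass in the same units as `ref$mass_ug`.
#' @export
equal_area_mass <- function(ref, target_diameter_nm) {
  stopifnot(inherits(ref, "bead_spec"))
  if (any(target_diameter_nm <= 0)) stop_config("target diameter must be positive")
  ref$mass_ug * target_diameter_nm / ref$diameter_nm
}

#' Per-lipid masses from a molar ratio
#'
#' Converts a molar mixing ratio and a total lipid mass into per-component
#' masses: mass_i is proportional to ratio_i * molar_mass_i, normalized to
#' the requested total.
#'
#' @param total_mass_ug total lipid mass.
#' @param molar_ratio named numeric vector of molar parts (> 0).
#' @param molar_masses named numeric vector of molar masses (g/mol), same
#'   names as `molar_ratio`.
#' @return named numeric vector of masses summing to `total_mass_ug`.
#' @export
lipid_mix_masses <- function(total_mass_ug, molar_ratio, molar_masses) {
  if (!length(molar_ratio)) stop_config("empty lipid mixture")
  if (is.null(names(molar_ratio)) ||
      !all(names(molar_ratio) %in% names(molar_masses))) {
    stop_config("molar_ratio and molar_masses must share component names")
  }
  mm <- molar_masses[names(molar_ratio)]
  if (any(molar_ratio <= 0) || any(mm <= 0)) {
    stop_config("ratios and molar masses must be positive")
  }
  w <- molar_ratio * mm
  total_mass_ug * w / sum(w)
}

#' SSLB design table
#'
#' One row per bead diameter: the mass required for equal total surface area
#' relative to the reference preparation, and the membrane curvature the bead
#' presents.
#'
#' @param diameters_nm bead diameters (nm).
#' @param ref reference [bead_spec()]; default 2 mg (2000 µg) of 1000 nm
#'   beads.
#' @return data frame with `diameter_nm`, `mass_ug`, `kappa_per_um`.
#' @examples
#' sslb_design_table()
#' @export
sslb_design_table <- function(diameters_nm = c(1000, 100, 50, 30),
                              ref = bead_spec(1000, 2000)) {
  data.frame(diameter_nm = diameters_nm,
             mass_ug = equal_area_mass(ref, diameters_nm),
             kappa_per_um = sphere_curvature(diameters_nm))
}
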
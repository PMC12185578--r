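#' Mass of test substance applied to the skin
#'
#' For an aqueous solution, micrograms applied = volume (uL) x
#' concentration (g/L), since uL * g/L = ug. For aqueous solutions,
#' ppm is equivalent to mg/L, so concentration in g/L = ppm / 1000.
#'
#' @param volume_uL applied volume, microlitres.
#' @param conc_g_per_L solution concentration, g/L.
#' @return Applied mass in micrograms.
#' @examples
#' appliedMass(20, 0.03)  # 0.6 ug
#' @export
appliedMass <- function(volume_uL, conc_g_per_L) {
    if (any(volume_uL <= 0) || any(conc_g_per_L <= 0))
        stop("volume and concentration must be positive")
    volume_uL * conc_g_per_L
}

#' Areal exposure dose over a circular insert
#'
#' Dose in g/m^2 = mass (g) / insert area (m^2) for a circular insert of
#' the given diameter. Reported at full precision; use
#' `signif(x, 2)` for the 2-significant-figure display convention.
#'
#' @param mass_ug applied mass, micrograms.
#' @param diameter_mm insert diameter, millimetres.
#' @return Areal dose in g/m^2.
#' @examples
#' arealDose(0.6, 8)            # 0.01194...
#' signif(arealDose(0.6, 8), 2) # 0.012
#' @export
arealDose <- function(mass_ug, diameter_mm) {
    if (any(mass_ug <= 0) || any(diameter_mm <= 0))
        stop("mass and diameter must be positive")
    (mass_ug * 1e-6) / (pi * (diameter_mm * 1e-3 / 2)^2)
}

#' Exposure-dose table for a set of test solutions
#'
#' Computes, for each solution, the concentration in g/L and percent,
#' the mass applied and the areal dose over the insert, from the ppm
#' concentration and the application geometry. The default rows are the
#' isothiazolinone exposures used with a 20 uL application inside an
#' 8 mm diameter insert.
#'
#' @param compound character vector of compound names.
#' @param molarMass molar masses, g/mol (carried through for reference).
#' @param ppm solution concentrations, ppm (= mg/L aqueous).
#' @param volume_uL applied volume, microlitres.
#' @param diameter_mm insert diameter, millimetres.
#' @return data.frame with full-precision and 2-significant-figure dose
#'   columns.
#' @examples
#' doseTable()
#' @export
doseTable <- function(compound = c("MCI", "MI", "MI", "BIT", "BIT",
                                   "OIT", "OIT"),
                      molarMass = c(149.60, 115.15, 115.15, 151.19,
                                    151.19, 213.34, 213.34),
                      ppm = c(30, 30, 300, 300, 500, 300, 600),
                      volume_uL = 20, diameter_mm = 8) {
    conc_g_per_L <- ppm / 1000
    mass_ug <- appliedMass(volume_uL, conc_g_per_L)
    dose <- arealDose(mass_ug, diameter_mm)
    data.frame(compound = compound, molar_mass_g_mol = molarMass,
               ppm = ppm, conc_g_per_L = conc_g_per_L,
               conc_percent = ppm / 1e4, mass_ug = mass_ug,
               dose_g_m2 = dose, dose_g_m2_2sf = signif(dose, 2))
}
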
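#' Physical constants for bulk gold
#'
#' Bulk-gold density and molar mass plus the Avogadro constant, collected in
#' one place so dosimetry never hard-codes them.
#'
#' @return Named list: `density_g_cm3` (19.3), `molar_mass_g_mol` (196.97),
#'   `avogadro` (6.02214076e23 / mol).
#' @export
gold_constants <- function() {
  list(density_g_cm3 = 19.3, molar_mass_g_mol = 196.97,
       avogadro = 6.02214076e23)
}

#' Size-dependent extinction calibration for spherical gold nanoparticles
#'
#' Log-log calibration `ln(epsilon) = a + k * ln(d)` with `d` in nm and
#' `epsilon` in 1/(M cm) at the surface plasmon resonance band. Default
#' constants are the widely used regression for citrate-capped spherical
#' AuNPs from Liu, Atwater, Wang & Huo (Colloids Surf. B 58, 2007).
#'
#' @param k Power-law exponent (slope in log-log space).
#' @param a Intercept in log space.
#' @return Named list `k`, `a`, `provenance`.
#' @export
liu_calibration <- function(k = 3.32111, a = 10.80505) {
  list(k = k, a = a,
       provenance = paste(
         "ln(eps/M^-1 cm^-1) = a + k ln(d/nm); regression for citrate-capped",
         "spherical AuNPs, Liu et al., Colloids Surf. B 58 (2007) 3-7"
       ))
}

#' Molar extinction coefficient of a spherical gold nanoparticle
#'
#' @param diameter_nm Particle diameter(s) in nm, > 0.
#' @param calibration Calibration constants, see [liu_calibration()].
#' @return Extinction coefficient(s) in 1/(M cm); strictly increasing in
#'   diameter for `k > 0`.
#' @export
#' @examples
#' extinction_coefficient(23)
extinction_coefficient <- function(diameter_nm,
                                   calibration = liu_calibration()) {
  if (any(diameter_nm <= 0)) abort("diameter must be positive")
  exp(calibration$a + calibration$k * log(diameter_nm))
}

#' Sphere-derived quantities of a gold nanoparticle
#'
#' Volume `pi d^3 / 6`, surface area `pi d^2`, gold atoms per particle from
#' bulk density, and the size-dependent extinction coefficient. Vectorized
#' over `diameter_nm`.
#'
#' @param diameter_nm Diameter(s) in nm, > 0.
#' @param label Optional label(s); defaults to `Au<d>`.
#' @param constants Gold constants, see [gold_constants()].
#' @param calibration Extinction calibration, see [liu_calibration()].
#' @return A tibble: `label`, `diameter_nm`, `volume_nm3`,
#'   `surface_area_nm2`, `atoms_per_particle`, `extinction_m1cm1`.
#' @export
#' @examples
#' sphere_quantities(c(23, 68))
sphere_quantities <- function(diameter_nm, label = NULL,
                              constants = gold_constants(),
                              calibration = liu_calibration()) {
  if (any(diameter_nm <= 0)) abort("diameter must be positive")
  volume_nm3 <- pi * diameter_nm^3 / 6
  volume_cm3 <- volume_nm3 * 1e-21
  atoms <- volume_cm3 * constants$density_g_cm3 * constants$avogadro /
    constants$molar_mass_g_mol
  tibble(
    label = label %||% paste0("Au", round(diameter_nm)),
    diameter_nm = diameter_nm,
    volume_nm3 = volume_nm3,
    surface_area_nm2 = pi * diameter_nm^2,
    atoms_per_particle = atoms,
    extinction_m1cm1 = extinction_coefficient(diameter_nm, calibration)
  )
}

#' Particle concentration from absorbance (Beer-Lambert)
#'
#' `c = A / (epsilon * l)`.
#'
#' @param absorbance Absorbance in AU (>= 0).
#' @param extinction Extinction coefficient in 1/(M cm), > 0.
#' @param pathlength_cm Optical pathlength in cm, > 0 (default 0.3 cm, a
#'   100-uL well in a 96-well plate).
#' @return Molar concentration(s).
#' @export
concentration_from_absorbance <- function(absorbance, extinction,
                                          pathlength_cm = 0.3) {
  if (any(pathlength_cm <= 0)) abort("pathlength must be positive")
  if (any(extinction <= 0)) abort("extinction must be positive")
  absorbance / (extinction * pathlength_cm)
}

#' Peptide surface density from the nanoparticle:peptide molar ratio
#'
#' The conjugation scheme is anchored at a reference molar ratio of
#' 1:100,000 peptides per particle, taken to correspond to full (1.00)
#' surface coverage at 0.3 nmol-peptide/nm^2 on the reference particle. The
#' density scale is linear in the ratio and treated as bookkeeping in the
#' reference unit.
#'
#' @param molar_ratio Peptides per particle, > 0.
#' @param reference_ratio Ratio defining coverage 1.00 (default 100,000).
#' @param reference_density Density at the reference ratio in
#'   nmol-peptide/nm^2 (default 0.3).
#' @return Density in nmol-peptide/nm^2.
#' @export
#' @examples
#' surface_density_from_ratio(75000)   # 0.225
surface_density_from_ratio <- function(molar_ratio,
                                       reference_ratio = 1e5,
                                       reference_density = 0.3) {
  if (any(molar_ratio <= 0)) abort("molar ratio must be positive")
  reference_density * molar_ratio / reference_ratio
}

#' Truncate a surface density for report parity
#'
#' Report formatter that truncates (never rounds) to `digits` decimals, so
#' 0.225 prints as "0.22" and 0.375 as "0.37".
#'
#' @param density Numeric density values.
#' @param digits Decimals kept (default 2).
#' @return Character vector.
#' @export
format_surface_density <- function(density, digits = 2L) {
  scale <- 10^digits
  formatC(floor(density * scale + 1e-9) / scale,
          format = "f", digits = digits)
}

#' Plan a peptide-nanoparticle conjugation
#'
#' Computes the peptide:particle molar ratio implied by a coverage label,
#' the peptide amount needed for a given particle solution, and the stock
#' volume to pipette. With `normalize_by_area = TRUE` (the default) the
#' per-particle ratio is scaled by the particle's surface area relative to
#' the reference particle, keeping the peptide surface density equal across
#' sizes; with `FALSE` the ratio numbers are reused per particle regardless
#' of size.
#'
#' @param np_conc_nM Particle concentration in nM, > 0.
#' @param np_vol_mL Particle solution volume in mL, > 0.
#' @param coverage Coverage label (1.00 = reference; 0.75/1.25 in the
#'   standard series), > 0.
#' @param np One-row tibble from [sphere_quantities()] for the particle.
#' @param reference_np Reference particle (default the 23-nm particle).
#' @param peptide_stock_mM Peptide stock concentration in mM, > 0.
#' @param normalize_by_area Scale the ratio by relative surface area?
#' @param reference_ratio Peptides per particle at coverage 1.00 on the
#'   reference particle (default 100,000).
#' @param reference_density Surface density at coverage 1.00 (0.3
#'   nmol-peptide/nm^2).
#' @return One-row tibble with the full audit trail: `label`, `coverage`,
#'   `area_scale`, `molar_ratio`, `surface_density_nmol_nm2`,
#'   `surface_density_printed`, `np_conc_nM`, `np_vol_mL`, `np_amount_nmol`,
#'   `peptide_amount_nmol`, `peptide_stock_mM`, `peptide_volume_uL`.
#' @export
#' @examples
#' au23 <- sphere_quantities(23)
#' conjugation_recipe(2.47, 2, 0.75, au23, peptide_stock_mM = 30,
#'                    normalize_by_area = FALSE)
conjugation_recipe <- function(np_conc_nM, np_vol_mL, coverage, np,
                               reference_np = sphere_quantities(23),
                               peptide_stock_mM,
                               normalize_by_area = TRUE,
                               reference_ratio = 1e5,
                               reference_density = 0.3) {
  if (peptide_stock_mM <= 0) abort("peptide stock must be positive")
  if (any(c(np_conc_nM, np_vol_mL, coverage) <= 0)) {
    abort("np_conc_nM, np_vol_mL and coverage must all be positive")
  }
  area_scale <- if (normalize_by_area) {
    np$surface_area_nm2 / reference_np$surface_area_nm2
  } else 1
  molar_ratio <- coverage * reference_ratio * area_scale
  ## density is defined on the reference scale, independent of particle size
  density <- surface_density_from_ratio(coverage * reference_ratio,
                                        reference_ratio, reference_density)
  np_amount_nmol <- np_conc_nM * 1e-9 * np_vol_mL * 1e-3 * 1e9   # nM * L -> nmol
  peptide_amount_nmol <- np_amount_nmol * molar_ratio
  peptide_volume_uL <- peptide_amount_nmol * 1e-9 /
    (peptide_stock_mM * 1e-3) * 1e6                              # mol / M -> L -> uL
  tibble(
    label = np$label, coverage = coverage, area_scale = area_scale,
    molar_ratio = molar_ratio,
    surface_density_nmol_nm2 = density,
    surface_density_printed = format_surface_density(density),
    np_conc_nM = np_conc_nM, np_vol_mL = np_vol_mL,
    np_amount_nmol = np_amount_nmol,
    peptide_amount_nmol = peptide_amount_nmol,
    peptide_stock_mM = peptide_stock_mM,
    peptide_volume_uL = peptide_volume_uL
  )
}
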
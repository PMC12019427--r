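# Physical constants and the internal unit system.
#
# Internally everything runs in Angstrom / kBT / Dalton; the derived time
# unit is sqrt(Da A^2 / kBT), about 63.3 fs at 300 K.  Users only ever see
# Angstrom, pN, ns and kBT.

.kB_pN_A_per_K <- 0.1380649    # Boltzmann constant, pN*A/K (1.380649e-23 J/K)
.amu_kg <- 1.66053906660e-27

#' Physical constants of the coarse-grained DNA model
#'
#' Fixed model-level constants: thermal energy at the reference temperature,
#' helical rise, bead coarse-graining level and bead mass.  One bead stands
#' for 11 base pairs (one helical turn of B-DNA), so the equilibrium bond
#' length is `11 * 3.38 = 37.18` Angstrom and the bead mass is
#' `11 * 650 = 7150` Da.
#'
#' @param temperature Temperature in Kelvin (default 300).
#' @return A list with elements `kBT_pN_A` (thermal energy, pN*Angstrom),
#'   `helical_rise_A`, `bead_bp`, `r0_A`, `bead_mass_Da`, `bp_mass_Da`,
#'   `tau_fs` (internal time unit in fs) and `temperature_K`.
#' @examples
#' physics_constants()$kBT_pN_A   # ~41.42 pN*A at 300 K
#' @export
physics_constants <- function(temperature = 300) {
  list(
    kBT_pN_A = kBT_pN_A(temperature),
    helical_rise_A = 3.38,
    bead_bp = 11L,
    r0_A = 11 * 3.38,
    bead_mass_Da = 7150,
    bp_mass_Da = 650,
    tau_fs = tau_fs(temperature),
    temperature_K = temperature
  )
}

# thermal energy in pN*Angstrom
kBT_pN_A <- function(temperature = 300) .kB_pN_A_per_K * temperature

# internal time unit in femtoseconds
tau_fs <- function(temperature = 300) {
  1e15 * sqrt(.amu_kg * 1e-20 / (1.380649e-23 * temperature))
}

.r0_default <- 11 * 3.38       # 37.18 A
.bead_mass <- 7150             # Da
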
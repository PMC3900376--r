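# Unit handling. Internal units follow MD convention: coordinates nm,
# energies kJ/mol, forces kJ/mol/nm, angles radians internally and degrees
# user-facing. Forces are *reported* in pN.

#' Physical constants used by the force engine
#'
#' `ke_coulomb` is the Coulomb prefactor in MD units so that
#' `U = ke_coulomb * q1 * q2 / r` with charges in elementary-charge units and
#' r in nm gives kJ/mol. `kb` is the Boltzmann constant in kJ/mol/K.
#' `kj_mol_nm_per_pn` converts kJ/mol/nm to pN:
#' 1 kJ/mol/nm = 1e3 / (N_A * 1e-9) N = 1.66054e-12 N.
#' @keywords internal
.fda_const <- list(
  ke_coulomb = 138.935458,          # kJ mol^-1 nm e^-2
  kb = 0.008314462618,              # kJ mol^-1 K^-1
  kj_mol_nm_to_pn = 1e3 / (6.02214076e23 * 1e-9) * 1e12
)

#' Convert forces between kJ/mol/nm and pN
#'
#' Linear conversion between the internal MD force unit and the piconewton
#' scale used in reports and network cutoffs.
#'
#' @param x numeric vector of force values.
#' @param from,to one of `"kJ/mol/nm"`, `"pN"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_force(1, "kJ/mol/nm", "pN")  # ~1.660539
#' @export
convert_force <- function(x, from, to) {
  units <- c("kJ/mol/nm", "pN")
  if (!(from %in% units) || !(to %in% units)) {
    stop("unknown force unit; supported units: ", paste(units, collapse = ", "))
  }
  if (from == to) return(x)
  if (from == "kJ/mol/nm") x * .fda_const$kj_mol_nm_to_pn
  else x / .fda_const$kj_mol_nm_to_pn
}

#' @rdname convert_force
#' @export
force_unit_constant <- function() .fda_const$kj_mol_nm_to_pn

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
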
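#' Thermodynamic constants for binding free-energy estimates
#'
#' @param R Gas constant in J mol^-1 K^-1 (default 8.314).
#' @param temperature Absolute temperature in kelvin (default 310.15 K,
#'   i.e. 37 degrees C, the expression temperature).
#' @param c0 Standard-state concentration in molar for Ki conversion
#'   (default 1 M).
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(R = 8.314, temperature = 310.15, c0 = 1) {
  if (R <= 0 || temperature <= 0 || c0 <= 0) {
    stop("R, temperature and c0 must all be > 0")
  }
  structure(list(R = R, temperature = temperature, c0 = c0),
            class = "thermo_params")
}

#' Binding free energy from trafficking fold-enhancement
#'
#' Within a subunit folding (F) - unfolding (U) equilibrium model with
#' equilibrium constant K_FU, a chaperone that enhances trafficking
#' competence by a factor dK_FU has shifted the equilibrium by a per-subunit
#' free energy of -R T ln(dK_FU). Because the drug binds the assembled
#' tetramer, that stabilization is distributed among the four subunits, so
#' the per-tetramer binding free energy is four times the per-subunit value.
#'
#' @param delta_k_fu Fold-increase in trafficking competence (> 0),
#'   typically a [fold_enhancement()].
#' @param params A [thermo_params()].
#' @return List with `delta_k_fu`, `dg_subunit` and `dg_tetramer` (kJ/mol).
#' @export
#' @examples
#' dg_from_fold(17.36)$dg_subunit  # about -7.36 kJ/mol at 37 C
dg_from_fold <- function(delta_k_fu, params = thermo_params()) {
  stopifnot(inherits(params, "thermo_params"))
  if (any(!is.finite(delta_k_fu)) || any(delta_k_fu <= 0)) {
    stop("`delta_k_fu` must be > 0")
  }
  dg_sub <- -params$R * params$temperature * log(delta_k_fu) / 1000
  list(delta_k_fu = delta_k_fu, dg_subunit = dg_sub,
       dg_tetramer = 4 * dg_sub)
}

#' Binding free energy from an inhibitory constant
#'
#' Standard-state conversion `dG = R T ln(Ki / c0)`, the comparator used for
#' experimentally measured drug affinities at the cell surface.
#'
#' @param ki Inhibitory constant in molar (> 0).
#' @param params A [thermo_params()].
#' @return Binding free energy in kJ/mol (negative for sub-molar Ki).
#' @export
#' @examples
#' dg_from_ki(10e-9)  # ~ -47.5 kJ/mol at 37 C
dg_from_ki <- function(ki, params = thermo_params()) {
  stopifnot(inherits(params, "thermo_params"))
  if (any(!is.finite(ki)) || any(ki <= 0)) stop("`ki` must be > 0")
  params$R * params$temperature * log(ki / params$c0) / 1000
}

#' Per-variant binding free energies from a rescue table
#'
#' Computes the E-4031 fold-enhancement (`homo_e4031_cse / homo_cse`) and
#' the derived per-subunit and per-tetramer binding free energies for every
#' eligible variant. Variants with non-positive untreated CSE are skipped
#' with a warning (no fold can be formed). Folds corresponding to less than
#' 1 kJ/mol of stabilization (well under thermal energy RT ~ 2.6 kJ/mol at
#' 37 C) are flagged as negligible rescue.
#'
#' @param records Wide rescue table ([herg_table1()] or
#'   [build_rescue_table()] output).
#' @param params A [thermo_params()].
#' @return data.frame: `variant`, `delta_k_fu`, `dg_subunit`, `dg_tetramer`
#'   (kJ/mol), `negligible`.
#' @export
thermo_table <- function(records, params = thermo_params()) {
  req <- c("variant", "homo_cse", "homo_e4031_cse")
  if (!all(req %in% names(records))) {
    stop("records must have columns ", paste(req, collapse = ", "))
  }
  ok <- is.finite(records$homo_cse) & records$homo_cse > 0 &
    is.finite(records$homo_e4031_cse)
  if (any(!ok)) {
    warning("skipping variant(s) without a positive untreated CSE: ",
            paste(records$variant[!ok], collapse = ", "))
  }
  if (!any(ok)) stop("no eligible variants for thermodynamic estimates")
  rec <- records[ok, , drop = FALSE]
  fold <- fold_enhancement(rec$homo_e4031_cse, rec$homo_cse)
  dg <- dg_from_fold(fold, params)
  data.frame(variant = rec$variant,
             delta_k_fu = fold,
             dg_subunit = dg$dg_subunit,
             dg_tetramer = dg$dg_tetramer,
             negligible = dg$dg_subunit > -1,
             stringsAsFactors = FALSE)
}
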
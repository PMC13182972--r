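#' Default assembly parameters for the ten study variants
#'
#' The generator's stated world. Trafficking probabilities follow the
#' heterotetramer interpretation of the study: tetramers with zero or one
#' variant subunit traffic like WT, tetramers with two or more variant
#' subunits do not (`t = (t0, t0, 0, 0, t4)`). The WT homotetramer
#' probability is `t0 = 0.5` (WT itself sits mid-equilibrium, which is why a
#' chaperone can nearly double WT surface expression); each variant's
#' homotetramer probability `t4` and drug boost are taken from the packaged
#' measured table: `t4 = t0 * homo_cse / 100` and
#' `drug_boost = homo_e4031_cse / homo_cse` (1.868 for WT).
#'
#' @param t0 WT homotetramer trafficking probability (default 0.5).
#' @param t1_factor Trafficking probability of 3 WT / 1 variant
#'   heterotetramers relative to `t0` (default 1: trafficked like WT).
#' @return Named list of [assembly_params()], keyed by `"WT"` and each
#'   variant label.
#' @export
default_assembly_params <- function(t0 = 0.5, t1_factor = 1) {
  t1 <- herg_table1()
  out <- list(WT = assembly_params(
    t = c(t0, t0 * t1_factor, 0, 0, 0),
    drug_boost = t1$homo_e4031_cse[t1$variant == "WT"] /
      t1$homo_cse[t1$variant == "WT"]
  ))
  for (v in setdiff(t1$variant, "WT")) {
    a <- t1$homo_cse[t1$variant == v]
    b <- t1$homo_e4031_cse[t1$variant == v]
    out[[v]] <- assembly_params(
      t = c(t0, t0 * t1_factor, 0, 0, t0 * a / 100),
      drug_boost = b / a
    )
  }
  out
}

# 48-well plate well labels, row-major: A1..A8, B1.., .., F8.
plate_well_ids <- function(n) {
  if (n > 48L) stop("design needs ", n, " wells; a 48-well plate has 48")
  all_ids <- as.vector(t(outer(LETTERS[1:6], 1:8, paste0)))
  all_ids[seq_len(n)]
}

# Deterministic per-(seed, repeat, assay) RNG seed, kept within 32-bit range.
derive_seed <- function(seed, repeat_index, assay_type) {
  offset <- if (assay_type == "In-Cell") 104729L else 0L
  (abs(seed) + 7919L * repeat_index + offset) %% 2147483629L
}

# Expected per-tetramer-equivalent antibody signal for one condition.
condition_signal <- function(comp, assembly, assay_type) {
  if (comp$herg_mass <= 0) return(0)
  if (assay_type == "In-Cell") return(incell_signal())
  key <- if (is.na(comp$variant)) "WT" else comp$variant
  params <- assembly[[key]]
  if (is.null(params)) {
    stop("no assembly parameters supplied for '", key, "'")
  }
  w <- params$pool_weight
  params$f_var <- if (comp$var_mass > 0) {
    w * comp$var_mass / (w * comp$var_mass + comp$wt_mass)
  } else 0
  if (!is.na(comp$drug)) params <- apply_drug(params)
  oncell_signal(params, tau_wt = comp$tau_wt, tau_var = comp$tau_var)
}

# Mean-1 lognormal multiplier with the given coefficient of variation.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one independent repeat of a plate assay
#'
#' Generates raw two-channel well intensities for a transfection design under
#' the binomial tetramer-assembly model, with known ground truth. Per well:
#' total subunit synthesis is proportional to the total hERG plasmid mass
#' with lognormal noise (`cv_expression`); a latent per-well cell density
#' (lognormal, `cv_stain`) multiplies both channels, so the 800/700 ratio
#' used downstream cancels cell-number variation by construction;
#' `ch800 = gain_800 * (signal * synthesis + background_800) * density` and
#' `ch700 = gain_700 * density`. On-Cell signal comes from
#' [expected_oncell_signal()] (tag-count detection); In-Cell signal counts
#' all four subunits per tetramer-equivalent regardless of tag or location,
#' so In-Cell means are equal across conditions with equal total hERG
#' plasmid — the assay's synthesis-control contract holds by construction.
#' Each condition occupies two duplicate technical-replicate wells.
#'
#' @param design Design data.frame (see [builtin_designs()]).
#' @param assembly Named list of [assembly_params()] with an entry for
#'   `"WT"` and every variant appearing in the design.
#' @param noise A [noise_params()] object (carries the mandatory seed).
#' @param assay_type `"On-Cell"` or `"In-Cell"`.
#' @param repeat_index Independent repeat index (enters the derived RNG
#'   seed, so repeats differ but the whole experiment is reproducible).
#' @param plate_id Optional plate label.
#' @return An [assay_plate()].
#' @export
#' @examples
#' d <- builtin_designs()["fig5"]
#' p <- simulate_repeat(d$fig5, default_assembly_params(),
#'                      noise_params(seed = 1), "On-Cell")
simulate_repeat <- function(design, assembly, noise,
                            assay_type = c("On-Cell", "In-Cell"),
                            repeat_index = 1L, plate_id = NULL) {
  assay_type <- match.arg(assay_type)
  stopifnot(inherits(noise, "noise_params"))
  validate_design(design)
  conds <- unique(design$condition_id)
  comps <- lapply(conds, condition_composition, design = design)
  signals <- vapply(comps, condition_signal, numeric(1),
                    assembly = assembly, assay_type = assay_type)
  herg_mass <- vapply(comps, `[[`, numeric(1), "herg_mass")

  n_wells <- 2L * length(conds)
  wells <- plate_well_ids(n_wells)
  cond_of_well <- rep(conds, each = 2L)
  sig_of_well <- rep(signals, each = 2L)
  mass_of_well <- rep(herg_mass, each = 2L)

  set.seed(derive_seed(noise$seed, repeat_index, assay_type))
  density <- rlnorm_cv(n_wells, noise$cv_stain)
  synthesis <- mass_of_well * rlnorm_cv(n_wells, noise$cv_expression)
  ch800 <- noise$gain_800 * (sig_of_well * synthesis + noise$background_800) *
    density
  ch700 <- noise$gain_700 * density

  if (is.null(plate_id)) {
    plate_id <- sprintf("sim-%s-r%d", tolower(sub("-", "", assay_type)),
                        repeat_index)
  }
  assay_plate(
    data.frame(well = wells, condition_id = cond_of_well,
               ch700 = ch700, ch800 = ch800, stringsAsFactors = FALSE),
    design = design, assay_type = assay_type,
    repeat_index = repeat_index, plate_id = plate_id
  )
}

#' Simulate a full experiment (several independent repeats)
#'
#' @inheritParams simulate_repeat
#' @param n_repeats Number of independent repeats (default 4, the study's
#'   standard design).
#' @return List of [assay_plate()] objects, one per repeat.
#' @export
simulate_experiment <- function(design, assembly, noise,
                                assay_type = c("On-Cell", "In-Cell"),
                                n_repeats = 4L) {
  assay_type <- match.arg(assay_type)
  lapply(seq_len(n_repeats), function(r) {
    simulate_repeat(design, assembly, noise, assay_type, repeat_index = r)
  })
}
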
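#' Tetramer assembly and detection parameters
#'
#' `assembly_params()` bundles the parameters of the tetramer-assembly model
#' used by the synthetic plate generator. hERG channels are tetramers; when
#' wild-type (WT) and a variant subunit are co-expressed, subunits are assumed
#' to co-assemble by binomial sampling of four subunits from a well-mixed
#' pool. A tetramer carrying `k` variant subunits traffics to the cell surface
#' with probability `t[k + 1]`.
#'
#' @param f_var Fraction of variant subunits in the subunit pool, in
#'   \[0, 1\]. Usually derived from plasmid mass shares by the simulator and
#'   may be left `NA` in a parameter template.
#' @param t Numeric vector of length 5: trafficking probabilities
#'   `(t0, ..., t4)` for tetramers containing 0..4 variant subunits, each in
#'   \[0, 1\].
#' @param drug_boost Multiplicative fold applied to every `t[k]` under drug
#'   treatment (pharmacological chaperoning); boosted probabilities are
#'   clipped at 1. Must be > 0; 1 means no drug effect.
#' @param capacity Optional surface-capacity constant for saturation of
#'   surface expression (same units as the pre-saturation surface-subunit
#'   count per tetramer-equivalent, i.e. 0..4). `Inf` (default) disables
#'   saturation.
#' @param pool_weight Relative efficiency with which variant subunits enter
#'   the assembling pool, in (0, 1\]. Values < 1 express partial exclusion of
#'   a variant from tetramers; folded into the effective `f_var` by the
#'   simulator.
#' @return An object of class `assembly_params` (a list).
#' @seealso [assembly_fractions()], [expected_oncell_signal()],
#'   [simulate_repeat()]
#' @export
#' @examples
#' p <- assembly_params(f_var = 0.5, t = c(1, 1, 0, 0, 0))
#' expected_oncell_signal(p, tagged = "WT")
assembly_params <- function(f_var = NA_real_, t = c(1, 1, 0, 0, 0),
                            drug_boost = 1, capacity = Inf,
                            pool_weight = 1) {
  if (!is.na(f_var) && (f_var < 0 || f_var > 1)) {
    stop("`f_var` must lie in [0, 1], got ", f_var)
  }
  if (length(t) != 5L || any(!is.finite(t)) || any(t < 0) || any(t > 1)) {
    stop("`t` must be 5 trafficking probabilities in [0, 1]")
  }
  if (!is.finite(drug_boost) || drug_boost <= 0) {
    stop("`drug_boost` must be a positive finite fold")
  }
  if (is.na(capacity) || capacity <= 0) {
    stop("`capacity` must be positive (Inf disables saturation)")
  }
  if (pool_weight <= 0 || pool_weight > 1) {
    stop("`pool_weight` must lie in (0, 1]")
  }
  structure(
    list(f_var = as.numeric(f_var), t = as.numeric(t),
         drug_boost = as.numeric(drug_boost), capacity = as.numeric(capacity),
         pool_weight = as.numeric(pool_weight)),
    class = "assembly_params"
  )
}

#' Noise and detection parameters for the synthetic plate generator
#'
#' All noise is multiplicative lognormal (fluorescence noise scales with
#' signal); every draw comes from one seeded generator so simulations are
#' fully reproducible.
#'
#' @param seed Integer seed; mandatory for any simulation.
#' @param cv_expression Coefficient of variation of per-well total subunit
#'   synthesis (default 0.10).
#' @param cv_stain CV of the per-well cell density read out by the
#'   700-channel cell stain (default 0.08). Cell density multiplies both
#'   channels, so the per-well 800/700 ratio cancels it by construction.
#' @param background_800 Mean nonspecific 800-channel signal per well, on the
#'   scale of the surface signal (0..4 tagged subunits per
#'   tetramer-equivalent); default 0.05.
#' @param gain_800,gain_700 Channel gains converting model signal to
#'   arbitrary fluorescence counts. Defaults give raw intensities and
#'   normalized values on the scale seen on real scanners (normalized values
#'   of order 1e-8).
#' @return An object of class `noise_params` (a list).
#' @export
noise_params <- function(seed, cv_expression = 0.10, cv_stain = 0.08,
                         background_800 = 0.05, gain_800 = 1e6,
                         gain_700 = 1e5) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("`seed` is mandatory for simulation")
  }
  if (cv_expression < 0 || cv_stain < 0) stop("CVs must be >= 0")
  if (background_800 < 0) stop("`background_800` must be >= 0")
  if (gain_800 <= 0 || gain_700 <= 0) stop("gains must be > 0")
  structure(
    list(seed = as.integer(seed), cv_expression = cv_expression,
         cv_stain = cv_stain, background_800 = background_800,
         gain_800 = gain_800, gain_700 = gain_700),
    class = "noise_params"
  )
}

#' Binomial tetramer composition distribution
#'
#' Probability that a tetramer assembled from a well-mixed subunit pool with
#' variant fraction `f_var` contains k = 0..4 variant subunits:
#' P(k) = C(4,k) f^k (1-f)^(4-k).
#'
#' @param f_var Variant subunit fraction in \[0, 1\].
#' @return Numeric vector of 5 probabilities (k = 0..4), summing to 1.
#' @export
#' @examples
#' assembly_fractions(0.5)  # c(1, 4, 6, 4, 1) / 16
assembly_fractions <- function(f_var) {
  if (!is.numeric(f_var) || length(f_var) != 1L || is.na(f_var) ||
      f_var < 0 || f_var > 1) {
    stop("`f_var` must be a single number in [0, 1]")
  }
  stats::dbinom(0:4, size = 4, prob = f_var)
}

#' Apply drug treatment to assembly parameters
#'
#' Multiplies every trafficking probability by `drug_boost` and clips at 1,
#' modelling a pharmacological chaperone that shifts the subunit
#' folding-unfolding equilibrium toward the traffic-competent state uniformly
#' across tetramer compositions.
#'
#' @param params An [assembly_params()] object.
#' @return A new `assembly_params` with boosted, clipped `t` and
#'   `drug_boost = 1`.
#' @export
apply_drug <- function(params) {
  stopifnot(inherits(params, "assembly_params"))
  params$t <- pmin(1, params$t * params$drug_boost)
  params$drug_boost <- 1
  params
}

# Expected tagged-subunit surface count per tetramer-equivalent for arbitrary
# tag fractions within the WT and variant subunit classes. tau_wt (tau_var)
# is the fraction of WT (variant) subunits carrying the HA tag.
oncell_signal <- function(params, tau_wt, tau_var) {
  stopifnot(inherits(params, "assembly_params"))
  if (is.na(params$f_var)) stop("`f_var` must be set to compute a signal")
  k <- 0:4
  p <- assembly_fractions(params$f_var)
  surf_total <- sum(p * params$t * 4)        # surface subunits, all tags
  tagged <- sum(p * params$t * ((4 - k) * tau_wt + k * tau_var))
  if (is.finite(params$capacity) && surf_total > 0) {
    scaled <- surf_total * params$capacity / (surf_total + params$capacity)
    tagged <- tagged * scaled / surf_total
  }
  tagged
}

#' Expected On-Cell signal per tetramer-equivalent
#'
#' Expected number of HA-tagged subunits detected at the cell surface per
#' tetramer-equivalent of synthesis, under the binomial assembly model.
#' Detection is proportional to the count of HA epitopes per surface
#' tetramer: a tetramer with k variant subunits contributes `4 - k` tagged
#' subunits if only WT is tagged, `k` if only the variant is tagged, and 4 if
#' both are. With a finite `capacity`, the pre-saturation total surface count
#' S is mapped to `S * capacity / (S + capacity)` before tag apportioning.
#'
#' @param params An [assembly_params()] object with `f_var` set.
#' @param tagged Character subset of `c("WT", "var")` naming which subunit
#'   classes carry the HA tag. Empty (`character()`) models a background-only
#'   condition and returns 0.
#' @return Expected tagged surface-subunit count (scalar, 0..4).
#' @export
#' @examples
#' p <- assembly_params(f_var = 0.5, t = c(1, 1, 0, 0, 0))
#' expected_oncell_signal(p, "WT")           # 1.0
#' expected_oncell_signal(p, "var")          # 0.25
expected_oncell_signal <- function(params, tagged = c("WT", "var")) {
  if (length(tagged) > 0 && !all(tagged %in% c("WT", "var"))) {
    stop("`tagged` must be a subset of c(\"WT\", \"var\")")
  }
  oncell_signal(params,
                tau_wt = as.numeric("WT" %in% tagged),
                tau_var = as.numeric("var" %in% tagged))
}

# In-Cell detection: the pan-hERG antibody sees every synthesized subunit in
# fixed, permeabilized cells regardless of tag or trafficking outcome, so the
# per-tetramer-equivalent signal is the full 4 subunits.
incell_signal <- function() 4
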
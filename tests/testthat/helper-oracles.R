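# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration for the assembly model,
# explicit normal equations for OLS.

# Tetramer composition distribution by exhaustive enumeration of all 2^4
# ordered WT/variant 4-tuples.
enum_assembly_fractions <- function(f_var) {
  tuples <- expand.grid(rep(list(c(0, 1)), 4))
  k <- rowSums(tuples)
  prob <- apply(tuples, 1, function(tt) {
    prod(ifelse(tt == 1, f_var, 1 - f_var))
  })
  vapply(0:4, function(kk) sum(prob[k == kk]), numeric(1))
}

# Expected tagged surface-subunit count per tetramer-equivalent by the same
# enumeration, with optional hyperbolic capacity applied to the total.
enum_oncell <- function(f_var, t, tau_wt, tau_var, capacity = Inf) {
  p <- enum_assembly_fractions(f_var)
  k <- 0:4
  total <- sum(p * t * 4)
  tagged <- sum(p * t * ((4 - k) * tau_wt + k * tau_var))
  if (is.finite(capacity) && total > 0) {
    tagged <- tagged * (total * capacity / (total + capacity)) / total
  }
  tagged
}

# Closed-form OLS by normal equations, solved explicitly.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  det <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / det
  intercept <- (sy * sxx - sx * sxy) / det
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Zero-noise ground truth for the rescue-table columns, computed from the
# enumeration oracle (not the package's signal function). `assembly` is a
# default_assembly_params()-shaped list.
truth_rescue_table <- function(assembly, variants) {
  t0vec <- assembly$WT$t
  ctrl_homo <- enum_oncell(0, t0vec, 1, 0)            # HA-WT alone
  ctrl_het <- enum_oncell(0, t0vec, 0.5, 0)           # HA-WT + un-WT
  rows <- lapply(variants, function(v) {
    pv <- assembly[[v]]
    tv <- pv$t
    tvd <- pmin(1, tv * pv$drug_boost)
    data.frame(
      variant = v,
      homo_cse = 100 * enum_oncell(1, tv, 0, 1) / ctrl_homo,
      homo_e4031_cse = 100 * enum_oncell(1, tvd, 0, 1) / ctrl_homo,
      total_coexpr_cse = 100 * enum_oncell(0.5, tv, 1, 1) / ctrl_homo,
      wt_residual_cse = 100 * enum_oncell(0.5, tv, 1, 0) / ctrl_het,
      wt_rescue_cse = 100 * enum_oncell(0.5, tv, 0, 1) / ctrl_het
    )
  })
  wt <- data.frame(
    variant = "WT", homo_cse = 100,
    homo_e4031_cse = 100 * enum_oncell(0, pmin(1, t0vec * assembly$WT$drug_boost),
                                       1, 0) / ctrl_homo,
    total_coexpr_cse = 100, wt_residual_cse = 100, wt_rescue_cse = 100
  )
  rbind(wt, do.call(rbind, rows))
}

zero_noise <- function(seed = 1) {
  noise_params(seed = seed, cv_expression = 0, cv_stain = 0,
               background_800 = 0)
}

# Simulate all four designs On-Cell and return the rescue table.
simulate_rescue_table <- function(assembly, noise, n_repeats = 4L,
                                  variants = herg_study_variants()) {
  designs <- builtin_designs(variants)
  summaries <- lapply(designs, function(d) {
    plates <- simulate_experiment(d, assembly, noise, "On-Cell",
                                  n_repeats = n_repeats)
    summarize_conditions(do.call(rbind, lapply(plates, normalize_plate)))
  })
  build_rescue_table(summaries, variants = variants)
}

# Tiny synthetic PDB (CA-only) covering the given residue numbers.
synthetic_pdb_lines <- function(positions, bfac = 0) {
  vapply(seq_along(positions), function(i) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, positions[i], i * 1.0, 0, 0, 1.00, bfac)
  }, character(1))
}

# Tolerance ordering used for monotonicity checks (no_data excluded).
tolerance_rank <- function(category) {
  match(category, residue_categories())
}
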
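#' The ten hERG variants of the heterozygous trafficking study
#'
#' Eight natural variants in or near the S2-S3 loop of the voltage sensor
#' domain plus the two previously characterized controls N470D (VSD) and
#' L615F (pore domain).
#'
#' @return Character vector of variant labels.
#' @export
herg_study_variants <- function() {
  c("L615F", "N470D", "I400N", "H402R", "R472P",
    "T473P", "T474I", "Y475C", "V483F", "H492L")
}

#' Build one transfection condition
#'
#' A condition is the plasmid mix transfected into a well, plus an optional
#' drug arm. Construct names follow the tagging convention `HA-WT`,
#' `HA-<variant>`, `un-WT`, `un-<variant>` and `empty-vector`; the HA prefix
#' marks constructs whose protein carries the extracellular HA tag used for
#' surface detection.
#'
#' @param id Short unique condition label.
#' @param constructs Named numeric vector of plasmid masses in micrograms,
#'   names being construct names. Masses must be strictly positive and sum
#'   to 1 (the fixed total of 1 ug plasmid per well).
#' @param drug Drug name or `NA` for untreated.
#' @param drug_um Drug concentration in micromolar (`NA` if untreated).
#' @return A data.frame with one row per construct (columns `condition_id`,
#'   `construct`, `mass_ug`, `drug`, `drug_um`).
#' @export
#' @examples
#' condition("HA-WT", c("HA-WT" = 0.5, "empty-vector" = 0.5))
condition <- function(id, constructs, drug = NA_character_,
                      drug_um = NA_real_) {
  if (is.null(names(constructs)) || any(!nzchar(names(constructs)))) {
    stop("`constructs` must be a named mass vector")
  }
  if (anyDuplicated(names(constructs))) {
    stop("construct names must be unique within condition '", id, "'")
  }
  if (any(constructs <= 0)) {
    stop("plasmid masses must be strictly positive in condition '", id, "'")
  }
  if (abs(sum(constructs) - 1) > 1e-9) {
    stop("total plasmid mass in condition '", id, "' must be 1 ug, got ",
         sum(constructs))
  }
  data.frame(condition_id = id, construct = names(constructs),
             mass_ug = as.numeric(constructs), drug = drug,
             drug_um = drug_um, stringsAsFactors = FALSE)
}

#' Validate a transfection design
#'
#' @param design A design data.frame (rows = construct entries, see
#'   [condition()]), typically from [builtin_designs()].
#' @return The design, invisibly, if valid; otherwise an error.
#' @export
validate_design <- function(design) {
  req <- c("condition_id", "construct", "mass_ug", "drug", "drug_um")
  if (!all(req %in% names(design))) {
    stop("design must have columns ", paste(req, collapse = ", "))
  }
  for (id in unique(design$condition_id)) {
    rows <- design[design$condition_id == id, ]
    if (anyDuplicated(rows$construct)) {
      stop("duplicate construct in condition '", id, "'")
    }
    if (any(rows$mass_ug <= 0)) {
      stop("non-positive plasmid mass in condition '", id, "'")
    }
    if (abs(sum(rows$mass_ug) - 1) > 1e-9) {
      stop("condition '", id, "' plasmid masses sum to ",
           sum(rows$mass_ug), ", not 1 ug")
    }
    if (length(unique(paste(rows$drug, rows$drug_um))) != 1L) {
      stop("inconsistent drug annotation within condition '", id, "'")
    }
  }
  invisible(design)
}

# Decompose a construct name into tag status and subunit identity.
parse_construct <- function(construct) {
  if (construct %in% c("empty-vector", "empty")) {
    return(list(is_herg = FALSE, tagged = FALSE, base = NA_character_))
  }
  if (grepl("^HA-", construct)) {
    return(list(is_herg = TRUE, tagged = TRUE, base = sub("^HA-", "", construct)))
  }
  if (grepl("^un-", construct)) {
    return(list(is_herg = TRUE, tagged = FALSE, base = sub("^un-", "", construct)))
  }
  stop("unrecognized construct name '", construct, "'")
}

# Per-condition composition summary used by the simulator: hERG mass, WT and
# variant mass shares, tag fractions within each class, drug arm.
condition_composition <- function(design, id) {
  rows <- design[design$condition_id == id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown condition '", id, "'")
  info <- lapply(rows$construct, parse_construct)
  is_herg <- vapply(info, `[[`, logical(1), "is_herg")
  tagged <- vapply(info, `[[`, logical(1), "tagged")
  base <- vapply(info, `[[`, character(1), "base")
  m <- rows$mass_ug
  herg_mass <- sum(m[is_herg])
  wt <- is_herg & base == "WT"
  vr <- is_herg & base != "WT"
  variants <- unique(base[vr])
  if (length(variants) > 1L) {
    stop("condition '", id, "' mixes more than one variant")
  }
  wt_mass <- sum(m[wt])
  var_mass <- sum(m[vr])
  list(
    id = id,
    herg_mass = herg_mass,
    wt_mass = wt_mass,
    var_mass = var_mass,
    variant = if (length(variants)) variants else NA_character_,
    tau_wt = if (wt_mass > 0) sum(m[wt & tagged]) / wt_mass else 0,
    tau_var = if (var_mass > 0) sum(m[vr & tagged]) / var_mass else 0,
    drug = rows$drug[1],
    drug_um = rows$drug_um[1]
  )
}

#' Built-in transfection designs of the heterozygous trafficking study
#'
#' Returns the four 48-well plate designs used throughout the study, exactly
#' as run (all conditions total 1 ug plasmid per well, duplicate wells):
#' \describe{
#'   \item{fig2}{Total surface expression under heterozygosity: empty vector;
#'     0.5 ug HA-WT control; 0.25 ug HA-WT + 0.25 ug HA-variant (+ 0.5 ug
#'     empty vector) for each variant. 12 conditions.}
#'   \item{fig3}{Dominant-negative readout (only WT tagged): empty vector;
#'     0.5 ug un-WT; 0.5 ug un-variant each; 0.5 ug HA-WT; 0.5 ug HA-WT +
#'     0.5 ug un-WT (control); 0.5 ug HA-WT + 0.5 ug un-variant each.
#'     24 conditions.}
#'   \item{fig4}{WT rescue of variant (only variant tagged): empty vector;
#'     0.5 ug un-WT; 0.5 ug HA-variant each; 0.5 ug HA-WT; 0.5 ug HA-WT +
#'     0.5 ug un-WT (control); 0.5 ug HA-variant + 0.5 ug un-WT each.
#'     24 conditions.}
#'   \item{fig5}{Pharmacological rescue: every hERG condition is 0.5 ug
#'     HA-construct + 0.5 ug empty vector, paired with and without 5 uM
#'     E-4031 applied 24 h before assay. 23 conditions.}
#' }
#'
#' @param variants Character vector of variant labels (default the ten study
#'   variants).
#' @return Named list of validated design data.frames.
#' @export
builtin_designs <- function(variants = herg_study_variants()) {
  half <- function(x) stats::setNames(c(0.5, 0.5), c(x, "empty-vector"))
  co <- function(a, b) stats::setNames(c(0.5, 0.5), c(a, b))

  fig2 <- rbind(
    condition("empty", c("empty-vector" = 1)),
    condition("HA-WT", half("HA-WT")),
    do.call(rbind, lapply(variants, function(v) {
      condition(paste0("HA-WT+HA-", v),
                stats::setNames(c(0.25, 0.25, 0.5),
                                c("HA-WT", paste0("HA-", v), "empty-vector")))
    }))
  )

  fig3 <- rbind(
    condition("empty", c("empty-vector" = 1)),
    condition("un-WT", half("un-WT")),
    do.call(rbind, lapply(variants, function(v) {
      condition(paste0("un-", v), half(paste0("un-", v)))
    })),
    condition("HA-WT", half("HA-WT")),
    condition("HA-WT+un-WT", co("HA-WT", "un-WT")),
    do.call(rbind, lapply(variants, function(v) {
      condition(paste0("HA-WT+un-", v), co("HA-WT", paste0("un-", v)))
    }))
  )

  fig4 <- rbind(
    condition("empty", c("empty-vector" = 1)),
    condition("un-WT", half("un-WT")),
    do.call(rbind, lapply(variants, function(v) {
      condition(paste0("HA-", v), half(paste0("HA-", v)))
    })),
    condition("HA-WT", half("HA-WT")),
    condition("HA-WT+un-WT", co("HA-WT", "un-WT")),
    do.call(rbind, lapply(variants, function(v) {
      condition(paste0("HA-", v, "+un-WT"), co(paste0("HA-", v), "un-WT"))
    }))
  )

  e4031 <- function(id, constructs) {
    condition(paste0(id, "+E4031"), constructs, drug = "E-4031", drug_um = 5)
  }
  fig5 <- rbind(
    condition("empty", c("empty-vector" = 1)),
    condition("HA-WT", half("HA-WT")),
    e4031("HA-WT", half("HA-WT")),
    do.call(rbind, lapply(variants, function(v) {
      rbind(condition(paste0("HA-", v), half(paste0("HA-", v))),
            e4031(paste0("HA-", v), half(paste0("HA-", v))))
    }))
  )

  designs <- list(fig2 = fig2, fig3 = fig3, fig4 = fig4, fig5 = fig5)
  lapply(designs, validate_design)
  designs
}
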
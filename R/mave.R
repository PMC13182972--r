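#' Classify a trafficking score against the 40% threshold
#'
#' Variant-effect surface-expression scores are dichotomized at 40% of WT:
#' scores of 40% or greater count as moderate-to-high trafficking ("pass"),
#' below 40% as poor. The boundary is inclusive.
#'
#' @param score Cell-surface expression as % of WT (>= 0).
#' @param threshold Pass threshold in % of WT (default 40).
#' @return Character vector, `"pass"` or `"poor"`.
#' @export
traffic_class <- function(score, threshold = 40) {
  if (any(!is.finite(score)) || any(score < 0)) {
    stop("scores must be finite and >= 0")
  }
  ifelse(score >= threshold, "pass", "poor")
}

#' Default physicochemical amino-acid grouping
#'
#' Substitutions within a group are conservative; across groups,
#' non-conservative. A standard hydrophobic / aromatic / polar / charged
#' grouping with glycine, proline and cysteine as singletons (their backbone
#' or redox chemistry is not interchangeable with anything).
#'
#' @return Named list of character vectors of single-letter codes.
#' @export
default_aa_groups <- function() {
  list(aliphatic = c("A", "V", "L", "I", "M"),
       aromatic = c("F", "W", "Y"),
       hydroxyl = c("S", "T"),
       amide = c("N", "Q"),
       acidic = c("D", "E"),
       basic = c("K", "R", "H"),
       glycine = "G",
       proline = "P",
       cysteine = "C")
}

#' Is a substitution conservative?
#'
#' @param ref_aa,alt_aa Single-letter amino-acid codes.
#' @param groups Substitution grouping (default [default_aa_groups()]).
#' @return `TRUE` iff both residues share a group.
#' @export
#' @examples
#' is_conservative("V", "I")  # TRUE
#' is_conservative("R", "C")  # FALSE
is_conservative <- function(ref_aa, alt_aa, groups = default_aa_groups()) {
  known <- unlist(groups, use.names = FALSE)
  bad <- setdiff(c(ref_aa, alt_aa), known)
  if (length(bad)) {
    stop("nonstandard residue code(s): ", paste(unique(bad), collapse = ", "))
  }
  grp <- function(aa) which(vapply(groups, function(g) aa %in% g, logical(1)))
  mapply(function(r, a) identical(grp(r), grp(a)), ref_aa, alt_aa,
         USE.NAMES = FALSE)
}

#' Default residue-category rules
#'
#' Thresholds for [categorize_residue()]. `orange_max` and `blue_min` are
#' pass-fraction bounds; the pass threshold feeds [traffic_class()].
#'
#' @param pass_threshold Score threshold, % of WT (default 40).
#' @param orange_max Upper pass-fraction bound for `low_tolerance`
#'   (default 0.25).
#' @param blue_min Exclusive lower pass-fraction bound for `exchangeable`
#'   (default 0.75).
#' @return List of rules.
#' @export
category_rules <- function(pass_threshold = 40, orange_max = 0.25,
                           blue_min = 0.75) {
  if (orange_max < 0 || blue_min > 1 || orange_max >= blue_min) {
    stop("need 0 <= orange_max < blue_min <= 1")
  }
  list(pass_threshold = pass_threshold, orange_max = orange_max,
       blue_min = blue_min)
}

#' Residue tolerance categories, in increasing order of tolerance
#'
#' The ordering used for monotonicity guarantees: a residue where only
#' conservative substitutions are accommodated (`conservative_only`) is
#' considered less tolerant than one where some non-conservative
#' substitution passes (`low_tolerance`), even at a low pass fraction.
#' `no_data` is outside the ordering. Display codes (0-5) follow the
#' conventional color legend grey, red, orange, yellow, cyan, blue.
#'
#' @return Character vector of category names.
#' @export
residue_categories <- function() {
  c("intolerant", "conservative_only", "low_tolerance", "moderate",
    "exchangeable")
}

# Display codes for annotation output (legend order).
category_code <- function(category) {
  codes <- c(no_data = 0L, intolerant = 1L, low_tolerance = 2L,
             conservative_only = 3L, moderate = 4L, exchangeable = 5L)
  unname(codes[category])
}

#' Aggregate variant scores at one residue into a tolerance category
#'
#' Deterministic category from the count tuple (number of variants, number
#' passing the trafficking threshold, conservative/non-conservative passes),
#' first matching rule wins:
#' \enumerate{
#'   \item no variants -> `no_data` (grey);
#'   \item no variant passes -> `intolerant` (red);
#'   \item every passing variant is conservative and at least one
#'     non-conservative variant was tested and failed -> `conservative_only`
#'     (yellow);
#'   \item pass fraction > `blue_min` -> `exchangeable` (blue);
#'   \item pass fraction <= `orange_max` -> `low_tolerance` (orange);
#'   \item otherwise -> `moderate` (cyan).
#' }
#' The function is a pure function of the counts: permuting the variant rows
#' never changes the outcome, and raising any score can only move the
#' residue toward a more tolerant category under the ordering of
#' [residue_categories()].
#'
#' @param variants data.frame with columns `position`, `ref_aa`, `alt_aa`,
#'   `score` (% of WT), all rows sharing one position; zero rows allowed.
#' @param rules A [category_rules()] list.
#' @param groups Conservative grouping ([default_aa_groups()]).
#' @param position Residue number; required when `variants` has zero rows.
#' @return One-row data.frame: `position`, `category`, `code`, `n_variants`,
#'   `n_pass`, `n_conservative_pass`, `n_nonconservative_pass`.
#' @export
categorize_residue <- function(variants, rules = category_rules(),
                               groups = default_aa_groups(),
                               position = NULL) {
  n <- if (is.null(variants)) 0L else nrow(variants)
  if (n == 0L) {
    if (is.null(position)) stop("`position` required for an empty variant set")
    return(data.frame(position = position, category = "no_data",
                      code = category_code("no_data"), n_variants = 0L,
                      n_pass = 0L, n_conservative_pass = 0L,
                      n_nonconservative_pass = 0L, stringsAsFactors = FALSE))
  }
  pos <- unique(variants$position)
  if (length(pos) != 1L) {
    stop("variants span several positions: ", paste(pos, collapse = ", "))
  }
  if (any(variants$ref_aa == variants$alt_aa)) {
    stop("synonymous entries must be removed upstream")
  }
  pass <- traffic_class(variants$score, rules$pass_threshold) == "pass"
  cons <- is_conservative(variants$ref_aa, variants$alt_aa, groups)
  n_pass <- sum(pass)
  n_cons_pass <- sum(pass & cons)
  n_noncons_pass <- sum(pass & !cons)
  n_noncons <- sum(!cons)
  pf <- n_pass / n

  category <- if (n_pass == 0L) {
    "intolerant"
  } else if (n_noncons_pass == 0L && n_noncons >= 1L) {
    "conservative_only"
  } else if (pf > rules$blue_min) {
    "exchangeable"
  } else if (pf <= rules$orange_max) {
    "low_tolerance"
  } else {
    "moderate"
  }
  data.frame(position = pos, category = category,
             code = category_code(category), n_variants = n,
             n_pass = n_pass, n_conservative_pass = n_cons_pass,
             n_nonconservative_pass = n_noncons_pass,
             stringsAsFactors = FALSE)
}

#' Categorize every residue in a variant-effect table
#'
#' @param scores data.frame with columns `position`, `ref_aa`, `alt_aa`,
#'   `score`.
#' @param positions Optional integer vector of residue positions to report;
#'   positions without data are returned as `no_data`. Defaults to the
#'   positions present in `scores`.
#' @inheritParams categorize_residue
#' @return data.frame with one row per position (see [categorize_residue()]).
#' @export
categorize_variants <- function(scores, rules = category_rules(),
                                groups = default_aa_groups(),
                                positions = NULL) {
  req <- c("position", "ref_aa", "alt_aa", "score")
  if (!all(req %in% names(scores))) {
    stop("`scores` must have columns ", paste(req, collapse = ", "))
  }
  if (is.null(positions)) positions <- sort(unique(scores$position))
  out <- do.call(rbind, lapply(positions, function(p) {
    categorize_residue(scores[scores$position == p, , drop = FALSE],
                       rules = rules, groups = groups, position = p)
  }))
  rownames(out) <- NULL
  out
}

#' Write residue-category annotations for molecular viewers
#'
#' Writes a tab-separated residue-attribute file (`position`, `category`,
#' `code`) and, when a PDB structure file is supplied, a copy of the
#' structure with the per-residue category code placed in the
#' temperature-factor (B-factor) column of every ATOM/HETATM record.
#' Residues of the structure absent from the category table are coded as
#' `no_data` (0); category positions absent from the structure trigger a
#' warning and are kept in the attribute file only.
#'
#' @param categories Category table from [categorize_variants()].
#' @param out_path Output path for the attribute TSV.
#' @param structure_path Optional input PDB file.
#' @param structure_out Output path for the annotated PDB (required when
#'   `structure_path` is given).
#' @return Invisibly, the attribute data.frame written.
#' @export
write_structure_annotation <- function(categories, out_path,
                                       structure_path = NULL,
                                       structure_out = NULL) {
  if (anyDuplicated(categories$position)) {
    stop("duplicate positions in category table")
  }
  attr_df <- categories[order(categories$position),
                        c("position", "category", "code")]
  con <- file(out_path, "w")
  on.exit(close(con))
  writeLines(c("# residue mutational-tolerance categories",
               "# code: 0 no_data, 1 intolerant, 2 low_tolerance, 3 conservative_only, 4 moderate, 5 exchangeable",
               paste(c("position", "category", "code"), collapse = "\t")),
             con)
  writeLines(paste(attr_df$position, attr_df$category, attr_df$code,
                   sep = "\t"), con)

  if (!is.null(structure_path)) {
    if (is.null(structure_out)) {
      stop("`structure_out` required when annotating a structure")
    }
    lines <- readLines(structure_path)
    is_atom <- grepl("^(ATOM  |HETATM)", lines)
    resseq <- suppressWarnings(as.integer(substr(lines[is_atom], 23, 26)))
    code <- category_code("no_data") + integer(length(resseq))
    hit <- match(resseq, attr_df$position)
    code[!is.na(hit)] <- attr_df$code[hit[!is.na(hit)]]
    bfac <- sprintf("%6.2f", code)
    lines[is_atom] <- paste0(substr(lines[is_atom], 1, 60), bfac,
                             substring(lines[is_atom], 67))
    writeLines(lines, structure_out)
    missing <- setdiff(attr_df$position, resseq)
    if (length(missing)) {
      warning("category position(s) absent from structure: ",
              paste(missing, collapse = ", "))
    }
  }
  invisible(attr_df)
}
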
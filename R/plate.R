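#' Construct an assay plate object
#'
#' One independent repeat of an On-Cell or In-Cell western plate: per-well
#' raw 700-channel (WGA-680 cell stain) and 800-channel (antibody) arbitrary
#' fluorescence intensities joined to a condition layout.
#'
#' @param wells data.frame with columns `well` (e.g. "A1"), `condition_id`,
#'   `ch700`, `ch800`.
#' @param design The condition design data.frame the layout refers to
#'   (see [builtin_designs()]); may be `NULL` for layout-only use.
#' @param assay_type `"On-Cell"` (surface) or `"In-Cell"` (total protein).
#' @param repeat_index Positive integer index of the independent repeat.
#' @param plate_id Plate label.
#' @return An object of class `assay_plate`.
#' @export
assay_plate <- function(wells, design = NULL,
                        assay_type = c("On-Cell", "In-Cell"),
                        repeat_index = 1L, plate_id = "plate1") {
  assay_type <- match.arg(assay_type)
  req <- c("well", "condition_id", "ch700", "ch800")
  if (!all(req %in% names(wells))) {
    stop("`wells` must have columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(wells$well)) stop("duplicate well identifiers")
  bad700 <- wells$well[!is.finite(wells$ch700) | wells$ch700 <= 0]
  if (length(bad700)) {
    stop("ch700 must be > 0 (normalization divisor); offending well(s): ",
         paste(bad700, collapse = ", "))
  }
  bad800 <- wells$well[!is.finite(wells$ch800) | wells$ch800 < 0]
  if (length(bad800)) {
    stop("ch800 must be >= 0; offending well(s): ",
         paste(bad800, collapse = ", "))
  }
  if (!is.null(design)) {
    validate_design(design)
    unknown <- setdiff(wells$condition_id, design$condition_id)
    if (length(unknown)) {
      stop("condition_id not declared in design: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(plate_id = plate_id, assay_type = assay_type,
         repeat_index = as.integer(repeat_index),
         wells = wells[order(wells$well), , drop = FALSE],
         design = design),
    class = "assay_plate"
  )
}

#' @export
print.assay_plate <- function(x, ...) {
  cat(sprintf("<assay_plate> %s | %s | repeat %d | %d wells, %d conditions\n",
              x$plate_id, x$assay_type, x$repeat_index, nrow(x$wells),
              length(unique(x$wells$condition_id))))
  invisible(x)
}

#' Read a plate from layout and intensity CSV files
#'
#' The layout CSV (`well,condition_id`) describes the plate design once; the
#' intensities CSV (`well,ch700,ch800[,repeat]`) holds one repeat's raw
#' two-channel readings. An explicit `repeat` column in the intensities file
#' wins over the `repeat_index` argument.
#'
#' @param layout_path Path to the layout CSV.
#' @param intensities_path Path to the intensities CSV.
#' @inheritParams assay_plate
#' @return An [assay_plate()].
#' @export
read_plate <- function(layout_path, intensities_path, design = NULL,
                       assay_type = c("On-Cell", "In-Cell"),
                       repeat_index = 1L, plate_id = NULL) {
  assay_type <- match.arg(assay_type)
  layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  inten <- utils::read.csv(intensities_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!all(c("well", "condition_id") %in% names(layout))) {
    stop("layout CSV must have columns well,condition_id")
  }
  if (!all(c("well", "ch700", "ch800") %in% names(inten))) {
    stop("intensities CSV must have columns well,ch700,ch800")
  }
  miss_i <- setdiff(layout$well, inten$well)
  if (length(miss_i)) {
    stop("well(s) missing from intensities file: ",
         paste(miss_i, collapse = ", "))
  }
  miss_l <- setdiff(inten$well, layout$well)
  if (length(miss_l)) {
    stop("well(s) missing from layout file: ",
         paste(miss_l, collapse = ", "))
  }
  if ("repeat" %in% names(inten)) {
    ri <- unique(inten[["repeat"]])
    if (length(ri) != 1L) stop("intensities file mixes repeat indices")
    repeat_index <- as.integer(ri)
  }
  wells <- merge(layout, inten[c("well", "ch700", "ch800")], by = "well")
  wells$ch700 <- as.numeric(wells$ch700)
  wells$ch800 <- as.numeric(wells$ch800)
  if (is.null(plate_id)) {
    plate_id <- sub("\\.[^.]*$", "", basename(intensities_path))
  }
  assay_plate(wells, design = design, assay_type = assay_type,
              repeat_index = repeat_index, plate_id = plate_id)
}

#' Write a plate to layout and intensity CSV files
#'
#' Inverse of [read_plate()]; values are written at full double precision so
#' that `read_plate(write_plate(x))` reproduces `x` bit-identically.
#'
#' @param plate An [assay_plate()].
#' @inheritParams read_plate
#' @export
write_plate <- function(plate, layout_path, intensities_path) {
  stopifnot(inherits(plate, "assay_plate"))
  w <- plate$wells
  utils::write.csv(w[c("well", "condition_id")], layout_path,
                   row.names = FALSE, quote = FALSE)
  inten <- data.frame(well = w$well,
                      ch700 = sprintf("%.17g", w$ch700),
                      ch800 = sprintf("%.17g", w$ch800),
                      check.names = FALSE)
  inten[["repeat"]] <- plate$repeat_index
  utils::write.csv(inten, intensities_path, row.names = FALSE, quote = FALSE)
  invisible(plate)
}

#' Write a result table to CSV
#'
#' Result tables are long-format records `(variant, measurement, value, sem,
#' n)`; measurement labels mirror the columns of the study's summary table
#' (e.g. `homo_cse`, `homo_e4031_cse`). Values are written at full float
#' precision and round-trip losslessly through [read_result_table()].
#'
#' @param table data.frame with columns `variant`, `measurement`, `value`,
#'   `sem`, `n`.
#' @param path Output CSV path.
#' @export
write_result_table <- function(table, path) {
  req <- c("variant", "measurement", "value", "sem", "n")
  if (!all(req %in% names(table))) {
    stop("result table must have columns ", paste(req, collapse = ", "))
  }
  if (any(!is.na(table$sem) & table$sem < 0)) stop("sem must be >= 0")
  if (any(is.na(table$n) | table$n < 1)) stop("n must be >= 1")
  out <- data.frame(
    variant = table$variant,
    measurement = table$measurement,
    value = ifelse(is.na(table$value), "NA", sprintf("%.17g", table$value)),
    sem = ifelse(is.na(table$sem), "NA", sprintf("%.17g", table$sem)),
    n = table$n
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(table)
}

#' Read a result table from CSV
#'
#' @param path CSV path as written by [write_result_table()].
#' @return data.frame with columns `variant`, `measurement`, `value`, `sem`,
#'   `n`.
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(variant = "character",
                                 measurement = "character",
                                 value = "numeric", sem = "numeric",
                                 n = "integer"))
}

#' Packaged summary-table fixture of measured cell-surface expression
#'
#' The published per-variant cell-surface expression (CSE) percentages, with
#' background (empty-vector) levels subtracted and scaled to the relevant
#' control (HA-WT alone = 100 for homozygous and total co-expression columns;
#' HA-WT + untagged WT = 100 for the dominant-negative and WT-rescue
#' columns). Measurements:
#' \describe{
#'   \item{homo_cse}{homozygous variant CSE, % of HA-WT.}
#'   \item{homo_e4031_cse}{homozygous CSE after 24 h 5 uM E-4031, % of
#'     untreated HA-WT.}
#'   \item{total_coexpr_cse}{total CSE when HA-WT and HA-variant are
#'     co-expressed, % of HA-WT alone.}
#'   \item{wt_residual_cse}{residual HA-WT CSE on co-expression with
#'     untagged variant, % of HA-WT + un-WT.}
#'   \item{wt_rescue_cse}{HA-variant CSE on co-expression with untagged WT,
#'     % of HA-WT + un-WT.}
#'   \item{mave_cse}{homozygous CSE in the published multiplexed
#'     variant-effect (MAVE) screen, % of WT; absent where the screen has no
#'     data.}
#' }
#' These numbers are a packaged fixture (the raw plate fluorescence behind
#' them is not publicly deposited), used downstream for rescue metrics,
#' regression and thermodynamic estimates.
#'
#' @param format `"wide"` (default; one row per variant, one column per
#'   measurement, `<measurement>_sem` columns alongside) or `"long"` (the raw
#'   result-table records).
#' @return data.frame.
#' @export
#' @examples
#' t1 <- herg_table1()
#' t1[t1$variant == "N470D", c("homo_cse", "homo_e4031_cse")]
herg_table1 <- function(format = c("wide", "long")) {
  format <- match.arg(format)
  path <- system.file("extdata", "table1.csv", package = "hergtraffick",
                      mustWork = TRUE)
  long <- read_result_table(path)
  if (format == "long") return(long)
  variants <- unique(long$variant)
  meas <- c("homo_cse", "homo_e4031_cse", "total_coexpr_cse",
            "wt_residual_cse", "wt_rescue_cse", "mave_cse")
  wide <- data.frame(variant = variants, stringsAsFactors = FALSE)
  for (m in meas) {
    sub <- long[long$measurement == m, ]
    wide[[m]] <- sub$value[match(variants, sub$variant)]
    wide[[paste0(m, "_sem")]] <- sub$sem[match(variants, sub$variant)]
  }
  wide
}
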
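#' Run the full analysis pipeline from a configuration
#'
#' Wires the stages end to end: simulate the four experiment designs
#' (On-Cell and In-Cell, `n_repeats` independent repeats each) ->
#' normalize-by-sum -> condition summaries -> rescue table ->
#' rescue-vs-rescue regression -> thermodynamic table (-> residue tolerance
#' map when a variant-effect table is supplied). All outputs are CSV/JSON
#' under `out_dir`, plus a `manifest.json` recording the package version,
#' seed, configuration hash and the MD5 of every output file, so a run is
#' reproducible and verifiable byte by byte.
#'
#' @param config Either a named list or a path to a JSON file with fields:
#'   `seed` (mandatory), `out_dir` (mandatory), and optionally `n_repeats`
#'   (default 4), `variants`, `t0`, `t1_factor` (assembly world, see
#'   [default_assembly_params()]), `noise` (named list overriding
#'   [noise_params()] defaults), `denominator` and `include_empty`
#'   (normalization options), `regression_exclude` (default WT and L615F),
#'   `thermo` (list with `R`, `temperature`, `c0`), `mave_scores`
#'   (path to a variant-effect CSV `position,ref_aa,alt_aa,score`) and
#'   `structure` (path to a PDB to annotate).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stop("config must set `seed`")
  if (is.null(config$out_dir)) stop("config must set `out_dir`")
  for (f in c("mave_scores", "structure")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("config file reference does not exist: ", config[[f]])
    }
  }
  n_repeats <- config$n_repeats %||% 4L
  variants <- config$variants %||% herg_study_variants()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  files <- character()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  assembly <- stage("assembly", default_assembly_params(
    t0 = config$t0 %||% 0.5, t1_factor = config$t1_factor %||% 1))
  noise_args <- c(list(seed = config$seed), config$noise)
  noise <- stage("noise", do.call(noise_params, noise_args))
  designs <- stage("designs", builtin_designs(variants))

  summaries <- list()
  values_all <- list()
  for (dn in names(designs)) {
    for (at in c("On-Cell", "In-Cell")) {
      plates <- stage(paste0("simulate:", dn),
                      simulate_experiment(designs[[dn]], assembly, noise,
                                          at, n_repeats = n_repeats))
      vals <- stage(paste0("normalize:", dn), do.call(rbind, lapply(
        plates, normalize_plate,
        denominator = config$denominator %||% "raw_ch800",
        include_empty = config$include_empty %||% TRUE)))
      smry <- stage(paste0("summarize:", dn), summarize_conditions(vals))
      tag <- if (at == "On-Cell") "oncell" else "incell"
      vf <- out(sprintf("%s_%s_values.csv", dn, tag))
      sf <- out(sprintf("%s_%s_summary.csv", dn, tag))
      utils::write.csv(vals, vf, row.names = FALSE)
      utils::write.csv(smry, sf, row.names = FALSE)
      files <- c(files, vf, sf)
      if (at == "On-Cell") {
        summaries[[dn]] <- smry
        values_all[[dn]] <- vals
      }
    }
  }

  rescue <- stage("rescue-table",
                  build_rescue_table(summaries, variants = variants))
  rf <- out("rescue_table.csv")
  utils::write.csv(rescue, rf, row.names = FALSE)
  files <- c(files, rf)

  fit <- stage("regress", fit_rescue_regression(
    rescue, exclude = config$regression_exclude %||% c("WT", "L615F")))
  ff <- out("rescue_fit.json")
  jsonlite::write_json(unclass(fit), ff, auto_unbox = TRUE, digits = NA)
  files <- c(files, ff)

  tp <- if (is.null(config$thermo)) thermo_params() else {
    do.call(thermo_params, config$thermo)
  }
  thermo <- stage("thermo", thermo_table(rescue, tp))
  tf <- out("thermo_table.csv")
  utils::write.csv(thermo, tf, row.names = FALSE)
  files <- c(files, tf)

  if (!is.null(config$mave_scores)) {
    scores <- utils::read.csv(config$mave_scores, stringsAsFactors = FALSE)
    cats <- stage("mave-paint", categorize_variants(scores))
    af <- out("residue_categories.tsv")
    pdb_out <- if (!is.null(config$structure)) out("annotated_structure.pdb")
    stage("mave-paint", write_structure_annotation(
      cats, af, structure_path = config$structure, structure_out = pdb_out))
    files <- c(files, af, pdb_out)
  }

  manifest <- list(
    package = "hergtraffick",
    version = as.character(utils::packageVersion("hergtraffick")),
    seed = config$seed,
    n_repeats = n_repeats,
    config_hash = digest_config(config),
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

# Stable hash of the scientific configuration (serialize to canonical JSON,
# then MD5). The output directory is bookkeeping, not configuration.
digest_config <- function(config) {
  config$out_dir <- NULL
  config <- config[order(names(config))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
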
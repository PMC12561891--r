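#' Build a validated pipeline run configuration
#'
#' Collects everything [run_pipeline()] needs: generator settings, the
#' pretreatment grid, the split fraction, the cross-validation scheme and
#' the leakage mode.  Every field is validated here, before any
#' computation.
#'
#' @param seed master integer seed; all randomness in the run flows from
#'   it.
#' @param generator a [generator_config()]; its `seed` is overwritten by
#'   `seed` so one number controls the run.
#' @param codes pretreatment grid (character codes).
#' @param assays which assays to calibrate.
#' @param fraction Set 1 fraction for the Kennard-Stone split.
#' @param cv cross-validation scheme: list with `type` (`"loo"` or
#'   `"kfold"`) and, for k-fold, `k`.
#' @param max_lv maximum latent variables for LV selection.
#' @param paper_mode calibrate on Set 1+2 instead of Set 1 (see
#'   [evaluate_model()]).
#' @param out_dir output directory (created if missing).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       generator = generator_config(seed = seed),
                       codes = default_pretreatment_codes(),
                       assays = c("DPPH", "ABTS", "ORAC"),
                       fraction = 0.7,
                       cv = list(type = "loo"),
                       max_lv = 20,
                       paper_mode = FALSE,
                       out_dir = "olivenir_run") {
  seed <- as.integer(seed)
  if (is.na(seed)) stop_olivenir("seed must be an integer")
  stopifnot(inherits(generator, "generator_config"))
  generator$seed <- seed
  assays <- match.arg(assays, .olivenir_assays, several.ok = TRUE)
  if (!is.character(codes) || length(codes) < 1) {
    stop_olivenir("codes must be a nonempty character vector")
  }
  lapply(codes, parse_pretreatment_code)  # validate early
  if (fraction <= 0 || fraction >= 1) {
    stop_olivenir("fraction must lie strictly between 0 and 1")
  }
  if (!cv$type %in% c("loo", "kfold")) {
    stop_olivenir("cv$type must be 'loo' or 'kfold'")
  }
  if (cv$type == "kfold" && (is.null(cv$k) || cv$k < 2)) {
    stop_olivenir("k-fold cv needs cv$k >= 2")
  }
  structure(list(seed = seed, generator = generator, codes = codes,
                 assays = assays, fraction = fraction, cv = cv,
                 max_lv = as.integer(max_lv),
                 paper_mode = isTRUE(paper_mode),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar generator settings (`n_samples`, `wavenumber_step`, noise
#' levels, ...) may be given under a `generator` key; everything else maps
#' onto the arguments of [run_config()].
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  gen_args <- raw$generator %||% list()
  gen <- do.call(generator_config,
                 c(gen_args, list(seed = raw$seed %||% 1L)))
  args <- raw[setdiff(names(raw), "generator")]
  args$generator <- gen
  if (!is.null(args$codes)) args$codes <- unlist(args$codes)
  if (!is.null(args$assays)) args$assays <- unlist(args$assays)
  do.call(run_config, args)
}

#' Hash a run configuration
#'
#' FNV-1a 32-bit hash of the canonical JSON serialization of a config.
#' [run_pipeline()] stamps it on its outputs so result files can be traced
#' back to the exact configuration that produced them.
#'
#' @param config a [run_config()].
#' @return An 8-character lowercase hex string.
#' @export
config_hash <- function(config) {
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  txt <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  bytes <- utf8ToInt(as.character(txt))
  hash <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- hash %% 65536
    hi <- hash %/% 65536
    lo <- bitwXor(as.integer(lo), as.integer(b %% 256))
    # (hi*2^16 + lo) * prime mod 2^32
    hash <- ((hi * prime) %% 65536) * 65536 + lo * prime
    hash <- hash %% 4294967296
  }
  sprintf("%04x%04x", as.integer(hash %/% 65536), as.integer(hash %% 65536))
}

#' Run the full calibration pipeline
#'
#' Orchestrates a complete run on synthetic data: generates profiles,
#' reference values and spectra; performs the Kennard-Stone split (on the
#' spectra pretreated with the first grid code); grid-searches the
#' pretreatments per assay; writes the evaluation tables, the best model
#' per assay, the compound/assay correlation table and a structured log.
#' Re-running with an identical config reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`profiles`,
#'   `references`, `spectra`, `split`, `grids`, `correlations`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log <- list(config_hash = hash, seed = config$seed,
              package_version = as.character(utils::packageVersion("olivenir")),
              seeds_consumed = list(
                profiles = config$seed,
                references = config$seed + 1000L +
                  seq_along(config$assays),
                spectra = config$seed + 2000L),
              stages = character())
  note <- function(stage) log$stages <<- c(log$stages, stage)
  files <- character()
  emit <- function(name) {
    files[[name]] <<- file.path(out, name)
    files[[name]]
  }

  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop_olivenir("pipeline stage '", name, "' failed: ",
                    conditionMessage(e))
    })
  }

  profiles <- stage("simulate_profiles", function()
    generate_profiles(config$generator))
  write_profiles_csv(profiles, emit("profiles.csv"))
  note("simulate_profiles")

  references <- stage("simulate_references", function() {
    refs <- lapply(config$assays, generate_reference_values,
                   profiles = profiles, config = config$generator)
    names(refs) <- config$assays
    refs
  })
  for (assay in config$assays) {
    write_reference_csv(references[[assay]],
                        emit(paste0("reference_", assay, ".csv")))
  }
  note("simulate_references")

  spectra <- stage("simulate_spectra", function()
    generate_spectra(profiles, config$generator))
  write_spectra_csv(spectra, emit("spectra.csv"))
  note("simulate_spectra")

  split <- stage("split", function()
    split_sets(apply_pretreatment(spectra, config$codes[[1]]),
               config$fraction))
  write_split_csv(split, emit("split.csv"))
  note("split")

  scheme <- if (config$cv$type == "loo") cv_loo()
            else cv_kfold(config$cv$k, seed = config$seed)
  grids <- list()
  for (assay in config$assays) {
    g <- stage(paste0("evaluate_", assay), function()
      grid_search(spectra, references[[assay]], codes = config$codes,
                  split = split, cv_scheme = scheme,
                  max_lv = config$max_lv,
                  paper_mode = config$paper_mode))
    grids[[assay]] <- g
    tab <- report_table(g)
    tab$config_hash <- hash
    data.table::fwrite(tab, emit(paste0("evaluation_", assay, ".csv")))
    best <- g$reports[[1]]
    write_report_json(best, emit(paste0("best_report_", assay, ".json")))
    write_pls_model(best$model, emit(paste0("best_model_", assay, ".json")))
    note(paste0("evaluate_", assay))
  }

  correlations <- stage("correlate", function()
    correlation_table(profiles, references))
  write_correlation_csv(correlations, emit("correlations.csv"))
  note("correlate")

  log$files <- as.list(files)
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(profiles = profiles, references = references,
                 spectra = spectra, split = split, grids = grids,
                 correlations = correlations, files = files,
                 config_hash = hash))
}
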
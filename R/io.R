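#' Read integrated injection heats from CSV
#'
#' Expects a plain CSV with columns `injection`, `volume_uL` and `heat`
#' (other columns are ignored with a warning; alternative column names can
#' be supplied through `col_map`). Heats are converted to the internal
#' calorie scale according to `units`; volumes are converted from uL to L.
#'
#' @param path Path to the CSV file.
#' @param units Unit of the `heat` column: `"cal"` or `"ucal"`.
#' @param col_map Named character vector mapping the expected names to the
#'   file's column names, e.g. `c(heat = "Q_ucal")`.
#' @return Tibble: `injection`, `volume` (L), `heat` (cal).
#' @export
read_heats <- function(path, units = c("cal", "ucal"), col_map = NULL) {
  units <- match.arg(units)
  if (!file.exists(path))
    abort(paste0("File not found: ", path), class = "itcbayes_format_error")
  df <- utils::read.csv(path, comment.char = "#")
  expected <- c(injection = "injection", volume_uL = "volume_uL",
                heat = "heat")
  if (!is.null(col_map)) expected[names(col_map)] <- col_map
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0)
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "itcbayes_format_error")
  extra <- setdiff(names(df), expected)
  if (length(extra) > 0)
    warn(paste0("Ignoring unknown column(s): ",
                paste(extra, collapse = ", ")))
  scale <- if (units == "ucal") 1e-6 else 1
  tibble(
    injection = as.integer(df[[expected[["injection"]]]]),
    volume = as.numeric(df[[expected[["volume_uL"]]]]) * 1e-6,
    heat = as.numeric(df[[expected[["heat"]]]]) * scale
  )
}

#' Read an experiment design from YAML or JSON
#'
#' Required fields: `cell_volume_mL`, `injection_volumes_uL` (a list or,
#' alternatively, `first_injection_uL` + `main_injection_uL` +
#' `n_injections`), `temperature_K`, `stated_R0_mM`, `stated_Ls_mM`.
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` file.
#' @return An [itc_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path))
    abort(paste0("File not found: ", path), class = "itcbayes_format_error")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  need <- function(field) {
    if (is.null(cfg[[field]]))
      abort(paste0("Missing required design field: ", field),
            class = "itcbayes_format_error")
    cfg[[field]]
  }
  vols <- if (!is.null(cfg$injection_volumes_uL)) {
    as.numeric(unlist(cfg$injection_volumes_uL))
  } else {
    c(as.numeric(need("first_injection_uL")),
      rep(as.numeric(need("main_injection_uL")),
          as.integer(need("n_injections")) - 1))
  }
  itc_design(
    cell_volume = as.numeric(need("cell_volume_mL")) * 1e-3,
    injection_volumes = vols * 1e-6,
    temperature = as.numeric(need("temperature_K")),
    stated_R0 = as.numeric(need("stated_R0_mM")) * 1e-3,
    stated_Ls = as.numeric(need("stated_Ls_mM")) * 1e-3
  )
}

#' Read a full experiment bundle
#'
#' Combines a heats CSV and a design into a single experiment object,
#' checking that the number of heats matches the design's injection count
#' (and, when both state per-injection volumes, that they agree).
#'
#' @param path Path to the heats CSV.
#' @param design An [itc_design()] or a path to a design YAML/JSON.
#' @param units Heat units in the file (`"cal"` or `"ucal"`).
#' @param id Experiment identifier (defaults to the file name).
#' @return Object of class `itc_experiment`: list with `id`, `design`,
#'   `data`, `provenance`.
#' @export
read_experiment <- function(path, design, units = c("cal", "ucal"),
                            id = NULL) {
  units <- match.arg(units)
  if (is.character(design)) design <- read_design(design)
  data <- read_heats(path, units = units)
  n <- length(design$injection_volumes)
  if (nrow(data) != n)
    abort(sprintf("File has %d heats but the design has %d injections.",
                  nrow(data), n),
          class = "itcbayes_format_error")
  if (any(abs(data$volume - design$injection_volumes) >
          1e-9 * design$injection_volumes + 1e-15))
    warn("Injection volumes in the file differ from the design; using the design's.")
  data$volume <- design$injection_volumes
  structure(
    list(id = if (is.null(id)) basename(path) else id,
         design = design, data = data,
         provenance = list(source = path, units = units)),
    class = "itc_experiment"
  )
}

pkg_version <- function() {
  as.character(utils::packageVersion("itcbayes"))
}

write_csv_with_header <- function(df, path, meta) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# itcbayes %s", pkg_version()), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  df <- as.data.frame(df)
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) format(col, digits = 17, trim = TRUE) else col
  })
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Write posterior samples to CSV
#'
#' One row per stored draw, full precision, with provenance (package
#' version, seed, prior model, thinning) recorded in `#` header comments
#' so that a trace can be reproduced. [read_samples()] round-trips the
#' values exactly.
#'
#' @param fit An `itc_bayes_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(fit, path) {
  if (nrow(fit$samples) == 0)
    abort("No samples to write.", class = "itcbayes_invalid_input")
  write_csv_with_header(
    fit$samples[, c(state_names, "lp")], path,
    meta = list(seed = if (is.null(fit$seed)) "NA" else fit$seed,
                prior_model = fit$prior$model,
                n_samples = nrow(fit$samples),
                thin = fit$sampler$thin)
  )
  invisible(path)
}

#' Read posterior samples written by [write_samples()]
#'
#' @param path Path to the trace CSV.
#' @return Tibble of draws with attribute `meta` (named list parsed from
#'   the header comments).
#' @export
read_samples <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^# ([^:]+): (.*)$", h))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  out <- as_tibble(df)
  attr(out, "meta") <- meta
  out
}

#' Write a posterior or fit summary to CSV
#'
#' One row per parameter and level, with provenance header comments.
#'
#' @param summary A data frame, e.g. from [posterior_summary()].
#' @param path Output path.
#' @param meta Named list of provenance fields for the header (seed,
#'   prior model, ...).
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, meta = list()) {
  if (!is.data.frame(summary) || nrow(summary) == 0)
    abort("Nothing to write.", class = "itcbayes_invalid_input")
  write_csv_with_header(summary, path, meta = meta)
  invisible(path)
}

#' Write a simulated study to disk
#'
#' One CSV per replicate (columns `injection`, `volume_uL`, `heat`, in the
#' requested units) plus a JSON manifest recording the seed, the
#' simulation settings and each replicate's true parameters.
#'
#' @param study Tibble from [generate_study()].
#' @param dir Output directory (created if needed).
#' @param spec The [simulation_spec()] used.
#' @param seed The seed used, recorded in the manifest.
#' @param units Heat units for the CSV files.
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir, spec, seed = NULL,
                        units = c("ucal", "cal")) {
  units <- match.arg(units)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- if (units == "ucal") 1e6 else 1
  files <- character(nrow(study))
  for (i in seq_len(nrow(study))) {
    d <- study$data[[i]]
    files[i] <- file.path(dir, sprintf("replicate_%03d.csv", i))
    write_csv_with_header(
      tibble(injection = d$injection, volume_uL = d$volume * 1e6,
             heat = d$heat * scale),
      files[i],
      meta = list(replicate = i, heat_units = units)
    )
  }
  manifest <- list(
    package_version = pkg_version(),
    seed = seed,
    heat_units = units,
    spec = unclass(spec),
    replicates = purrr::map(seq_len(nrow(study)), function(i) {
      list(file = basename(files[i]),
           truth = as.list(unclass(study$truth[[i]])))
    })
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
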
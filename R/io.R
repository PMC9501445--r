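# Plain-text dataset and parameter-file I/O.  Files use degC, mM/uM and
# the observable's natural units; everything is converted to internal
# units (K, mol/L, kcal) on read.

DATASET_SCHEMAS <- list(
  CD = c("temperature_C", "ellipticity"),
  DSC = c("temperature_C", "cp_kcal_mol_K"),
  ITC = c("injection_index", "volume_uL", "heat_kcal_per_mol_DNA"))

#' Read a measurement dataset from CSV
#'
#' Schemas (header row required): CD `temperature_C, ellipticity`; DSC
#' `temperature_C, cp_kcal_mol_K`; ITC `injection_index, volume_uL,
#' heat_kcal_per_mol_DNA`; SPECTRA has `wavelength_nm` first and one
#' column per temperature named by its value in degC.  Temperatures must
#' be strictly increasing for CD and DSC.
#'
#' @param path CSV file path.
#' @param kind `"CD"`, `"DSC"`, `"ITC"` or `"SPECTRA"`.
#' @param conditions named list of condition values not carried by the
#'   file (e.g. `cK` in mol/L, `cDNA`; for ITC: `tempC`, `cK`,
#'   `cellVolume`, `syringeDNA`, `cellLigand`).
#' @return An [experiment_dataset()].
#' @export
read_dataset <- function(path, kind, conditions = list()) {
  kind <- match.arg(kind, c("CD", "DSC", "ITC", "SPECTRA"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (kind == "SPECTRA") {
    if (names(df)[1] != "wavelength_nm") {
      stop("spectra CSV must have first column 'wavelength_nm'", call. = FALSE)
    }
    tempC <- as.numeric(names(df)[-1])
    if (anyNA(tempC)) stop("spectra CSV column names after the first must be temperatures in degC",
                           call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    dimnames(m) <- list(df$wavelength_nm, tempC)
    return(experiment_dataset("SPECTRA", m,
                              conditions = utils::modifyList(
                                list(tempC = tempC,
                                     wavelengths = df$wavelength_nm),
                                conditions)))
  }
  want <- DATASET_SCHEMAS[[kind]]
  missing_cols <- setdiff(want, names(df))
  extra <- setdiff(names(df), want)
  if (length(missing_cols) || length(extra)) {
    stop(sprintf("%s CSV schema mismatch: missing [%s], unexpected [%s]",
                 kind, paste(missing_cols, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  df <- df[, want]
  df[] <- lapply(df, as.double)
  if (kind %in% c("CD", "DSC")) {
    bad <- which(diff(df$temperature_C) <= 0)
    if (length(bad)) {
      stop(sprintf("temperatures must be strictly increasing; first offending row: %d",
                   bad[1] + 1L), call. = FALSE)
    }
  }
  if (kind == "ITC") {
    proto <- itc_protocol(
      tempC = conditions$tempC %||% 25,
      cK = conditions$cK %||% 0.1,
      cellVolume = conditions$cellVolume %||% 1.4e-3,
      syringeDNA = conditions$syringeDNA %||% 70e-6,
      cellLigand = conditions$cellLigand %||% 10e-6,
      injectionVolumes = df$volume_uL * 1e-6)
    conditions <- list(protocol = proto)
  }
  experiment_dataset(kind, df, conditions = conditions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a measurement dataset to CSV
#'
#' Inverse of [read_dataset()]: numeric columns round-trip to identical
#' double values.
#'
#' @param ds an [experiment_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  fmt <- function(x) {
    if (!is.numeric(x)) return(as.character(x))
    vapply(x, function(v) formatC(v, digits = 17, format = "g"), character(1))
  }
  if (ds$kind == "SPECTRA") {
    m <- ds$data
    df <- data.frame(wavelength_nm = fmt(as.numeric(rownames(m))),
                     check.names = FALSE)
    for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt(m[, j])
  } else {
    df <- as.data.frame(lapply(ds$data, fmt), check.names = FALSE)
    names(df) <- names(ds$data)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write model parameter files
#'
#' YAML files with a `reference` block (`T0_C`, `cref_mM`), a
#' `transitions` block (keys `U->I` and `I->Q` with `dG0`, `dH0`, `dCp`,
#' `n`) and a `sites` block (`site1`, `site2` with `dG0`, `dH0`, `dCp`).
#' Numbers are serialized at 17 significant digits so that a write/read
#' cycle reproduces bit-identical doubles.
#'
#' @param path parameter file path.
#' @return For `read_parameters`, a [system_model()].
#' @export
read_parameters <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("reference", "transitions", "sites")
  missing_blocks <- setdiff(need, names(y))
  if (length(missing_blocks)) {
    stop("parameter file missing blocks: ",
         paste(missing_blocks, collapse = ", "), call. = FALSE)
  }
  ref <- ref_conditions(T0 = celsius_to_kelvin(y$reference$T0_C),
                        cref = mM_to_M(y$reference$cref_mM))
  tr <- lapply(c("U->I", "I->Q"), function(nm) {
    b <- y$transitions[[nm]]
    if (is.null(b)) stop("parameter file missing transition '", nm, "'",
                         call. = FALSE)
    transition_thermo(nm, b$dG0, b$dH0, b$dCp, b$n)
  })
  st <- lapply(1:2, function(k) {
    b <- y$sites[[paste0("site", k)]]
    if (is.null(b)) stop("parameter file missing site", k, call. = FALSE)
    site_thermo(k, b$dG0, b$dH0, b$dCp)
  })
  system_model(tr, st, ref)
}

#' @rdname read_parameters
#' @param model a [system_model()].
#' @export
write_parameters <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  tr <- function(t) {
    # "n" must be quoted: bare n is a YAML 1.1 boolean
    sprintf("  \"%s\": {dG0: %s, dH0: %s, dCp: %s, \"n\": %s}",
            t$name, num(t$dG0), num(t$dH0), num(t$dCp), num(t$n))
  }
  st <- function(s) {
    sprintf("  site%d: {dG0: %s, dH0: %s, dCp: %s}",
            s$site, num(s$dG0), num(s$dH0), num(s$dCp))
  }
  lines <- c(
    "reference:",
    sprintf("  T0_C: %s", num(kelvin_to_celsius(model$ref$T0))),
    sprintf("  cref_mM: %s", num(model$ref$cref * 1e3)),
    "transitions:",
    vapply(model$transitions, tr, character(1)),
    "sites:",
    vapply(model$sites, st, character(1)))
  writeLines(lines, path)
  invisible(path)
}
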
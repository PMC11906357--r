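# Shared configuration and table I/O.

#' Load a simulation configuration file
#'
#' Flat key/value YAML mirroring [simParams()] plus run settings. Unknown
#' keys, missing required types and type mismatches raise errors naming the
#' key; every consumed value is echoed with `message()` when `verbose`.
#' Overrides (e.g. from command-line flags) replace file values.
#'
#' Recognized keys: `j_medium_epi`, `j_medium_pre`, `j_epi_epi`,
#' `j_pre_pre`, `j_epi_pre`, `j_medium_ecm`, `j_epi_ecm`, `j_pre_ecm`,
#' `kappa`, `alpha_medium`, `alpha_epi`, `alpha_pre`, `alpha_ecm`,
#' `phi_epi_ecm`, `phi_pre_ecm`, `epsilon`, `kt`, `dt`, `growth_rate`,
#' `division_volumes`, `seed`, `duration_min`, `record_every_min`,
#' `n_cells`, `pre_fraction`, `radius_um`, `mean_cell_volume`.
#'
#' @param path YAML file (empty file = all defaults), or `NULL` for pure
#'   defaults.
#' @param overrides named list of key overrides.
#' @param verbose echo consumed values.
#' @return list with `params` (a [SimParams]) and `run` (list of run
#'   settings).
#' @examples
#' cfg <- loadConfig(system.file("extdata", "example-config.yaml",
#'                               package = "icmDynamics"))
#' cfg$params@dt
#' @export
loadConfig <- function(path = NULL, overrides = list(), verbose = FALSE) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]

  base <- simParams()
  defaults <- list(
    j_medium_epi = base@J["MEDIUM", "EPI"],
    j_medium_pre = base@J["MEDIUM", "PRE"],
    j_epi_epi = base@J["EPI", "EPI"], j_pre_pre = base@J["PRE", "PRE"],
    j_epi_pre = base@J["EPI", "PRE"],
    j_medium_ecm = base@J["MEDIUM", "ECM"],
    j_epi_ecm = base@J["EPI", "ECM"], j_pre_ecm = base@J["PRE", "ECM"],
    kappa = base@kappa,
    alpha_medium = base@alpha[["MEDIUM"]], alpha_epi = base@alpha[["EPI"]],
    alpha_pre = base@alpha[["PRE"]], alpha_ecm = base@alpha[["ECM"]],
    phi_epi_ecm = base@phi["EPI", "ECM"],
    phi_pre_ecm = base@phi["PRE", "ECM"],
    epsilon = base@epsilon, kt = base@kT, dt = base@dt,
    growth_rate = base@growthRate,
    division_volumes = base@divisionVolumes,
    seed = base@seed,
    duration_min = 480, record_every_min = 30,
    n_cells = 30L, pre_fraction = 0.6, radius_um = NA_real_,
    mean_cell_volume = 1000)

  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (!is.numeric(cfg[[k]]))
      stop("config key '", k, "' must be numeric, got ", class(cfg[[k]])[1])
    defaults[[k]] <- cfg[[k]]
  }
  if (verbose)
    for (k in names(defaults))
      message(sprintf("config %s = %s", k,
                      paste(defaults[[k]], collapse = ", ")))

  params <- simParams(
    J = .symmetricJ(defaults$j_medium_epi, defaults$j_medium_pre,
                    defaults$j_epi_epi, defaults$j_pre_pre,
                    defaults$j_epi_pre, defaults$j_medium_ecm,
                    defaults$j_epi_ecm, defaults$j_pre_ecm),
    kappa = defaults$kappa,
    alpha = c(MEDIUM = defaults$alpha_medium, EPI = defaults$alpha_epi,
              PRE = defaults$alpha_pre, ECM = defaults$alpha_ecm),
    phiEpiEcm = defaults$phi_epi_ecm, phiPreEcm = defaults$phi_pre_ecm,
    epsilon = defaults$epsilon, kT = defaults$kt, dt = defaults$dt,
    growthRate = defaults$growth_rate,
    divisionVolumes = defaults$division_volumes,
    seed = defaults$seed)
  run <- defaults[c("duration_min", "record_every_min", "n_cells",
                    "pre_fraction", "radius_um", "mean_cell_volume",
                    "seed")]
  list(params = params, run = run)
}

#' Read / write CSV tables with schema checks
#'
#' CSV is the interchange format of every stage. Writing uses a
#' round-trip-safe decimal representation (shortest representation that
#' parses back to the identical double), so `readTable(writeTable(x))`
#' returns value-identical records.
#'
#' @param df records to write.
#' @param path file path.
#' @param required column names that must be present on read; a missing
#'   column raises an error naming it.
#' @return [readTable()]: a `data.frame`; [writeTable()]: `path`,
#'   invisibly.
#' @export
writeTable <- function(df, path) {
  # %.17g is a representation guaranteed to round-trip doubles exactly
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) {
    v <- sprintf("%.17g", df[[j]])
    v[is.na(df[[j]])] <- NA_character_
    df[[j]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path, required = character(0)) {
  df <- utils::read.csv(path, header = TRUE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  df
}
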
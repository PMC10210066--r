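# Configuration and tabular I/O.  Analyses are driven from R, so the
# "interface" is a validated config structure plus strict CSV readers for
# the two dialects the assays produce (kinetics and titrations).

run_config_keys <- list(
  top = c("constants_set", "receptor", "ligands", "total_metal",
          "estimators", "output", "seed", "verbosity"),
  receptor = c("site_kds", "total_conc", "label"),
  ligand = c("label", "stoich", "kd", "total_conc")
)

#' Load and validate a run configuration
#'
#' Reads a YAML file describing a competition system (receptor, ligands,
#' total metal), the constant set to use, estimator choices and run
#' metadata.  Unknown keys are rejected with their full path; negative
#' concentrations and unknown constant-set names are schema errors.  The
#' returned object carries the resolved system and a content digest of the
#' file for reproducibility.
#'
#' @param path Path to a YAML configuration file.
#' @return Object of class `run_config`: a list with the validated fields,
#'   a built `system` ([zn_system()]) and `digest`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) zc_stop(paste("config file not found:", path),
                                  type = "config")
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), run_config_keys$top)
  if (length(bad))
    zc_stop(paste("unknown config keys:", paste(bad, collapse = ", ")),
            type = "config")
  set_name <- cfg$constants_set %||% "mt2_ref32"
  kds <- mt_constants(set_name)   # errors with available sets if unknown
  rec_cfg <- cfg$receptor %||% list()
  bad <- setdiff(names(rec_cfg), run_config_keys$receptor)
  if (length(bad))
    zc_stop(paste("unknown keys under receptor:",
                  paste(bad, collapse = ", ")), type = "config")
  if (!is.null(rec_cfg$site_kds)) kds <- as.numeric(rec_cfg$site_kds)
  rec_total <- rec_cfg$total_conc %||% 1.7e-6
  if (!is.numeric(rec_total) || rec_total < 0)
    zc_stop("receptor.total_conc must be a non-negative number",
            type = "config")
  receptor <- multisite_receptor(kds, rec_total,
                                 rec_cfg$label %||% set_name)
  ligands <- lapply(seq_along(cfg$ligands), function(i) {
    lc <- cfg$ligands[[i]]
    bad <- setdiff(names(lc), run_config_keys$ligand)
    if (length(bad))
      zc_stop(sprintf("unknown keys under ligands[%d]: %s", i,
                      paste(bad, collapse = ", ")), type = "config")
    if (is.null(lc$kd) || is.null(lc$total_conc))
      zc_stop(sprintf("ligands[%d] needs `kd` and `total_conc`", i),
              type = "config")
    if (lc$total_conc < 0)
      zc_stop(sprintf("ligands[%d].total_conc must be >= 0", i),
              type = "config")
    competitor_ligand(lc$kd, lc$total_conc, lc$stoich %||% 1,
                      lc$label %||% sprintf("ligand%d", i))
  })
  total_metal <- cfg$total_metal %||%
    (length(kds) * receptor$total_conc)
  if (!is.numeric(total_metal) || total_metal < 0)
    zc_stop("total_metal must be a non-negative number", type = "config")
  estimators <- cfg$estimators %||% "stepwise"
  known <- c("stepwise", "cooperative", "ci_based", "grid_matched")
  if (!all(estimators %in% known))
    zc_stop(paste("unknown estimator(s):",
                  paste(setdiff(estimators, known), collapse = ", ")),
            type = "config")
  structure(list(constants_set = set_name,
                 system = zn_system(receptor, ligands, total_metal),
                 estimators = estimators,
                 output = cfg$output %||% ".",
                 seed = cfg$seed %||% NA_integer_,
                 verbosity = cfg$verbosity %||% 0L,
                 digest = unname(tools::md5sum(path))),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> constants: %s, estimators: %s, digest: %s\n",
              x$constants_set, paste(x$estimators, collapse = "/"),
              substr(x$digest, 1, 8)))
  print(x$system)
  invisible(x)
}

csv_dialects <- list(
  kinetics = c("time_s", "signal_au"),
  titration = c("conc_M", "signal"),
  fluorescence = c("probe_conc_M", "f", "fmin", "fmax")
)

#' Read an assay CSV with column and type validation
#'
#' @param path CSV path (header row, dot decimal separator, UTF-8).
#' @param dialect One of `"kinetics"` (`time_s`, `signal_au`),
#'   `"titration"` (`conc_M`, `signal`) or `"fluorescence"`
#'   (`probe_conc_M`, `f`, `fmin`, `fmax`).  Extra columns are preserved.
#' @return A data frame; parse failures report the offending row.
#' @export
read_titration_csv <- function(path, dialect = c("titration", "kinetics",
                                                 "fluorescence")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) zc_stop(paste("file not found:", path),
                                  type = "config")
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) zc_stop(paste("cannot parse CSV:",
                                                    conditionMessage(e)),
                                              type = "config"))
  if (nrow(tab) == 0) zc_stop("empty file", type = "config")
  need <- csv_dialects[[dialect]]
  missing <- setdiff(need, names(tab))
  if (length(missing))
    zc_stop(paste("missing column(s):", paste(missing, collapse = ", ")),
            type = "config")
  for (col in need) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      zc_stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                      col, bad[1], tab[[col]][bad[1]]), type = "config")
    tab[[col]] <- v
  }
  tab
}

#' Write an assay table as CSV in the package dialects
#'
#' @param tab Data frame to write.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
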
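# File formats and configuration: the risk-record CSV schema and the YAML
# run configuration.

#' Read a risk-record CSV
#'
#' Required columns: `patient_id`, `p_hat`, `outcome`. Optional columns
#' (`sample`, `admit_date`, `gender`, `race`, `ethnicity`, `payor`,
#' `facility`, `service_line`, `threshold`, ...) are preserved; unknown
#' columns pass through untouched. `p_hat` must parse as a decimal in
#' `[0, 1]` (boundary values are eps-clipped into the open interval);
#' `outcome` must be 0/1. Violations are reported with their row number.
#'
#' @param path CSV file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param eps Clipping bound applied to boundary probabilities.
#' @param quiet Suppress the row-count message.
#' @return Data frame of typed risk records.
#' @export
read_risk_records <- function(path, delim = ",", eps = 1e-6, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("patient_id", "p_hat", "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  p <- suppressWarnings(as.numeric(df$p_hat))
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad))
    stop("unparseable or out-of-range p_hat at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  df$p_hat <- pmin(pmax(p, eps), 1 - eps)
  o <- suppressWarnings(as.numeric(df$outcome))
  bad <- which(is.na(o) | !(o %in% c(0, 1)))
  if (length(bad))
    stop("outcome not 0/1 at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  df$outcome <- as.integer(o)
  if ("admit_date" %in% names(df)) df$admit_date <- as.Date(df$admit_date)
  if ("threshold" %in% names(df)) {
    th <- suppressWarnings(as.numeric(df$threshold))
    bad <- which(!is.na(df$threshold) & (is.na(th) | th <= 0 | th >= 1))
    if (length(bad))
      stop("threshold outside (0, 1) at row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    df$threshold <- th
  }
  if (!quiet) message("read ", nrow(df), " risk records from ", path)
  df
}

#' Write risk records to CSV
#'
#' RFC-4180-style quoting; round-trips through [read_risk_records()].
#'
#' @param records Risk-record data frame.
#' @param path Output CSV path.
#' @export
write_risk_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Defaults for the run configuration; all resolvable without a config file.
default_run_config <- function() {
  list(seed = 1L, bootstrap_reps = 100L, span = 0.75, degree = 1L,
       boundary_date = "2022-12-31",
       subgroups = c("gender", "race", "payor", "hospital_type"),
       pairs = list(c("White", "Black"), c("Female", "Male")),
       methods = c("none", "ritl", "logistic"),
       alpha = 0.05, fixed_threshold = NULL, min_cell = 50L,
       n = 50000L, threshold = NULL)
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to the package
#' defaults, so an empty (or absent) file is a valid configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}
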
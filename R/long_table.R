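#' Long-format repeated-measures table
#'
#' One row per blood draw: a patient identifier, the administered dosage,
#' the measured steady-state trough response, and the patient's covariate
#' values.  Separating inter- from intra-patient variability requires
#' repeated measures, so a valid table has at least two patients and at
#' least one patient with two or more rows.
#'
#' @param patient_id Vector of patient labels (coerced to character).
#' @param dose,response Strictly positive numeric vectors.
#' @param covariates Optional data frame / matrix of numeric covariates,
#'   one row per observation.  Each patient's covariate values must be
#'   constant across that patient's rows (time-varying covariates are
#'   rejected).
#' @param validate Run invariant checks (default `TRUE`).
#' @return A `data.frame` of class `long_table` with columns
#'   `patient_id`, `dose`, `response`, then covariates.
#' @seealso [read_long_table()], [generate_long_table()]
#' @export
long_table <- function(patient_id, dose, response, covariates = NULL,
                       validate = TRUE) {
  df <- data.frame(patient_id = as.character(patient_id),
                   dose = as.numeric(dose),
                   response = as.numeric(response),
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(df))
      stop("covariates must have one row per observation")
    df <- cbind(df, covariates)
  }
  class(df) <- c("long_table", "data.frame")
  if (validate) validate_long_table(df)
  df
}

#' Validate a long-format table's invariants
#'
#' @param data A `long_table` or plain data frame with columns
#'   `patient_id`, `dose`, `response` (+ covariates).
#' @param allow_time_varying Permit covariates that vary within a patient.
#'   The default (`FALSE`) enforces the patient-constant contract; the
#'   pharmacogenomic screen relaxes it for the screened column only, so
#'   that observation-level artifacts masquerading as genotype effects can
#'   be detected.
#' @return The validated data, invisibly.
#' @export
validate_long_table <- function(data, allow_time_varying = FALSE) {
  req <- c("patient_id", "dose", "response")
  if (!all(req %in% names(data)))
    stop("long table must have columns patient_id, dose, response")
  if (any(!is.finite(data$dose)) || any(data$dose <= 0))
    stop("all doses must be finite and > 0")
  if (any(!is.finite(data$response)) || any(data$response <= 0))
    stop("all responses must be finite and > 0")
  covs <- setdiff(names(data), req)
  for (cv in covs) {
    if (!is.numeric(data[[cv]]))
      stop("covariate '", cv, "' must be numeric")
    if (any(!is.finite(data[[cv]])))
      stop("covariate '", cv, "' has non-finite values")
    if (!allow_time_varying) {
      rng <- tapply(data[[cv]], data$patient_id,
                    function(z) diff(range(z)))
      if (any(rng > 0))
        stop("covariate '", cv, "' varies within a patient; ",
             "time-varying covariates are not supported")
    }
  }
  if (length(unique(data$patient_id)) < 2L)
    stop("at least 2 patients are required")
  if (max(table(data$patient_id)) < 2L)
    stop("variance components not separable: ",
         "no patient has 2 or more observations")
  invisible(data)
}

#' Read / write a long-format table as CSV
#'
#' The CSV contract: header mandatory; required columns
#' `patient_id,dose,response`; every remaining column is treated as a
#' numeric covariate; decimal point, UTF-8.
#'
#' @param path File path.
#' @param data A `long_table`.
#' @param validate Run [validate_long_table()] after reading.
#' @return `read_long_table` returns a `long_table`; `write_long_table`
#'   returns `path` invisibly.
#' @export
read_long_table <- function(path, validate = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  req <- c("patient_id", "dose", "response")
  if (!all(req %in% names(df)))
    stop("CSV must contain columns patient_id, dose, response")
  df$patient_id <- as.character(df$patient_id)
  df <- df[c(req, setdiff(names(df), req))]
  class(df) <- c("long_table", "data.frame")
  if (validate) validate_long_table(df)
  df
}

#' @rdname read_long_table
#' @export
write_long_table <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

long_table_covariates <- function(data)
  setdiff(names(data), c("patient_id", "dose", "response"))
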
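# Tabular I/O: a single CSV dialect with the empty field as the missing
# sentinel, and JSON for configuration.

parse_tristate <- function(v, col, path) {
  v <- trimws(v)
  bad <- which(!(v %in% c("", "0", "1")))
  if (length(bad)) {
    stop("malformed value '", v[bad[1L]], "' in column '", col, "', row ",
         bad[1L], " of ", path, " (expected 0, 1 or empty)", call. = FALSE)
  }
  out <- suppressWarnings(as.integer(v))
  out
}

#' Read a trial dataset from CSV
#'
#' Expects a header row with at least columns `x`, `z1`, `z2`, `z3`
#' (optionally `y`); fields must be `0`, `1` or empty (the missing
#' sentinel). Any other token is rejected with its row and column.
#'
#' @param path Path to a CSV file.
#' @param required Character vector of required columns.
#' @return A data frame with integer 0/1/`NA` columns.
#' @export
read_trial_csv <- function(path, required = c("x", "z1", "z2", "z3")) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) == 0L) {
    stop("no data rows in ", path, call. = FALSE)
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in names(raw)) raw[[col]] <- parse_tristate(raw[[col]], col, path)
  for (col in intersect(c("x"), names(raw))) {
    if (anyNA(raw[[col]])) {
      stop("column 'x' may not contain missing values (", path, ")",
           call. = FALSE)
    }
  }
  raw
}

#' Write a trial dataset to CSV
#'
#' Missing values are serialized as empty fields, making the write/read
#' round trip lossless.
#'
#' @param data Data frame of 0/1/`NA` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_trial_csv
#' @export
read_daily_csv <- function(path) {
  read_trial_csv(path, required = c("x", day_cols()))
}

config_schemas <- function() {
  num <- function(default = NULL, required = FALSE) {
    list(type = "numeric", default = default, required = required)
  }
  chr <- function(default = NULL, required = FALSE) {
    list(type = "character", default = default, required = required)
  }
  lst <- function(default = NULL, required = FALSE) {
    list(type = "list", default = default, required = required)
  }
  list(
    simulate = list(
      n = num(2000), p_x = num(0.5), case = chr("I"),
      definition = chr("simple"), beta0 = num(0.3), beta_x = num(1.35),
      seed = num(required = TRUE)),
    mask = list(
      mechanism = chr(), coefficients = lst(), seed = num(required = TRUE)),
    impute = list(
      method = chr(required = TRUE), M = num(25), burnin = num(20),
      augment = list(type = "logical", default = TRUE, required = FALSE),
      definition = chr("simple"), seed = num(required = TRUE)),
    analyze = list(
      method = chr(required = TRUE), model = chr("logit"),
      conf_level = num(), M = num(25), burnin = num(20),
      definition = chr("simple"), seed = num(required = TRUE)),
    bias_surface = list(
      trt = num(required = TRUE), ctrl = num(required = TRUE),
      independent = list(type = "logical", default = TRUE, required = FALSE),
      alphas = num(required = TRUE)),
    simstudy = list(
      case = chr("I"), mechanism = chr("MCAR"), definition = chr("simple"),
      n_sample = num(2000), n_rep = num(500),
      methods = chr(c("full", "cra", "deriv")), M = num(5), burnin = num(5),
      beta0 = num(0.3), beta_x = num(1.35), seed = num(required = TRUE)),
    topps_demo = list(
      n = num(600), M = num(50), burnin = num(20),
      methods = chr(c("cra", "deriv", "mi_cra", "mi_deriv", "mic_main",
                      "mic_trt_all", "mic_trt_adjacent")),
      seed = num(required = TRUE))
  )
}

#' Validate and resolve a run configuration
#'
#' Checks a raw configuration list (typically parsed from JSON) against the
#' schema of a subcommand: unknown keys and type mismatches are rejected
#' (all violations listed at once), missing optional keys are filled with
#' their documented defaults, and missing required keys are errors. The
#' resolved configuration re-validates idempotently.
#'
#' @param raw A named list.
#' @param command One of `simulate`, `mask`, `impute`, `analyze`,
#'   `bias_surface`, `simstudy`, `topps_demo`.
#' @return The resolved configuration list with attribute `command`.
#' @export
validate_config <- function(raw, command) {
  schemas <- config_schemas()
  command <- gsub("-", "_", command)
  if (!command %in% names(schemas)) {
    stop("unknown subcommand '", command, "'", call. = FALSE)
  }
  schema <- schemas[[command]]
  if (is.null(raw)) raw <- list()
  stopifnot(is.list(raw))
  problems <- character()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  type_ok <- function(value, type) {
    switch(type,
           numeric = is.numeric(value),
           character = is.character(value),
           logical = is.logical(value),
           list = is.list(value))
  }
  resolved <- list()
  for (key in names(schema)) {
    entry <- schema[[key]]
    if (key %in% names(raw)) {
      if (!type_ok(raw[[key]], entry$type)) {
        problems <- c(problems, paste0("key '", key, "' must be ",
                                       entry$type))
      } else {
        resolved[[key]] <- raw[[key]]
      }
    } else if (entry$required) {
      problems <- c(problems, paste0("missing required key '", key, "'"))
    } else if (!is.null(entry$default)) {
      resolved[[key]] <- entry$default
    }
  }
  if (length(problems)) {
    stop("invalid '", command, "' configuration: ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  attr(resolved, "command") <- command
  resolved
}
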
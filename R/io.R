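# Plain-text recording and model I/O. Recordings are two-column delimited
# text (time_s, value) with '#'-prefixed "key: value" metadata headers;
# delimiters are sniffed so externally produced files load too. Models are
# versioned JSON.

MODEL_SCHEMA <- "flowmci-ocsvm/1"

#' Write a recording to delimited text
#'
#' Two columns (`time_s`, `value`) with a comment header carrying sample
#' rate, units, scenario and, for simulated recordings, the full generator
#' configuration as JSON.
#'
#' @param recording A [flow_recording()].
#' @param path Output file path.
#' @param sep Column separator (default tab).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, sep = "\t") {
  stopifnot(inherits(recording, "flow_recording"))
  hdr <- c(sprintf("# sample_rate: %.10g", recording$sample_rate),
           sprintf("# units: %s", recording$units))
  if (!is.null(recording$scenario))
    hdr <- c(hdr, sprintf("# scenario: %s", recording$scenario))
  if (!is.null(recording$config)) {
    cfg <- recording$config
    cfg <- cfg[!vapply(cfg, is.null, TRUE)]
    hdr <- c(hdr, sprintf("# config: %s", jsonlite::toJSON(
      unclass(cfg), auto_unbox = TRUE, digits = NA)))
  }
  hdr <- c(hdr, paste0("# columns: time_s", sep, "value"))
  body <- paste(format(recording$times, digits = 15, trim = TRUE,
                       scientific = FALSE),
                format(recording$values, digits = 15, trim = TRUE),
                sep = sep)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Accepts the format written by [write_recording()] and similar two-column
#' (time, value) or single-column (value only) layouts. `#`-prefixed header
#' lines are parsed for `sample_rate`, `units` and `scenario`; the column
#' delimiter is sniffed among tab, comma, semicolon and whitespace unless
#' given. Malformed rows are reported with their line numbers.
#'
#' @param path Input file.
#' @param sample_rate Sample rate in Hz; required for single-column files
#'   without a header, otherwise taken from the header or the time column.
#' @param sep Column separator, or `NULL` to sniff.
#' @param time_col,value_col 1-based column indices; `time_col = 0` declares
#'   a file with no time column.
#' @return A [flow_recording()].
#' @export
read_recording <- function(path, sample_rate = NULL, sep = NULL,
                           time_col = 1, value_col = 2) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop_input("empty file: %s", path)

  meta <- list()
  is_hdr <- grepl("^\\s*#", lines)
  for (h in lines[is_hdr]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  if (!is.null(meta$sample_rate) && is.null(sample_rate))
    sample_rate <- as.numeric(meta$sample_rate)
  units <- if (!is.null(meta$units)) meta$units else "unknown"
  scenario <- meta$scenario

  data_lines <- lines[!is_hdr & nzchar(trimws(lines))]
  data_nums <- which(!is_hdr & nzchar(trimws(lines)))
  if (length(data_lines) == 0) stop_input("no data rows in %s", path)

  if (is.null(sep)) {
    probe <- data_lines[1]
    sep <- if (grepl("\t", probe)) "\t"
      else if (grepl(",", probe)) ","
      else if (grepl(";", probe)) ";"
      else "[[:space:]]+"
  }
  parts <- strsplit(trimws(data_lines), sep)
  ncols <- lengths(parts)
  single <- all(ncols == 1)
  want <- if (single) 1L else max(time_col, value_col)
  bad <- which(ncols < want)
  vals <- suppressWarnings(lapply(parts, as.numeric))
  nonnum <- which(vapply(vals, anyNA, TRUE))
  bad <- sort(unique(c(bad, nonnum)))
  if (length(bad))
    stop_input("malformed rows in %s at line(s) %s", path,
               paste(utils::head(data_nums[bad], 10), collapse = ", "))

  if (single || time_col == 0) {
    if (is.null(sample_rate))
      stop_input("single-column file needs a declared sample_rate")
    values <- vapply(vals, `[`, 0, if (single) 1L else value_col)
    times <- (seq_along(values) - 1) / sample_rate
  } else {
    times <- vapply(vals, `[`, 0, time_col)
    values <- vapply(vals, `[`, 0, value_col)
  }
  flow_recording(times, values, sample_rate = sample_rate, units = units,
                 scenario = scenario)
}

#' Write a feature matrix to delimited text
#'
#' Columns `Z1`, `Z2` (and `Z3`) with a header carrying the scaler and
#' slicing convention, so downstream tools can reproduce the transform.
#'
#' @param fm A `feature_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  hdr <- c(sprintf("# anchor: %s", fm$anchor),
           sprintf("# heart_rate: %.10g", fm$heart_rate),
           sprintf("# scaler: %s", jsonlite::toJSON(
             fm$scaler, auto_unbox = TRUE, digits = NA)),
           paste0("# columns: ", paste(colnames(fm$Z), collapse = "\t")))
  body <- apply(fm$Z, 1, function(r)
    paste(format(r, digits = 15, trim = TRUE), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path Input file.
#' @return A `feature_matrix`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in lines[is_hdr]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  if (!length(body)) stop_input("no feature rows in %s", path)
  Z <- do.call(rbind, lapply(strsplit(trimws(body), "\t"), as.numeric))
  cols <- if (!is.null(meta$columns))
    strsplit(meta$columns, "\t| +")[[1]] else paste0("Z", seq_len(ncol(Z)))
  colnames(Z) <- cols[seq_len(ncol(Z))]
  scaler <- if (!is.null(meta$scaler)) jsonlite::fromJSON(meta$scaler) else NULL
  structure(
    list(Z = Z, scaler = scaler, n = nrow(Z),
         heart_rate = if (!is.null(meta$heart_rate))
           as.numeric(meta$heart_rate) else NA_real_,
         period = if (!is.null(meta$heart_rate))
           60 / as.numeric(meta$heart_rate) else NA_real_,
         anchor = meta$anchor),
    class = "feature_matrix"
  )
}

#' Save a trained model as versioned JSON
#'
#' Persists support vectors, dual coefficients, bias, hyperparameters, the
#' scaler and slicing convention and the training score, at full floating
#' precision.
#'
#' @param model An `ocsvm_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ocsvm_model"))
  doc <- list(
    schema = MODEL_SCHEMA,
    support_vectors = unname(model$support_vectors),
    alpha = model$alpha, rho = model$rho, gamma = model$gamma, nu = model$nu,
    l = model$l, n_features = model$n_features, tol = model$tol,
    training_score = model$training_score,
    dual_objective = model$dual_objective,
    anchor = model$anchor, scaler = model$scaler
  )
  # digits = I(17): decimal round-trip is bit-exact, so a reloaded model
  # reproduces every prediction identically
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Input file.
#' @return An `ocsvm_model` whose predictions reproduce the saved model's
#'   bit-identically.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    stop_input("cannot parse model file %s: %s", path,
                               conditionMessage(e)))
  if (is.null(doc$schema) || !identical(doc$schema, MODEL_SCHEMA))
    stop_validation("model schema '%s' not supported (expected %s)",
                    if (is.null(doc$schema)) "<missing>" else doc$schema,
                    MODEL_SCHEMA)
  need <- c("support_vectors", "alpha", "rho", "gamma", "nu", "l",
            "n_features")
  miss <- need[!need %in% names(doc)]
  if (length(miss))
    stop_validation("model file missing field(s): %s",
                    paste(miss, collapse = ", "))
  sv <- as.matrix(doc$support_vectors)
  if (ncol(sv) != doc$n_features)
    stop_validation("support vectors have %d columns, header says %d",
                    ncol(sv), doc$n_features)
  structure(
    list(support_vectors = sv, alpha = as.numeric(doc$alpha), rho = doc$rho,
         gamma = doc$gamma, nu = doc$nu, l = doc$l,
         n_features = doc$n_features,
         tol = if (is.null(doc$tol)) 1e-6 else doc$tol,
         training_score = doc$training_score,
         dual_objective = doc$dual_objective,
         anchor = doc$anchor, scaler = doc$scaler),
    class = "ocsvm_model"
  )
}
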
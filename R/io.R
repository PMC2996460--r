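# Trial-log, value-table and run-configuration serialization.
# CSV dialect: comma-separated, header row, UTF-8, no quoting of numerics.
# JSONL mirrors the CSV columns as keys, one record per line.

.LOG_COLS <- c("agent", "block", "environment", "task", "trial", "action",
               "reward", "s1", "f1", "s2", "f2", "p1", "p2")

.validate_log_rows <- function(df, where) {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) stop(sprintf("%s: %s at line %d", where, what, i[1] + 1L),
                        call. = FALSE)
  }
  bad(!df$action %in% c(1, 2), "invalid action (must be 1 or 2)")
  bad(!df$reward %in% c(0, 1), "invalid reward (must be 0 or 1)")
  bad(df$s1 < 0 | df$f1 < 0 | df$s2 < 0 | df$f2 < 0, "negative count")
  bad(!df$environment %in% c("independent", "coupled"),
      "unknown environment type")
  df
}

#' Write a trial log to CSV or JSONL
#'
#' @param log A trial-log data.frame (see [run_agent()]).
#' @param path Output file; the format is taken from the extension
#'   (`.jsonl` for JSON lines, anything else CSV) unless `format` is given.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path, format = NULL) {
  stopifnot(all(.LOG_COLS %in% names(log)))
  format <- format %||% if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  log <- log[, .LOG_COLS]
  if (format == "jsonl") {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(vapply(seq_len(nrow(log)), function(i)
      jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE, digits = NA),
      character(1)), con)
  } else {
    utils::write.csv(log, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a trial log from CSV or JSONL
#'
#' Malformed rows are reported with their line number; counts snapshots are
#' validated against the record sequence (each task's snapshot must equal the
#' running counts of its preceding records).
#'
#' @param path File written by [write_trial_log()].
#' @param format `"csv"` or `"jsonl"`; guessed from the extension if NULL.
#' @param priors Priors used only to replay the snapshot validation.
#' @return A trial-log data.frame (zero rows, with a warning, for an empty
#'   file).
#' @export
read_trial_log <- function(path, format = NULL, priors = bandit_priors()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- format %||% if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  empty <- function() {
    warning("empty trial log: ", path, call. = FALSE)
    df <- as.data.frame(stats::setNames(rep(list(integer(0)),
                                            length(.LOG_COLS)), .LOG_COLS))
    df$environment <- character(0)
    df
  }
  if (file.size(path) == 0) return(empty())
  df <- if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(empty())
    recs <- lapply(seq_along(lines), function(i) {
      r <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop(sprintf(
                      "%s: malformed JSON at line %d (%s)", path, i,
                      conditionMessage(e)), call. = FALSE))
      miss <- setdiff(.LOG_COLS, names(r))
      if (length(miss)) stop(sprintf("%s: missing fields (%s) at line %d",
                                     path, paste(miss, collapse = ", "), i),
                             call. = FALSE)
      as.data.frame(r[.LOG_COLS])
    })
    do.call(rbind, recs)
  } else {
    df <- utils::read.csv(path, fileEncoding = "UTF-8")
    if (nrow(df) == 0) return(empty())
    miss <- setdiff(.LOG_COLS, names(df))
    if (length(miss)) stop(sprintf("%s: missing columns: %s", path,
                                   paste(miss, collapse = ", ")),
                           call. = FALSE)
    df
  }
  df <- .validate_log_rows(df, path)
  .replay_beliefs(df, priors) # errors on inconsistent snapshots
  df
}

#' Write / read a value table (Gittins or structure-policy values) as CSV
#'
#' @param table A data.frame keyed by count tuples (e.g. from
#'   [gittins_table()] or [structure_value_lattice()]).
#' @param path CSV file path.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_value_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_value_table
#' @export
read_value_table <- function(path) {
  utils::read.csv(path)
}

#' Assemble a full run configuration
#'
#' Bundles the experiment design, solver settings, priors, analysis settings
#' and seed into one serializable object; every field has a documented
#' default.
#'
#' @param experiment An [experiment_config()].
#' @param solver A [solver_config()].
#' @param priors A [bandit_priors()].
#' @param analysis List of analysis settings (`n_bins`,
#'   `high_count_threshold`).
#' @param seed Master seed for the run.
#' @param output_dir Where run artifacts are written.
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment = experiment_config(),
                       solver = solver_config(), priors = bandit_priors(),
                       analysis = list(n_bins = 10, high_count_threshold = 8),
                       seed = 1L, output_dir = ".") {
  structure(list(experiment = experiment, solver = solver, priors = priors,
                 analysis = analysis, seed = seed, output_dir = output_dir),
            class = "run_config")
}

#' Write / read a run configuration (YAML or JSON)
#'
#' The format follows the file extension (`.json` for JSON, else YAML).
#' Configurations round-trip losslessly.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `path` invisibly (write); a [run_config()] (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- lapply(unclass(config), function(el)
    if (is.object(el)) unclass(el) else el)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path) else
    yaml::read_yaml(path)
  ex <- x$experiment
  run_config(
    experiment = experiment_config(ex$n_blocks, ex$tasks_per_block,
                                   unlist(ex$block_envs), ex$stop_prob,
                                   ex$fixed_stop_time, ex$seed),
    solver = solver_config(x$solver$gamma, x$solver$horizon,
                           x$solver$index_tolerance,
                           x$solver$gittins_horizon, x$solver$max_states),
    priors = do.call(bandit_priors, x$priors),
    analysis = x$analysis, seed = x$seed, output_dir = x$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
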
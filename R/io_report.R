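# TSV readers/writers for time courses and partitions, run configuration,
# and the plain-text budget report.

TC_COLUMNS <- c("experiment", "tracer", "pool", "day", "replicate",
                "value", "units")

#' Read a pulse-chase time course from TSV
#'
#' Expects the tab-separated schema written by [write_timecourse()]:
#' columns `experiment`, `tracer`, `pool`, `day`, `replicate`, `value`,
#' `units`. Schema violations name the offending row and column.
#'
#' @param path File path.
#' @return A `timecourse` data frame.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop_schema("no such file: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(TC_COLUMNS, names(df))
  if (length(miss)) {
    stop_schema("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  }
  df <- df[, TC_COLUMNS]
  if (nrow(df) == 0L) {
    warning(sprintf("%s: empty data section", path))
    return(new_timecourse(df))
  }
  for (col in c("day", "replicate", "value")) {
    if (!is.numeric(df[[col]])) {
      stop_schema("%s: column '%s' must be numeric", path, col)
    }
  }
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad)) {
    stop_schema("%s: negative or non-finite value at data row %d (column 'value')",
                path, bad[1L])
  }
  key <- paste(df$experiment, df$pool, df$day, df$replicate)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_schema("%s: duplicate (pool, day, replicate) key at data row %d",
                path, dup[1L])
  }
  new_timecourse(df)
}

#' Write a pulse-chase time course as TSV
#'
#' Rows are written in canonical (pool, day, replicate) order so that
#' write-read-write round-trips are byte-identical.
#'
#' @param tc A `timecourse` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  miss <- setdiff(TC_COLUMNS, names(tc))
  if (length(miss)) stop_input("missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(tc)[, TC_COLUMNS]
  df <- df[order(df$pool, df$day, df$replicate), ]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(TC_COLUMNS, collapse = "\t"), con)
  if (nrow(df)) {
    lines <- do.call(paste, c(lapply(df, function(x) {
      if (is.numeric(x)) format(x, digits = 15, trim = TRUE,
                                scientific = FALSE) else as.character(x)
    }), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Render the daily TAG budget as a text table
#'
#' One row per day plus a `Total` row; pathway and total columns side by
#' side, rounded to one decimal (half away from zero) at this reporting
#' layer only.
#'
#' @param p A [assemble_partition()] result.
#' @param digits Decimals for reporting (default 1).
#' @return Character vector of table lines.
#' @export
render_partition_report <- function(p, digits = 1) {
  stopifnot(inherits(p, "pathway_partition"))
  if (anyNA(p$day) || any(diff(p$day) != 1)) {
    full <- seq(min(p$day), max(p$day))
    miss <- setdiff(full, p$day)
    stop_input("partition is missing day(s): %s", paste(miss, collapse = ", "))
  }
  hdr <- c("Day", "Starch", "De novo direct", "De novo via PLs",
           "Total calculated", "Total measured")
  num <- function(x) sprintf(paste0("%.", digits, "f"), report_round(x, digits))
  body <- cbind(as.character(p$day), num(p$from_starch),
                num(p$de_novo_direct), num(p$de_novo_via_pl),
                num(p$total_calculated), num(p$total_measured))
  tot <- attr(p, "totals")
  body <- rbind(body, c("Total", num(tot[["from_starch"]]),
                        num(tot[["de_novo_direct"]]),
                        num(tot[["de_novo_via_pl"]]),
                        num(tot[["total_calculated"]]),
                        num(tot[["total_measured"]])))
  tab <- rbind(hdr, body)
  widths <- apply(nchar(tab), 2, max)
  apply(tab, 1, function(r) {
    paste(mapply(formatC, r, width = widths,
                 flag = c("-", rep("", length(r) - 1))), collapse = "  ")
  })
}

#' Write a pathway partition as TSV
#'
#' @param p A [assemble_partition()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "pathway_partition"))
  utils::write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

CONFIG_KEYS <- c("conversion", "noise", "output", "seeds", "rounding",
                 "bicarbonate_model", "pla_model")

#' Read a run configuration
#'
#' YAML with top-level sections `conversion` (specific activity, carbon-mass
#' fractions, atomic mass), `noise` (`cv`, `replicates`), `seeds`, `output`,
#' `rounding`, and optional `bicarbonate_model` / `pla_model` rate
#' overrides. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return Named list of configuration sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_schema("no such config file: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_schema("%s: config must be a YAML mapping", path)
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown)) {
    stop_schema("%s: unknown config key(s): %s", path,
                paste(unknown, collapse = ", "))
  }
  cfg
}

#' Conversion constants from a run configuration
#'
#' @param cfg A [read_run_config()] result.
#' @return A [conversion_constants()] object.
#' @export
config_conversion_constants <- function(cfg) {
  cv <- cfg$conversion
  if (is.null(cv$specific_activity)) {
    stop_config("config section 'conversion' must set specific_activity")
  }
  do.call(conversion_constants, cv)
}
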
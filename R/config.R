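#' Read a flat TOML configuration file
#'
#' Minimal reader for the subset of TOML used by the command-line interface:
#' `[section]` headers and scalar `key = value` pairs (numbers, booleans,
#' quoted strings). Arrays, dates and nested tables are not supported. Keys are
#' returned as `section.key`; command-line flags override config values.
#'
#' @param path Path to the config file.
#' @return Named list of scalar values.
#' @export
read_flux_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) == 0L)
      abort(sprintf("cannot parse config line: '%s'", ln))
    key <- if (nzchar(section)) paste(section, m[2], sep = ".") else m[2]
    raw <- trimws(m[3])
    val <- if (grepl('^".*"$', raw)) {
      gsub('^"|"$', "", raw)
    } else if (raw %in% c("true", "false")) {
      raw == "true"
    } else {
      suppressWarnings(as.numeric(raw))
    }
    if (is.null(val) || (is.numeric(val) && is.na(val)))
      abort(sprintf("cannot parse config value in line: '%s'", ln))
    out[[key]] <- val
  }
  out
}

#' Write a run manifest
#'
#' All command-line entry points log their parameters, seed and outputs to a
#' small JSON manifest next to the results, for provenance.
#'
#' @param path Output path (JSON).
#' @param params Named list of parameters.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params) {
  params$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  params$package_version <- as.character(utils::packageVersion("fluxness"))
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
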
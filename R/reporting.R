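#' Assemble a design report
#'
#' A design report bundles the resolved inputs of a calculation with its
#' outputs and provenance (seed, package version, timestamp) so a run can
#' be audited and reproduced. Reports round-trip losslessly through their
#' JSON serialization (the timestamp aside, numbers are written at full
#' double precision).
#'
#' @param subcommand Name of the producing operation.
#' @param inputs Named list of resolved input parameters.
#' @param outputs Named list of results.
#' @param seed Seed used, or `NULL` for deterministic calculations.
#' @return An object of class `design_report`.
#' @export
design_report <- function(subcommand, inputs, outputs, seed = NULL) {
  structure(list(
    subcommand = subcommand,
    inputs = inputs,
    outputs = outputs,
    provenance = list(
      package = "pnidesign",
      version = as.character(utils::packageVersion("pnidesign")),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("pnidesign report: %s\n", x$subcommand))
  cat("inputs:\n")
  for (nm in names(x$inputs)) cat(sprintf("  %s: %s\n", nm, paste(format(x$inputs[[nm]]), collapse = ", ")))
  cat("outputs:\n")
  for (nm in names(x$outputs)) {
    v <- x$outputs[[nm]]
    shown <- if (is.numeric(v) && length(v) == 1L && !is.na(v) && v >= 0 && v <= 1 &&
                 grepl("^prob|^p_|conditional", nm))
      sprintf("%.6f (%s)", v, .pct(v)) else paste(format(v), collapse = ", ")
    cat(sprintf("  %s: %s\n", nm, shown))
  }
  invisible(x)
}

#' Write a design report to JSON
#'
#' @param report A [design_report()].
#' @param path Output path; the JSON is written at full double precision.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(report, path) {
  stopifnot(inherits(report, "design_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a design report back from JSON
#'
#' @param path Path written by [write_design_report()].
#' @return A `design_report`.
#' @export
read_design_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(x, class = "design_report")
}
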
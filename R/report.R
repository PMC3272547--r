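#' Structured run report
#'
#' Every command-line entry point emits one JSON report per run: tool
#' version, the effective configuration (after defaults and overrides),
#' the seed, the computed statistics and any warnings. A report written
#' with [write_report()] and read back with [read_report()] is
#' identical.
#'
#' @param statistics named list of results (nested lists allowed).
#' @param config named list echoing the effective configuration.
#' @param seed integer seed used for the run.
#' @param warnings character vector of warning messages.
#' @return A list of class `run_report`.
#' @export
run_report <- function(statistics, config = list(), seed = NA_integer_,
                       warnings = character(0)) {
  structure(
    list(tool = "crestswarm",
         version = as.character(utils::packageVersion("crestswarm")),
         seed = seed,
         config = config,
         statistics = statistics,
         warnings = as.character(warnings)),
    class = "run_report"
  )
}

#' @rdname run_report
#' @param report a `run_report`.
#' @param path output (input) JSON file.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  structure(obj, class = "run_report")
}

## strip non-serialisable pieces from a circular_result for reporting
circ_report <- function(cr, degrees = TRUE) {
  f <- if (degrees) 180 / pi else 1
  list(n = cr$n,
       mean_direction = cr$mean_direction * f,
       mean_resultant_length = cr$mean_resultant_length,
       circular_dispersion = cr$circular_dispersion * f,
       statistic = cr$statistic,
       p_value = cr$p_value,
       test = cr$test,
       angle_unit = if (degrees) "degrees" else "radians")
}
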
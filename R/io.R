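#' Read a pipeline configuration from YAML
#'
#' The file may contain any of the blocks `preprocessing`, `embedding`,
#' `ealm`, `select`, `window`; recognized keys override the corresponding
#' constructor defaults and everything omitted keeps its default.
#'
#' @param path YAML file path (NULL returns all defaults).
#' @return list with elements `preproc`, `embed`, `ealm`, `select`,
#'   `window`, ready to splice into [run_lassa()].
#' @export
read_lassa_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(ctor, block) {
    args <- raw[[block]]
    if (is.null(args)) return(ctor())
    known <- names(formals(ctor))
    unknown <- setdiff(names(args), known)
    stop_if(length(unknown) > 0,
            sprintf("unknown key(s) in '%s': %s", block,
                    paste(unknown, collapse = ", ")))
    do.call(ctor, args)
  }
  list(preproc = build(preproc_config, "preprocessing"),
       embed = build(embedding_config, "embedding"),
       ealm = build(ealm_config, "ealm"),
       select = build(select_config, "select"),
       window = build(window_config, "window"))
}

#' Write / read a windowed heart-rate series as CSV
#'
#' Columns: `time`, `hr_bpm`, `flag`.
#'
#' @param hr an [hr_series()].
#' @param path file path.
#' @return `write_hr_csv` returns `path` invisibly; `read_hr_csv` returns
#'   an [hr_series()].
#' @export
write_hr_csv <- function(hr, path) {
  stopifnot(inherits(hr, "hr_series"))
  utils::write.csv(as.data.frame(hr), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hr_csv
#' @export
read_hr_csv <- function(path) {
  d <- utils::read.csv(path)
  stop_if(!all(c("time", "hr_bpm") %in% names(d)),
          "HR CSV needs columns 'time' and 'hr_bpm'")
  hr_series(d$time, d$hr_bpm, if ("flag" %in% names(d)) d$flag else "ok")
}

#' Write an evaluation report as JSON
#'
#' @param report an [evaluate_hr()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
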
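#' Toxicokinetic observation dataset
#'
#' Whole-body (and optionally water) concentration observations from one
#' or several exposure experiments, the calibration target. The record
#' table uses the documented CSV schema: `design_id`, `compound`,
#' `time_hpf`, `conc_body` (ng/mg wet), `conc_body_sd`, `conc_water`
#' (nM, optional), `n_embryos`.
#'
#' @param records data.frame in the schema above (missing optional
#'   columns are added as `NA`).
#' @param designs named list of [exposure_design()] objects keyed by
#'   `design_id`.
#' @return Object of class `zfe_tkdata`.
#' @export
tk_dataset <- function(records, designs) {
  records <- as.data.frame(records)
  need <- c("design_id", "compound", "time_hpf", "conc_body")
  if (!all(need %in% names(records)))
    stop_input("records needs columns: ", paste(need, collapse = ", "))
  for (opt in c("conc_body_sd", "conc_water", "n_embryos"))
    if (!opt %in% names(records)) records[[opt]] <- rep(NA, nrow(records))
  if (any(records$conc_body <= 0, na.rm = TRUE))
    stop_input("conc_body must be > 0 (lognormal error model)")
  miss <- setdiff(unique(records$design_id), names(designs))
  if (length(miss))
    stop_input("designs missing for: ", paste(miss, collapse = ", "))
  for (id in unique(records$design_id)) {
    d <- designs[[id]]
    tt <- records$time_hpf[records$design_id == id]
    if (any(tt < d$start_age - 1e-9 | tt > d$start_age + d$duration + 1e-9))
      stop_input("observation times of ", id, " outside the exposure window")
  }
  res <- list(records = records, designs = designs)
  class(res) <- "zfe_tkdata"
  res
}

#' @export
print.zfe_tkdata <- function(x, ...) {
  cat("zfe TK dataset:", nrow(x$records), "observations,",
      length(unique(x$records$design_id)), "design(s), compound(s):",
      paste(unique(x$records$compound), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write the TK observation CSV
#'
#' @param path CSV file path.
#' @param designs named list of [exposure_design()] objects (reader only).
#' @return [tk_dataset()] object (reader); invisibly `path` (writer).
#' @export
read_tk_csv <- function(path, designs) {
  tk_dataset(read.csv(path, stringsAsFactors = FALSE), designs)
}

#' @rdname read_tk_csv
#' @param dataset a [tk_dataset()].
#' @export
write_tk_csv <- function(dataset, path) {
  write.csv(dataset$records, path, row.names = FALSE)
  invisible(path)
}
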
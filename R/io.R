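# Plain-text interchange formats: time series CSV (columns time,value;
# '#' comment lines), expert panel CSV (expert_id, t1..tT; cells beyond an
# expert's horizon left empty), and the 10-rate parameter table CSV.

#' Read and write time series CSV
#'
#' The on-disk dialect is a header `time,value` followed by numeric rows;
#' lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_timeseries()` returns a [timeseries()];
#'   `write_timeseries()` returns the path invisibly.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  if (!all(c("time", "value") %in% names(df)))
    stop("'", path, "' must have columns 'time' and 'value'")
  tm <- suppressWarnings(as.numeric(df$time))
  vl <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(tm) | !is.finite(vl))
  if (length(bad) > 0L)
    stop("non-numeric entry in '", path, "' at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  timeseries(vl, tm)
}

#' @rdname read_timeseries
#' @param ts a [timeseries()].
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries"))
  utils::write.csv(data.frame(time = ts$times, value = ts$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write expert panel CSV
#'
#' First column `expert_id`, remaining columns `t1..tT`; cells beyond an
#' expert's horizon are empty.
#'
#' @param path file path.
#' @return `read_expert_panel()` returns an [expert_panel()].
#' @export
read_expert_panel <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                        check.names = FALSE)
  if (names(df)[1L] != "expert_id")
    stop("'", path, "' must start with an 'expert_id' column")
  adv <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(adv) <- "double"
  expert_panel(adv, ids = as.character(df$expert_id))
}

#' @rdname read_expert_panel
#' @param panel an [expert_panel()].
#' @export
write_expert_panel <- function(panel, path) {
  stopifnot(inherits(panel, "expert_panel"))
  adv <- panel$advice
  for (i in seq_len(nrow(adv)))
    if (panel$horizon[i] < ncol(adv))
      adv[i, seq(panel$horizon[i] + 1L, ncol(adv))] <- NA_real_
  df <- data.frame(expert_id = panel$ids, adv, check.names = FALSE)
  names(df) <- c("expert_id", paste0("t", seq_len(ncol(adv))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write the model parameter table CSV
#'
#' Columns `id, d1..d6, e1..e4`: six on-treatment and four off-treatment
#' rates per previous patient.
#'
#' @param path file path.
#' @return `read_ias_param_table()` returns the validated data frame.
#' @export
read_ias_param_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  check_param_table(df)
  num <- c(paste0("d", 1:6), paste0("e", 1:4))
  for (cl in num) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop("non-numeric '", cl, "' in '", path, "' at data row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    df[[cl]] <- v
  }
  df
}

#' @rdname read_ias_param_table
#' @param tab parameter table data frame.
#' @export
write_ias_param_table <- function(tab, path) {
  check_param_table(tab)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
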
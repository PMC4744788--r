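#' Read a monitoring CSV
#'
#' Reads long-format monitoring data with columns `WellName`, `XCoord`,
#' `YCoord`, `SampleDate` (ISO 8601 date) and `Result` (concentration, >= 0).
#' Duplicate (well, date) rows are kept: replicate samples are legitimate.
#' Dates are converted to fractional days since the earliest sample in the
#' file and returned in column `t` alongside the parsed `date`. Nondetects /
#' censored values are not handled; impute them before reading.
#'
#' @param path CSV file (comma-separated, UTF-8, `.` decimal, header line).
#' @return data frame with columns `well`, `s1`, `s2`, `date`, `t`, `conc`,
#'   ready for [stps()].
#' @export
read_monitoring_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("WellName", "XCoord", "YCoord", "SampleDate", "Result")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | raw[[col]] == "")
    if (length(bad))
      stop("unparseable ", col, " on data row ", bad[1])
    v
  }
  x <- num("XCoord"); yy <- num("YCoord"); res <- num("Result")
  if (any(res < 0))
    stop("negative Result on data row ", which(res < 0)[1],
         "; censored/nondetect values must be imputed before reading")
  d <- as.Date(raw$SampleDate, format = "%Y-%m-%d")
  bad <- which(is.na(d))
  if (length(bad)) stop("unparseable SampleDate on data row ", bad[1])
  out <- data.frame(well = raw$WellName, s1 = x, s2 = yy, date = d,
                    t = as.numeric(d - min(d)), conc = res)
  message(sprintf("read %d observations at %d wells from %s",
                  nrow(out), length(unique(out$well)), path))
  out
}

#' Write a monitoring CSV
#'
#' Inverse of [read_monitoring_csv()] for simulated datasets: writes columns
#' `WellName`, `XCoord`, `YCoord`, `SampleDate`, `Result`. Numeric times in
#' `[0, 1]` are mapped to dates by `origin + round(t * 365)` days.
#'
#' @param data data frame with `well`, `s1`, `s2`, `conc` and either `date`
#'   or numeric `t`.
#' @param path output file.
#' @param origin origin date used when converting numeric `t`.
#' @return `path`, invisibly.
#' @export
write_monitoring_csv <- function(data, path, origin = as.Date("2000-01-01")) {
  d <- if (!is.null(data$date)) data$date else origin + round(data$t * 365)
  out <- data.frame(WellName = data$well, XCoord = data$s1, YCoord = data$s2,
                    SampleDate = format(d, "%Y-%m-%d"), Result = data$conc)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a prediction grid with a metadata header
#'
#' Long-format CSV `s1, s2, t, mean, lower, upper[, in_hull]` preceded by
#' `#`-prefixed metadata lines (fit settings, selected smoothing parameter,
#' effective degrees of freedom), so the file is self-describing while still
#' readable with `read.csv(comment.char = "#")`.
#'
#' @param pred data frame from [predict.stps()] / [prediction_grid()].
#' @param path output file.
#' @param fit optional `"stps"` fit supplying the metadata.
#' @return `path`, invisibly.
#' @export
write_prediction_grid <- function(pred, path, fit = NULL) {
  if (nrow(pred) == 0L) stop("empty prediction grid")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path))
  on.exit(close(con))
  meta <- c(sprintf("# stpspline prediction grid (%d rows)", nrow(pred)),
            sprintf("# written %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  if (!is.null(fit)) {
    meta <- c(meta,
              sprintf("# basis %s degree %d penalty_order %d",
                      paste(fit$spec$n_basis, collapse = "x"),
                      fit$spec$degree, fit$penalty$order),
              sprintf("# selector %s lambda %.10g edf %.6f",
                      fit$selector, fit$lambda, fit$edf))
  }
  writeLines(meta, con)
  utils::write.csv(pred, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prediction grid written by [write_prediction_grid()]
#'
#' @param path CSV file.
#' @return data frame; metadata lines are returned in attribute `"meta"`.
#' @export
read_prediction_grid <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  out <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  attr(out, "meta") <- meta
  out
}
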
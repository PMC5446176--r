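#' Read and write time-course records
#'
#' A record is stored as a two-column CSV (\code{time_s}, \code{signal};
#' header row, '.' decimal, UTF-8) with a JSON metadata sidecar at
#' \code{<path>.json}. Values are written with 15 significant digits so a
#' round trip is lossless to at least 12. For records whose natural time unit
#' is minutes the time column is still named \code{time_s} for schema
#' stability; \code{meta$time_unit} records the unit.
#'
#' @param record a \code{\link{time_course}}.
#' @param path CSV file path; the sidecar is written next to it.
#' @return \code{write_timecourse} returns \code{path} invisibly;
#'   \code{read_timecourse} returns a \code{time_course}.
#' @export
write_timecourse <- function(record, path) {
  stopifnot(inherits(record, "time_course"))
  lines <- c("time_s,signal",
             sprintf("%.15g,%.15g", record$time, record$signal))
  writeLines(lines, path)
  meta <- record$meta
  meta$schema <- "nexkin/timecourse/v1"
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) != 2L || !identical(names(df), c("time_s", "signal"))) {
    stop("expected schema: CSV with exactly two columns 'time_s,signal'; got ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  if (!is.numeric(df$time_s) || !is.numeric(df$signal) || anyNA(df$time_s) ||
      anyNA(df$signal)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$time_s))) |
                 !is.finite(suppressWarnings(as.numeric(df$signal))))
    stop("non-numeric values at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  neg <- which(df$time_s < 0)
  if (length(neg)) {
    stop("negative time at row(s): ", paste(neg, collapse = ", "), call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    warning("missing metadata sidecar ", sidecar,
            "; record usable only for bare exponential fits", call. = FALSE)
    list()
  }
  time_course(df$time_s, df$signal, meta = as.list(meta))
}

#' Read / write an emission spectrum
#'
#' Two-column CSV: \code{wavelength_nm}, \code{intensity}.
#'
#' @param spectrum data.frame spectrum.
#' @param path CSV path.
#' @export
write_spectrum <- function(spectrum, path) {
  validate_spectrum(spectrum)
  utils::write.csv(spectrum[, c("wavelength_nm", "intensity")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_spectrum(df)
}
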
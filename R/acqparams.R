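#' Phase-encoding specification
#'
#' Describes how an EPI volume was phase encoded: the grid axis along which
#' distortion displaces signal, the blip polarity, and the total readout
#' time.  A readout time of 0 encodes an acquisition free of susceptibility
#' distortion (infinite phase-encode bandwidth) — this is how the synthetic
#' undistorted b0 is presented to the field estimator.
#'
#' @param axis PE axis as 1-based grid index (1, 2 or 3).
#' @param polarity +1 or -1, the blip direction.
#' @param readout_time total readout time in seconds, >= 0.
#' @return object of class `pe_spec`.
#' @export
pe_spec <- function(axis, polarity = 1L, readout_time = 0.05) {
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("PE axis must be 1, 2 or 3")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  if (!is.finite(readout_time) || readout_time < 0)
    stop("readout_time must be >= 0 seconds")
  structure(list(axis = axis, polarity = as.integer(polarity),
                 readout_time = as.numeric(readout_time)),
            class = "pe_spec")
}

#' @export
print.pe_spec <- function(x, ...) {
  cat(sprintf("<pe_spec axis=%d polarity=%+d readout=%gs>\n",
              x$axis, x$polarity, x$readout_time))
  invisible(x)
}

format_acqparams_row <- function(spec) {
  v <- c(0L, 0L, 0L)
  v[spec$axis] <- spec$polarity
  paste(v[1], v[2], v[3], format(spec$readout_time, trim = TRUE))
}

#' Write a topup-style acquisition-parameters table
#'
#' One text row per phase-encoding spec: three signed unit phase-encode
#' vector components followed by the total readout time in seconds,
#' whitespace-separated.  The layout is interoperable with FSL topup's
#' `--datain` file.  For the zero-readout correction trick the table has two
#' rows: a "dummy" row carrying an arbitrary positive readout in the PE
#' column, then a row whose readout is exactly 0 marking the undistorted
#' volume.
#'
#' @param specs non-empty list of [pe_spec]; all must share the same axis.
#' @param path output file path, or `NULL` to skip writing.
#' @return character vector of rows, invisibly if written.
#' @export
write_acqparams <- function(specs, path = NULL) {
  if (inherits(specs, "pe_spec")) specs <- list(specs)
  if (length(specs) == 0) stop("need at least one phase-encoding spec")
  axes <- vapply(specs, function(s) s$axis, integer(1))
  if (length(unique(axes)) != 1L)
    stop("all specs in one acqparams table must share the PE axis")
  rows <- vapply(specs, format_acqparams_row, character(1))
  if (!is.null(path)) {
    writeLines(rows, path)
    return(invisible(rows))
  }
  rows
}

#' Parse a topup-style acquisition-parameters table
#'
#' @param path file with 4 whitespace-separated columns per row.
#' @return list of [pe_spec].
#' @export
read_acqparams <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("x", "y", "z", "readout"))
  lapply(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(tab[i, 1:3])
    nz <- which(v != 0)
    if (length(nz) != 1L || !v[nz] %in% c(-1, 1))
      stop("row ", i, ": PE vector must have exactly one entry in {+1,-1}")
    pe_spec(axis = nz, polarity = v[nz], readout_time = tab$readout[i])
  })
}
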
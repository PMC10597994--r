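#' Physiological recording paired with a scan
#'
#' Cardiac (pulse oximeter) and respiratory (bellows) waveforms sampled at
#' known rates, plus the acquisition onset time of every volume. Both
#' waveforms must cover the scan, i.e. the interval
#' `[0, last onset + tr]`.
#'
#' @param cardiac,respiratory numeric waveforms.
#' @param cardiac_rate_hz,respiratory_rate_hz sampling rates in Hz.
#' @param volume_onsets_s strictly increasing volume onset times (s).
#' @return an object of class `physio_recording`.
#' @export
physio_recording <- function(cardiac, cardiac_rate_hz,
                             respiratory, respiratory_rate_hz,
                             volume_onsets_s) {
  stopifnot(cardiac_rate_hz > 0, respiratory_rate_hz > 0,
            length(volume_onsets_s) >= 2L)
  dt <- diff(volume_onsets_s)
  if (any(dt <= 0))
    stop("volume onset times must be strictly increasing", call. = FALSE)
  tr <- stats::median(dt)
  scan_end <- volume_onsets_s[length(volume_onsets_s)] + tr
  for (trace in list(c = list(w = cardiac, r = cardiac_rate_hz),
                     r = list(w = respiratory, r = respiratory_rate_hz))) {
    cover <- (length(trace$w) - 1L) / trace$r
    if (cover < scan_end - 1e-9)
      stop(sprintf("physiological trace %.1f s short of scan end (covers %.1f of %.1f s)",
                   scan_end - cover, cover, scan_end), call. = FALSE)
  }
  structure(list(cardiac = as.numeric(cardiac),
                 cardiac_rate_hz = cardiac_rate_hz,
                 respiratory = as.numeric(respiratory),
                 respiratory_rate_hz = respiratory_rate_hz,
                 volume_onsets_s = as.numeric(volume_onsets_s),
                 tr_s = tr),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("<physio_recording> cardiac %d pts @ %g Hz, respiratory %d pts @ %g Hz, %d volumes (TR %.3g s)\n",
              length(x$cardiac), x$cardiac_rate_hz, length(x$respiratory),
              x$respiratory_rate_hz, length(x$volume_onsets_s), x$tr_s))
  invisible(x)
}

read_trace <- function(path, rate_hz = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#",
                           colClasses = "character")
  # accept comma-separated two-column files too
  if (ncol(tab) == 1L && any(grepl(",", tab[[1]], fixed = TRUE)))
    tab <- utils::read.table(path, header = FALSE, sep = ",",
                             comment.char = "#", colClasses = "character")
  tab <- as.data.frame(lapply(tab, as.numeric))
  if (ncol(tab) >= 2L) {
    t <- tab[[1]]; v <- tab[[2]]
    if (any(diff(t) <= 0)) stop("trace times must be increasing: ", path,
                                call. = FALSE)
    rate <- 1 / stats::median(diff(t))
    # resample to the uniform internal grid implied by the median step
    grid <- seq(t[1], t[length(t)], by = 1 / rate) - t[1]
    v <- stats::approx(t - t[1], v, xout = grid, rule = 2)$y
    list(values = v, rate_hz = rate)
  } else {
    if (is.null(rate_hz))
      stop("single-column trace needs an explicit sampling rate: ", path,
           call. = FALSE)
    list(values = tab[[1]], rate_hz = rate_hz)
  }
}

#' Read physiological traces and volume triggers from text files
#'
#' Traces are two-column text (`time_s value`, whitespace- or
#' comma-separated) or single-column at a declared rate (AFNI 1D style);
#' triggers are one onset time per line, one per volume.
#'
#' @param cardiac_path,resp_path,triggers_path file paths.
#' @param cardiac_rate_hz,resp_rate_hz sampling rates, required only for
#'   single-column traces.
#' @return a [physio_recording()].
#' @export
read_physio <- function(cardiac_path, resp_path, triggers_path,
                        cardiac_rate_hz = NULL, resp_rate_hz = NULL) {
  card <- read_trace(cardiac_path, cardiac_rate_hz)
  resp <- read_trace(resp_path, resp_rate_hz)
  trig <- utils::read.table(triggers_path, header = FALSE)[[1]]
  physio_recording(card$values, card$rate_hz, resp$values, resp$rate_hz, trig)
}

#' Write a physiological recording to text files
#'
#' Inverse of [read_physio()]: two-column traces and a one-column trigger
#' file.
#'
#' @param p a [physio_recording()].
#' @param cardiac_path,resp_path,triggers_path output paths.
#' @return invisibly, a character vector of the three paths.
#' @export
write_physio <- function(p, cardiac_path, resp_path, triggers_path) {
  stopifnot(inherits(p, "physio_recording"))
  tc <- (seq_along(p$cardiac) - 1) / p$cardiac_rate_hz
  tr <- (seq_along(p$respiratory) - 1) / p$respiratory_rate_hz
  utils::write.table(data.frame(t = tc, v = p$cardiac), cardiac_path,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(t = tr, v = p$respiratory), resp_path,
                     row.names = FALSE, col.names = FALSE)
  writeLines(format(p$volume_onsets_s, trim = TRUE, digits = 10),
             triggers_path)
  invisible(c(cardiac_path, resp_path, triggers_path))
}
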
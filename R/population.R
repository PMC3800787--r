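# Population panels: stimulus STFT spectrogram, DRNL-channel spectrogram and
# BF-ordered population PSTH matrix, all on a dB-FS scale (0 dB FS = the
# matrix maximum, floored at -60 dB FS for display).

#' Population matrix container
#'
#' A frequency-by-time matrix in dB FS with ascending frequency rows.
#'
#' @param row_axis_hz row frequencies/BFs, Hz (strictly increasing).
#' @param col_axis_ms column times, ms.
#' @param values_db matrix of dB FS values (max exactly 0).
#' @return A `population_matrix` object.
#' @export
population_matrix <- function(row_axis_hz, col_axis_ms, values_db) {
  if (is.unsorted(row_axis_hz, strictly = FALSE))
    stop("row_axis_hz must be sorted ascending")
  if (nrow(values_db) != length(row_axis_hz) ||
      ncol(values_db) != length(col_axis_ms))
    stop("matrix dimensions must match the axes")
  if (abs(max(values_db) - 0) > 1e-12)
    stop("dB FS matrix must have maximum 0")
  structure(list(row_axis_hz = row_axis_hz, col_axis_ms = col_axis_ms,
                 values_db = values_db),
            class = "population_matrix")
}

#' @export
print.population_matrix <- function(x, ...) {
  cat(sprintf("<population_matrix> %d rows (%.0f-%.0f Hz) x %d time bins, floor %.0f dB FS\n",
              length(x$row_axis_hz), min(x$row_axis_hz), max(x$row_axis_hz),
              length(x$col_axis_ms), min(x$values_db)))
  invisible(x)
}

# amplitude matrix -> dB relative to its own maximum, floored
to_db_fs <- function(v, floor_db = -60) {
  vmax <- max(v)
  if (vmax <= 0) stop("cannot scale to dB FS: maximum is not positive")
  pmax(20 * log10(pmax(v, 0) / vmax + .Machine$double.xmin), floor_db)
}

#' DRNL-channel spectrogram of a stimulus
#'
#' One row per DRNL channel: the un-normalized smoothed 1-ms envelope of that
#' channel, with the global maximum mapped to 0 dB FS.
#'
#' @param stim an [acoustic_stimulus()].
#' @param bf_grid channel best frequencies, Hz, sorted ascending.
#' @param coefs DRNL coefficient set.
#' @param floor_db display floor (default -60 dB FS).
#' @return A [population_matrix()].
#' @export
drnl_spectrogram <- function(stim, bf_grid, coefs = drnl_default_coefs(),
                             floor_db = -60) {
  if (length(bf_grid) == 0L) stop("empty BF grid")
  if (is.unsorted(bf_grid)) stop("bf_grid must be sorted ascending")
  if (max(abs(stim$samples)) == 0) stop("silent stimulus")
  rows <- lapply(bf_grid, function(bf)
    drnl_output(stim, bf, coefs = coefs, smooth = TRUE, normalize = FALSE)$values)
  v <- do.call(rbind, rows)
  population_matrix(bf_grid, seq_len(ncol(v)) - 1, to_db_fs(v, floor_db))
}

#' BF-ordered population PSTH matrix
#'
#' Rows are PSTHs sorted by ascending BF; negative driven bins are clipped to
#' 0 for the dB display only.
#'
#' @param psths list of `psth` objects, each with a finite `bf_hz` and equal
#'   length.
#' @param floor_db display floor (default -60 dB FS).
#' @return A [population_matrix()].
#' @export
population_psth_matrix <- function(psths, floor_db = -60) {
  bfs <- vapply(psths, function(p) as.numeric(p$bf_hz), numeric(1))
  if (any(is.na(bfs))) {
    bad <- vapply(psths[is.na(bfs)], function(p) as.character(p$site_id), "")
    stop("PSTHs without BF: ", paste(bad, collapse = ", "))
  }
  lens <- vapply(psths, function(p) length(p$bins), integer(1))
  if (length(unique(lens)) != 1L) stop("PSTHs must share a common 1-ms grid")
  ord <- order(bfs)
  v <- do.call(rbind, lapply(psths[ord], function(p) pmax(p$bins, 0)))
  population_matrix(bfs[ord], seq_len(ncol(v)) - 1, to_db_fs(v, floor_db))
}

#' STFT spectrogram of a stimulus
#'
#' Short-time Fourier transform magnitude in dB FS.
#'
#' @param stim an [acoustic_stimulus()].
#' @param window_samples FFT window length (default 512).
#' @param overlap_frac window overlap fraction (default 0.5).
#' @param floor_db display floor (default -60 dB FS).
#' @return A [population_matrix()].
#' @export
stft_spectrogram <- function(stim, window_samples = 512, overlap_frac = 0.5,
                             floor_db = -60) {
  if (max(abs(stim$samples)) == 0) stop("silent stimulus")
  sp <- signal::specgram(stim$samples, n = window_samples, Fs = stim$rate_hz,
                         overlap = round(window_samples * overlap_frac))
  v <- Mod(sp$S)
  population_matrix(as.numeric(sp$f), as.numeric(sp$t) * 1000,
                    to_db_fs(v, floor_db))
}

#' Write a population matrix as CSV
#'
#' First column `freq_hz`, remaining columns one per time bin (header in ms).
#'
#' @param pm a [population_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pm, path) {
  d <- data.frame(freq_hz = pm$row_axis_hz, pm$values_db, check.names = FALSE)
  names(d)[-1] <- format(pm$col_axis_ms, trim = TRUE)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
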
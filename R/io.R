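#' @include AllClasses.R
NULL

#' Write a recording to disk
#'
#' Emits the formats the pipeline reads: `signals.bin` (float32,
#' channel-interleaved column-major), `recording.json` (sampling rate,
#' channel names, layout), `seizures.csv` (onset_s, offset_s),
#' `evolutions/evolution_<i>.tsv` and `truth.json` when ground truth is
#' present.
#'
#' @param recording a \linkS4class{SyntheticRecording}.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRecording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "signals.bin"), "wb")
  writeBin(as.numeric(recording@signals), con, size = 4)
  close(con)
  jsonlite::write_json(list(
    fs = recording@fs,
    channel_names = recording@channelNames,
    n_channels = nrow(recording@signals),
    n_samples = ncol(recording@signals),
    dtype = "float32",
    layout = "column-major channels x samples"
  ), file.path(dir, "recording.json"), auto_unbox = TRUE, digits = NA)
  if (length(recording@seizureOnsets)) {
    n_steps <- vapply(recording@seizureEvolutions, nrow, integer(1))
    write.csv(data.frame(onset_s = recording@seizureOnsets,
                         offset_s = recording@seizureOnsets + 2 * n_steps),
              file.path(dir, "seizures.csv"), row.names = FALSE)
    evdir <- file.path(dir, "evolutions")
    dir.create(evdir, showWarnings = FALSE)
    for (i in seq_along(recording@seizureEvolutions))
      write.table(recording@seizureEvolutions[[i]],
                  file.path(evdir, sprintf("evolution_%02d.tsv", i)),
                  sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  if (length(recording@truth)) {
    tr <- recording@truth
    jsonlite::write_json(list(
      seed = tr$seed, noise_sd = tr$noise_sd,
      modulators = lapply(tr$modulators, function(m) list(
        period = m@period, amplitude = m@amplitude, phase = m@phase,
        jitter = m@jitter, loading = m@loading)),
      state_times_days = tr$state_times_days,
      states = tr$states,
      seizures = tr$seizures
    ), file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE,
    matrix = "rowmajor")
  }
  invisible(dir)
}

#' Read a recording from disk
#'
#' Reads the raw float32 binary + JSON sidecar layout written by
#' [writeRecording()], plus seizure annotations and evolution matrices
#' when present. Ground truth is not reloaded (it documents the
#' generator, not the recording).
#'
#' @param dir directory containing `signals.bin` and `recording.json`.
#' @return A \linkS4class{SyntheticRecording}.
#' @export
readRecording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  con <- file(file.path(dir, "signals.bin"), "rb")
  v <- readBin(con, numeric(), n = meta$n_channels * meta$n_samples, size = 4)
  close(con)
  signals <- matrix(v, nrow = meta$n_channels)
  onsets <- numeric(0); evolutions <- list()
  szp <- file.path(dir, "seizures.csv")
  if (file.exists(szp)) {
    onsets <- read.csv(szp)$onset_s
    evdir <- file.path(dir, "evolutions")
    if (dir.exists(evdir)) {
      fls <- sort(list.files(evdir, pattern = "^evolution_.*\\.tsv$",
                             full.names = TRUE))
      evolutions <- lapply(fls, function(f)
        unname(as.matrix(read.table(f, sep = "\t"))))
    }
  }
  new("SyntheticRecording", signals = signals, fs = meta$fs,
      channelNames = as.character(meta$channel_names), epoch_s = 30,
      seizureOnsets = as.numeric(onsets), seizureEvolutions = evolutions,
      truth = list())
}

#' Write a band-power matrix as delimited text + JSON row index
#'
#' @param bp a \linkS4class{BandPowerMatrix}.
#' @param path output TSV path; a `.json` sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
writeBandPower <- function(bp, path) {
  write.table(SummarizedExperiment::assay(bp), path, sep = "\t",
              row.names = TRUE, col.names = FALSE, quote = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(bp))
  jsonlite::write_json(list(
    epoch_s = S4Vectors::metadata(bp)$epoch_s,
    band = rd$band, channel = rd$channel
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a band-power matrix written by [writeBandPower()]
#'
#' @param path TSV path with its `.json` sidecar.
#' @return A \linkS4class{BandPowerMatrix}.
#' @export
readBandPower <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.table(path, sep = "\t", row.names = 1))
  colnames(m) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(X = m),
    rowData = S4Vectors::DataFrame(band = meta$band, channel = meta$channel),
    metadata = list(epoch_s = meta$epoch_s))
  new("BandPowerMatrix", se)
}
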
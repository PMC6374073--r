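# Session bundles on disk. A bundle is a directory of plain-text files:
#   config.yaml, stimulus.csv, trials.csv, vr.csv, eyes.csv, bouts.csv,
#   cells/<id>_{cs,ss}.csv, calcium/<id>.csv
# Volumes are written as TIFF, morphologies as SWC.

#' Write a synthetic session to a bundle directory
#'
#' @param session a "SyntheticSession" from [simulateSession()].
#' @param dir target directory (created).
#' @param writeVR include the raw VR trace (large; default TRUE).
#' @return the directory path, invisibly.
#' @export
writeSessionBundle <- function(session, dir, writeVR = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cells"), showWarnings = FALSE)
  cfg <- session$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  utils::write.csv(epochs(session$protocol),
                   file.path(dir, "stimulus.csv"), row.names = FALSE)
  utils::write.csv(trials(session$protocol),
                   file.path(dir, "trials.csv"), row.names = FALSE)
  if (writeVR) {
    vr <- session$behavior$vr
    utils::write.csv(data.frame(value = round(tsValues(vr), 5)),
                     file.path(dir, "vr.csv"), row.names = FALSE)
    cat(sprintf("rate: %g\nt0: %g\n", tsRate(vr), vr@t0),
        file = file.path(dir, "vr.meta"))
  }
  ey <- session$behavior$eyes
  utils::write.csv(data.frame(left = round(tsValues(ey$left), 5),
                              right = round(tsValues(ey$right), 5)),
                   file.path(dir, "eyes.csv"), row.names = FALSE)
  cat(sprintf("rate: %g\n", tsRate(ey$left)),
      file = file.path(dir, "eyes.meta"))
  utils::write.csv(bouts(session$behavior$boutTruth),
                   file.path(dir, "bouts.csv"), row.names = FALSE)
  for (cell in session$cells) {
    times <- c(if (!is.null(cell$cs)) spikeTimes(cell$cs),
               spikeTimes(cell$ss))
    lab <- c(if (!is.null(cell$cs))
      rep("complex", nSpikes(cell$cs)),
      rep(spikeLabel(cell$ss), nSpikes(cell$ss)))
    o <- order(times)
    utils::write.csv(data.frame(time_s = times[o], label = lab[o]),
                     file.path(dir, "cells",
                               paste0(cell$cellId, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read spike trains back from a session bundle
#'
#' @param dir bundle directory.
#' @return list with `config`, `epochs`, `trials`, `bouts`, and `cells`
#'   (per cell: list of cs/ss [SpikeTrain-class]).
#' @export
readSessionBundle <- function(dir) {
  cfgPath <- file.path(dir, "config.yaml")
  out <- list()
  if (file.exists(cfgPath)) out$config <- yaml::read_yaml(cfgPath)
  out$epochs <- utils::read.csv(file.path(dir, "stimulus.csv"))
  out$trials <- utils::read.csv(file.path(dir, "trials.csv"))
  bp <- file.path(dir, "bouts.csv")
  if (file.exists(bp)) out$bouts <- BoutTable(utils::read.csv(bp))
  cellFiles <- list.files(file.path(dir, "cells"), full.names = TRUE,
                          pattern = "\\.csv$")
  out$cells <- lapply(cellFiles, function(p) {
    d <- utils::read.csv(p)
    list(cs = SpikeTrain(d$time_s[d$label == "complex"], "complex"),
         ss = if (any(d$label == "granule"))
           SpikeTrain(d$time_s[d$label == "granule"], "granule")
         else SpikeTrain(d$time_s[d$label == "simple"], "simple"))
  })
  names(out$cells) <- sub("\\.csv$", "", basename(cellFiles))
  out
}

#' Write an image volume as multi-page TIFF
#'
#' Values are rescaled to [0, 1] (the scale is recorded in a sidecar file)
#' and written as one 32-bit float page per z-plane.
#'
#' @param volume 3D array.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeVolumeTIFF <- function(volume, path) {
  rng <- range(volume)
  sc <- if (diff(rng) > 0) (volume - rng[1]) / diff(rng) else volume * 0
  pages <- lapply(seq_len(dim(volume)[3]), function(k) sc[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  cat(sprintf("min: %g\nmax: %g\n", rng[1], rng[2]),
      file = paste0(path, ".meta"))
  invisible(path)
}

#' Read an image volume from TIFF (with optional sidecar rescaling)
#'
#' @param path TIFF path written by [writeVolumeTIFF()].
#' @return 3D array.
#' @export
readVolumeTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  vol <- simplify2array(pages)
  meta <- paste0(path, ".meta")
  if (file.exists(meta)) {
    m <- utils::read.table(meta, sep = ":", strip.white = TRUE,
                           row.names = 1)
    lo <- as.numeric(m["min", 1]); hi <- as.numeric(m["max", 1])
    vol <- vol * (hi - lo) + lo
  }
  vol
}
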
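#' Run configuration for the end-to-end pipeline
#'
#' @param seed master seed (forwarded to the generator).
#' @param outDir output directory (NULL for no file output).
#' @param stages character subset of c("synth", "extract", "behavior",
#'   "design", "fit", "classify").
#' @param generator a [generatorConfig()] (rebuilt with `seed` if omitted).
#' @param penaltyCS,penaltySS [penaltySpec()] for the CS and SS fits.
#' @param fitRate sampling rate of the design matrix and rate traces used
#'   for encoding fits, samples/s. 100 Hz resolves the 20-ms rate filter
#'   while keeping the regression tractable.
#' @param nGranule granule cells to include.
#' @return list of class "RunConfig".
#' @export
runConfig <- function(seed = 1L, outDir = NULL,
                      stages = c("synth", "extract", "behavior", "design",
                                 "fit", "classify"),
                      generator = NULL,
                      penaltyCS = penaltySpec(0.2, 0.9),
                      penaltySS = penaltySpec(0.2, 0.8),
                      fitRate = 100, nGranule = 0L) {
  if (is.null(generator)) generator <- generatorConfig(seed = seed)
  structure(list(seed = as.integer(seed), outDir = outDir, stages = stages,
                 generator = generator, penaltyCS = penaltyCS,
                 penaltySS = penaltySS, fitRate = fitRate,
                 nGranule = nGranule),
            class = "RunConfig")
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order on a synthetic session:
#' generate (synth), re-extract spikes from rendered traces (extract),
#' detect bouts and vigor from the VR envelope (behavior), build the design
#' matrices (design), fit elastic-net encoding models per cell (fit), and
#' classify phenotypes (classify). Identical config and seed give
#' identical numeric outputs.
#'
#' @param config a [runConfig()].
#' @param session optional pre-built session (required when "synth" is not
#'   among the stages).
#' @return list of class "RunManifest": `seed`, `parameters`, `session`,
#'   `bouts`, `designCS`, `designSS`, `fits` (per cell: csFit, ssFit,
#'   label), `outputs` (file paths when `outDir` given), `checksums`.
#' @export
runPipeline <- function(config = runConfig(), session = NULL) {
  st <- config$stages
  if ("synth" %in% st) {
    session <- simulateSession(config$generator, nGranule = config$nGranule)
  } else if (is.null(session))
    stop("missing input: a session is required when the synth stage is off")
  gen <- session$config
  manifest <- list(seed = config$seed,
                   parameters = list(generator = unclass(gen),
                                     penaltyCS = unclass(config$penaltyCS),
                                     penaltySS = unclass(config$penaltySS)),
                   outputs = character(0))
  manifest$session <- session
  if ("extract" %in% st) {
    # spike re-extraction sanity pass on rendered traces for the first cells
    params <- sortingParams(csThreshold = 5, ssThreshold = 1)
    manifest$extraction <- lapply(
      session$cells[seq_len(min(3, length(session$cells)))], function(cell) {
        if (is.null(cell$cs)) return(NULL)
        tr <- renderEphysTrace(cell$cs, cell$ss, rate = gen$ephysRate,
                               seed = .childSeed(gen$seed, 9000L))
        detectSpikes(tr, params)
      })
  }
  if ("behavior" %in% st) {
    if (is.null(session$behavior$vr))
      stop("missing input: VR trace required for the behavior stage")
    env <- envelopeSD(session$behavior$vr)
    manifest$bouts <- detectBouts(env)
    manifest$swimFreq <- swimFrequency(env, bouts = manifest$bouts,
                                       nShuffle = 50)
  }
  if ("design" %in% st) {
    bt <- if (!is.null(manifest$bouts)) manifest$bouts else
      session$behavior$boutTruth
    manifest$designCS <- ephysDesign(session$protocol, bt,
                                     rate = config$fitRate, target = "cs")
    manifest$designSS <- ephysDesign(session$protocol, bt,
                                     rate = config$fitRate, target = "ss")
  }
  if ("fit" %in% st) {
    if (is.null(manifest$designCS)) stop("missing input: design stage")
    dur <- protocolDuration(session$protocol)
    manifest$fits <- lapply(session$cells, function(cell) {
      out <- list(cellId = cell$cellId, phenotype = cell$phenotype)
      if (!is.null(cell$cs)) {
        yc <- rateFromTrain(cell$cs, config$fitRate, duration = dur)
        out$csFit <- fitElasticNet(yc, manifest$designCS, config$penaltyCS,
                                   standardizeY = FALSE)
        if (out$csFit@nonzeroCount == 0L)
          out$csOlsFit <- fitOLS(yc, manifest$designCS)
      }
      ys <- rateFromTrain(cell$ss, config$fitRate, duration = dur)
      out$ssFit <- fitElasticNet(ys, manifest$designSS, config$penaltySS,
                                 standardizeY = FALSE)
      out
    })
  }
  if ("classify" %in% st && !is.null(manifest$fits)) {
    # label from the sparse fit when it retains coefficients; otherwise
    # from the least-squares weights (the convention for weight heatmaps)
    manifest$fits <- lapply(manifest$fits, function(f) {
      f$label <- if (!is.null(f$csFit)) {
        if (f$csFit@nonzeroCount > 0L) classifyPhenotype(f$csFit)
        else classifyPhenotype(f$csOlsFit)
      } else "granule"
      f
    })
  }
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    manifest$outputs <- .writeRunOutputs(manifest, config$outDir)
    manifest$checksums <- tools::md5sum(manifest$outputs)
  }
  class(manifest) <- "RunManifest"
  manifest
}

.writeRunOutputs <- function(manifest, outDir) {
  paths <- character(0)
  if (!is.null(manifest$bouts)) {
    p <- file.path(outDir, "bouts.csv")
    utils::write.csv(bouts(manifest$bouts), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(manifest$fits)) {
    p <- file.path(outDir, "summary.csv")
    utils::write.csv(reportSummary(manifest), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(list(seed = manifest$seed,
                        parameters = manifest$parameters,
                        outputs = basename(paths)), p)
  c(paths, p)
}

#' Summarize a pipeline run
#'
#' Per-cell table of phenotype labels, best regressors, motor category
#' fractions, and (when ground truth is present) planted-versus-recovered
#' columns.
#'
#' @param manifest a "RunManifest" from [runPipeline()].
#' @return data.frame.
#' @export
reportSummary <- function(manifest) {
  if (is.null(manifest$fits)) stop("incomplete run: no fits present")
  catsCS <- if (!is.null(manifest$designCS))
    regressorCategories(manifest$designCS) else NULL
  rows <- lapply(manifest$fits, function(f) {
    row <- data.frame(cellId = f$cellId, label = f$label %||% NA_character_)
    if (!is.null(f$csFit)) {
      row$bestRegressor <- f$csFit@bestRegressor
      row$csR2 <- rSquared(f$csFit)
    }
    if (!is.null(f$ssFit) && !is.null(catsCS)) {
      cf <- categoryFractions(f$ssFit)
      motor <- sum(cf[names(cf) %in% c("swim", "eye")])
      row$ssMotorFraction <- motor
    }
    if (!is.null(f$phenotype)) {
      row$planted <- f$phenotype
      if (!is.null(row$label)) row$recovered <- row$label == f$phenotype
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.RunManifest <- function(x, ...) {
  cat(sprintf("RunManifest (seed %d): stages %s\n", x$seed,
              paste(names(x)[names(x) %in% c("session", "extraction",
                                             "bouts", "designCS", "fits")],
                    collapse = ", ")))
  invisible(x)
}
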
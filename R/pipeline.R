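#' Describe a generation job
#'
#' @param checkpointPath path to a checkpoint written by
#'   \code{\link{saveCheckpoint}} (or by \code{\link{scganTrain}}).
#' @param allocation an \linkS4class{AllocationTable}.
#' @param outDir output dataset directory.
#' @param seed integer seed; each image's noise is drawn from a stream
#'   derived from it by image index, so datasets are bit-reproducible.
#' @param batchSize generation batch size.
#' @return A list of class `"GenerationJob"`.
#' @export
generationJob <- function(checkpointPath, allocation, outDir, seed = 1L,
                          batchSize = 16L) {
  stopifnot(is(allocation, "AllocationTable"))
  if (sum(allocation@medium) + sum(allocation@dark) <= 0)
    stop("allocation totals must be positive")
  structure(list(checkpointPath = checkpointPath, allocation = allocation,
                 outDir = outDir, seed = as.integer(seed),
                 batchSize = as.integer(batchSize)),
            class = "GenerationJob")
}

.noise_for_index <- function(idx, seed, config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer((as.numeric(seed) * 48271 + idx * 16807) %% 2147483647))
  sampleNoise(1L, config)
}

#' Run dataset generation from a trained checkpoint
#'
#' For each tone, generates exactly `allocation[tone][class]` images per
#' lesion class with that tone's conditioning, blends them with that tone's
#' tint, and writes the PNG tree plus manifest via
#' \code{\link{writePngDataset}}. Lesion labels are attached by filling the
#' allocation's buckets from a single generation stream per tone: label
#' assignment is proportional bookkeeping, independent of image content.
#'
#' @param job a \code{\link{generationJob}}.
#' @return The manifest `data.frame` (columns `filename`, `class`, `tone`,
#'   `seed_index`).
#' @export
runGeneration <- function(job) {
  stopifnot(inherits(job, "GenerationJob"))
  ck <- loadCheckpoint(job$checkpointPath)
  gen <- ck$generator
  cfg <- gen@config
  al <- job$allocation
  res <- cfg$resolution

  counts <- list(medium = al@medium, dark = al@dark)
  total <- sum(al@medium) + sum(al@dark)
  vals <- array(0, c(res, res, 3L, total))
  labs <- character(total); tns <- character(total)
  k <- 0L; seedIdx <- integer(total)
  gidx <- 0L                     # global image index -> noise stream
  for (tone in toneLevels()) {
    ct <- counts[[tone]]
    tint <- tintSpec(tone)
    for (ci in seq_along(al@classNames)) {
      nci <- ct[ci]
      while (nci > 0L) {
        m <- min(nci, job$batchSize)
        z <- array(0, c(res, res, cfg$noise_channels, m))
        si <- integer(m)
        for (j in seq_len(m)) {
          gidx <- gidx + 1L
          si[j] <- gidx
          z[, , , j] <- .noise_for_index(gidx, job$seed, cfg)
        }
        img <- scganGenerate(gen, z, rep(tone, m))
        img <- blendTone(toUnitRange(img), tint)
        vals[, , , k + seq_len(m)] <- imageValues(img)
        labs[k + seq_len(m)] <- al@classNames[ci]
        tns[k + seq_len(m)] <- tone
        seedIdx[k + seq_len(m)] <- si
        k <- k + m
        nci <- nci - m
      }
    }
  }
  manifest <- writePngDataset(ImageBatch(vals, "unit"), labs, tns, job$outDir)
  manifest$seed_index <- seedIdx
  utils::write.csv(manifest, file.path(job$outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Full source-to-synthetic dataset build
#'
#' Wires the whole pipeline: load (or simulate) a source dataset, normalise,
#' train the tone-conditioned GAN, derive the proportional allocation from
#' the source class counts, generate and blend, and write images, manifest,
#' loss log and a config snapshot.
#'
#' @param sourceDir folder-per-class source dataset; when `NULL`, the
#'   fixture simulator provides the source.
#' @param outDir output directory.
#' @param totalPerTone synthetic images per tone.
#' @param genConfig \code{\link{generatorConfig}}.
#' @param trainCfg \code{\link{trainConfig}}.
#' @param fixtureCfg \code{\link{fixtureConfig}} used when `sourceDir` is
#'   `NULL`.
#' @param tintFixtures blend fixture source images with their tone's tint
#'   before training (gives the discriminator a real tone signal to learn);
#'   ignored when `sourceDir` is given.
#' @param verbose log training progress.
#' @return List with `manifest`, `history`, `allocation`, `checkpointPath`.
#' @export
fullBuild <- function(sourceDir = NULL, outDir, totalPerTone = 20L,
                      genConfig = generatorConfig(resolution = 32L,
                                                  base_width = 16L),
                      trainCfg = trainConfig(epochs = 5L, batch_size = 1L),
                      fixtureCfg = fixtureConfig(resolution = genConfig$resolution),
                      tintFixtures = TRUE, verbose = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(sourceDir)) {
    src <- simulateDataset(fixtureCfg)
    if (tintFixtures) src <- blendDatasetByTone(src)
    raw <- ImageBatch(round(imageValues(images(src)) * 255), "raw_u8")
    src <- LabeledImageSet(raw, lesionLabels(src),
                           classNames = classNames(src),
                           tones = as.character(tones(src)))
  } else {
    src <- loadLabeledImages(sourceDir, genConfig$resolution)
  }
  norm <- LabeledImageSet(normalizeImage(images(src)), lesionLabels(src),
                          classNames = classNames(src),
                          tones = if (length(tones(src))) as.character(tones(src)))

  set.seed(trainCfg$seed)
  gen <- scganGenerator(genConfig)
  disc <- scganDiscriminator(genConfig)
  ckPath <- file.path(outDir, "checkpoint.rds")
  fit <- scganTrain(gen, disc, norm, trainCfg, checkpointPath = ckPath,
                    verbose = verbose)

  alloc <- buildAllocation(datasetClassCounts(src), totalPerTone)
  writeAllocationCsv(alloc, file.path(outDir, "allocation.csv"))
  utils::write.csv(fit$history, file.path(outDir, "loss_log.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(generator = genConfig,
                        training = trainCfg,
                        total_per_tone = as.integer(totalPerTone),
                        source = if (is.null(sourceDir)) "fixture" else sourceDir),
                   file.path(outDir, "config.yaml"))

  job <- generationJob(ckPath, alloc, file.path(outDir, "images"),
                       seed = trainCfg$seed)
  manifest <- runGeneration(job)
  list(manifest = manifest, history = fit$history, allocation = alloc,
       checkpointPath = ckPath, discriminator = fit$discriminator,
       source = src)
}
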
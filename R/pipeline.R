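# Dataset bookkeeping and the end-to-end pipeline runner.

#' Split a dataset into train/validation/test sets
#'
#' Seeded shuffle followed by contiguous assignment with largest-remainder
#' rounding (so 10 entries at 70/15/15 give 7/2/1, remainder ties resolved
#' in train, val, test order). Assignment is per image: all objects of an
#' image inherit its split, which prevents leakage between sets.
#'
#' @param entries data.frame with columns `image` and optionally `mask`, or
#'   a character vector of image paths.
#' @param fractions positive split fractions summing to 1 (default
#'   `c(train = 0.70, val = 0.15, test = 0.15)`).
#' @param seed integer shuffle seed.
#' @return data.frame manifest with columns `image`, `mask`, `split`;
#'   attributes `fractions` and `seed`.
#' @examples
#' m <- splitDataset(sprintf("img%03d.png", 1:10), seed = 1)
#' table(m$split)
#' @export
splitDataset <- function(entries, fractions = c(train = 0.70, val = 0.15,
                                                test = 0.15), seed = 1L) {
  if (is.character(entries))
    entries <- data.frame(image = entries, mask = NA_character_)
  stopifnot(is.data.frame(entries), "image" %in% names(entries))
  if (!"mask" %in% names(entries)) entries$mask <- NA_character_
  n <- nrow(entries)
  if (n < 3L) stop("need at least 3 entries to split")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("'fractions' must be 3 positive values summing to 1")
  if (is.null(names(fractions))) names(fractions) <- c("train", "val", "test")
  # largest-remainder apportionment
  exact <- fractions * n
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(-(exact - counts), seq_along(exact))  # ties: train, val, test
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  perm <- withSeed(seed, sample.int(n))
  split <- rep(names(fractions), counts)[order(perm)]
  out <- data.frame(image = entries$image, mask = entries$mask, split = split)
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- as.integer(seed)
  out
}

# Validate a pipeline configuration before doing any work.
validatePipelineConfig <- function(config) {
  known <- c("simulate", "segment", "features", "select", "evaluate", "split")
  if (is.null(config$stages) || !length(config$stages))
    stop("config must list at least one stage in 'stages'")
  bad <- setdiff(unlist(config$stages), known)
  if (length(bad))
    stop(sprintf("unknown stage(s): %s (known: %s)",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  if (is.null(config$seed)) stop("config must set 'seed'")
  if ("simulate" %in% config$stages) {
    s <- config$simulate
    if (is.null(s$n) || s$n < 1) stop("simulate stage needs 'n' >= 1")
  }
  if ("segment" %in% config$stages) {
    m <- config$segment$method %||% "otsu"
    if (!m %in% listSegmenters())
      stop(sprintf("unknown segmentation method '%s' (registered: %s)", m,
                   paste(listSegmenters(), collapse = ", ")))
  }
  invisible(TRUE)
}

logLine <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Run the configured pipeline end to end
#'
#' Executes the configured stages in order — simulate (benchmark scene
#' generation), segment, features, select, evaluate — writing all artifacts
#' under `outDir` together with a JSON-lines run log (package version,
#' seeds, parameters, per-stage timing). The configuration is validated
#' before any work starts; identical configurations produce byte-identical
#' feature and curve CSVs.
#'
#' Config fields (R list or JSON file): `stages` (character vector),
#' `seed`; `simulate$n`, `simulate$profile`; `segment$method`,
#' `segment$filters` (list of [objectFilterParams()] arguments);
#' `select$criteria` (list as in [readSelectionCriteria()]'s JSON shape);
#' `evaluate$taus`.
#'
#' @param config configuration list or path to a JSON file.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list of in-memory stage results.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  validatePipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logCon <- file(file.path(outDir, "run_log.jsonl"), open = "wt")
  on.exit(close(logCon))
  logLine(logCon, "start",
          package_version = as.character(utils::packageVersion("spheropick")),
          seed = config$seed, stages = config$stages)
  res <- list()
  stages <- unlist(config$stages)
  tic <- function() proc.time()[["elapsed"]]
  if ("simulate" %in% stages) {
    t0 <- tic()
    s <- config$simulate
    res$set <- makeBenchmarkSet(s$n, profile = s$profile %||% "default",
                                seed = config$seed)
    imgDir <- file.path(outDir, "images"); mskDir <- file.path(outDir, "masks")
    dir.create(imgDir, showWarnings = FALSE); dir.create(mskDir, showWarnings = FALSE)
    for (i in seq_along(res$set)) {
      writeCalibratedImage(res$set[[i]]$image,
                           file.path(imgDir, sprintf("scene_%03d.tif", i)))
      writeLabelMask(res$set[[i]]$mask,
                     file.path(mskDir, sprintf("scene_%03d_mask.tif", i)))
      writeSceneSpec(res$set[[i]]$scene,
                     file.path(mskDir, sprintf("scene_%03d_spec.json", i)))
    }
    logLine(logCon, "simulate", n = s$n, profile = s$profile %||% "default",
            elapsed_s = round(tic() - t0, 3))
  }
  if ("segment" %in% stages) {
    t0 <- tic()
    method <- config$segment$method %||% "otsu"
    filters <- do.call(objectFilterParams,
                       as.list(config$segment$filters %||% list()))
    res$pred <- lapply(res$set, function(e)
      runSegmenter(method, e$image, filters = filters))
    predDir <- file.path(outDir, "predictions")
    dir.create(predDir, showWarnings = FALSE)
    for (i in seq_along(res$pred))
      writeLabelMask(res$pred[[i]],
                     file.path(predDir, sprintf("scene_%03d_pred.tif", i)))
    logLine(logCon, "segment", method = method,
            n_objects = sum(vapply(res$pred, nObjects, integer(1))),
            elapsed_s = round(tic() - t0, 3))
  }
  if ("features" %in% stages) {
    t0 <- tic()
    src <- res$pred %||% lapply(res$set, `[[`, "mask")
    feats <- lapply(seq_along(src), function(i) {
      f <- extractFeatures(src[[i]])
      if (nrow(f)) cbind(image = i, f) else NULL
    })
    res$features <- do.call(rbind, feats)
    writeFeatures(res$features, file.path(outDir, "features.csv"))
    logLine(logCon, "features", n_records = nrow(res$features),
            elapsed_s = round(tic() - t0, 3))
  }
  if ("select" %in% stages) {
    t0 <- tic()
    critList <- config$select$criteria %||% list()
    preferred <- critList$preferred; critList$preferred <- NULL
    maxCount <- critList$max_count; critList$max_count <- NULL
    args <- lapply(critList, function(iv) c(
      if (is.null(iv$min)) NA_real_ else as.numeric(iv$min),
      if (is.null(iv$max)) NA_real_ else as.numeric(iv$max)))
    crit <- do.call(selectionCriteria,
                    c(args, list(preferred = preferred, maxCount = maxCount)))
    res$selection <- applyCriteria(res$features, crit)
    writeFeatures(selected(res$selection), file.path(outDir, "selected.csv"))
    jsonlite::write_json(
      list(n_selected = nrow(selected(res$selection)),
           n_rejected = nrow(rejected(res$selection)),
           summary = selectionSummary(res$selection)),
      file.path(outDir, "selection_report.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
    logLine(logCon, "select", n_selected = nrow(selected(res$selection)),
            elapsed_s = round(tic() - t0, 3))
  }
  if ("evaluate" %in% stages) {
    t0 <- tic()
    taus <- config$evaluate$taus %||% seq(0.5, 0.95, by = 0.05)
    pairs <- lapply(seq_along(res$set), function(i)
      list(pred = res$pred[[i]], gt = res$set[[i]]$mask))
    res$curve <- evaluateDataset(pairs, taus = taus,
                                 scope = config$evaluate$scope %||% "pooled")
    utils::write.csv(curveData(res$curve),
                     file.path(outDir, "evaluation.csv"), row.names = FALSE)
    logLine(logCon, "evaluate",
            sensitivity_at_first_tau = curveData(res$curve)$sensitivity[1],
            elapsed_s = round(tic() - t0, 3))
  }
  logLine(logCon, "done")
  invisible(res)
}
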
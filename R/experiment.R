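#' @importFrom rlang .data
NULL

#' Save / load an encoder checkpoint
#'
#' A checkpoint bundles the encoder weights with the architecture
#' configuration so it can be rebuilt faithfully.
#'
#' @param encoder An \code{\linkS4class{Encoder}}.
#' @param path Destination file.
#' @return \code{saveCheckpoint} returns the path invisibly;
#'   \code{loadCheckpoint} returns the \code{\linkS4class{Encoder}}.
#' @export
saveCheckpoint <- function(encoder, path) {
  saveRDS(list(config = encoder@config, params = nnParams(encoder@net),
               buffers = nnBuffers(encoder@net)), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(encoderConfig, ck$config[c("arch", "featureDim",
                                            "numBnSplits", "cifarRecipe",
                                            "l2NormalizeOutput",
                                            "simclrStem")])
  enc <- buildEncoder(cfg, seed = 0L)
  enc@net <- nnSetParams(enc@net, ck$params)
  enc@net <- nnSetBuffers(enc@net, ck$buffers)
  enc
}

# Batch-norm running statistics, flattened like nnParams().
nnBuffers <- function(mod, prefix = "") {
  out <- list()
  if (!is.null(mod$children)) {
    for (i in seq_along(mod$children))
      out <- c(out, nnBuffers(mod$children[[i]], paste0(prefix, i, "/")))
  } else if (!is.null(mod$main)) {
    out <- c(out, nnBuffers(mod$main, paste0(prefix, "main/")))
    if (!is.null(mod$shortcut))
      out <- c(out, nnBuffers(mod$shortcut, paste0(prefix, "shortcut/")))
  } else if (inherits(mod, "nn_bn")) {
    out[[paste0(prefix, "runningMean")]] <- mod$runningMean
    out[[paste0(prefix, "runningVar")]] <- mod$runningVar
  }
  out
}

nnSetBuffers <- function(mod, flat, prefix = "") {
  if (!is.null(mod$children)) {
    for (i in seq_along(mod$children))
      mod$children[[i]] <- nnSetBuffers(mod$children[[i]], flat,
                                        paste0(prefix, i, "/"))
  } else if (!is.null(mod$main)) {
    mod$main <- nnSetBuffers(mod$main, flat, paste0(prefix, "main/"))
    if (!is.null(mod$shortcut))
      mod$shortcut <- nnSetBuffers(mod$shortcut, flat,
                                   paste0(prefix, "shortcut/"))
  } else if (inherits(mod, "nn_bn")) {
    rm_ <- flat[[paste0(prefix, "runningMean")]]
    rv <- flat[[paste0(prefix, "runningVar")]]
    if (!is.null(rm_)) mod$runningMean <- rm_
    if (!is.null(rv)) mod$runningVar <- rv
  }
  mod
}

#' Plot a training history CSV
#'
#' Writes one PNG per numeric series (beyond the epoch column) found in a
#' history CSV with an \code{epoch} column, e.g. \code{train_loss} and
#' \code{knn_accuracy_pct}.
#'
#' @param csvPath Path to the history CSV.
#' @param outDir Output directory (default: the CSV's directory).
#' @return Character vector of written PNG paths.
#' @export
plotHistory <- function(csvPath, outDir = dirname(csvPath)) {
  h <- utils::read.csv(csvPath)
  if (nrow(h) == 0 || !"epoch" %in% names(h))
    stop("history CSV must be non-empty with an 'epoch' column")
  series <- setdiff(names(h), "epoch")
  if (length(series) == 0) stop("history CSV has no data series")
  out <- character(0)
  for (s in series) {
    p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data[[s]])) +
      ggplot2::geom_line(color = "steelblue") +
      ggplot2::labs(x = "epoch", y = s) +
      ggplot2::theme_minimal()
    f <- file.path(outDir, paste0(tools::file_path_sans_ext(
      basename(csvPath)), "_", s, ".png"))
    ggplot2::ggsave(f, p, width = 5, height = 3.5, dpi = 120)
    out <- c(out, f)
  }
  out
}

#' Run a configured experiment end to end
#'
#' Executes the pipelines named in \code{config$tasks} -- any of
#' \code{"generate_data"}, \code{"train_moco"}, \code{"train_simclr"},
#' \code{"train_supervised"}, \code{"evaluate"}, \code{"embed"},
#' \code{"compare"} -- against a synthetic or on-disk dataset, writing a
#' resolved config snapshot, a log file, history CSVs, checkpoints, reports
#' and plots into a run directory. All randomness derives from
#' \code{config$seed}.
#'
#' @param config Nested configuration list, or path to a YAML file with the
#'   same structure. Recognized blocks: \code{seed}, \code{outDir},
#'   \code{tasks}, \code{data} (source = "synthetic" or "directory" plus
#'   generator / loader arguments), \code{encoder}, \code{moco},
#'   \code{simclr}, \code{supervised}, \code{knn}.
#' @return The run directory path, invisibly.
#' @export
runExperiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- if (is.null(config$outDir)) tempfile("run_") else config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "log.txt")
  logln <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                             "\n", file = logFile, append = TRUE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  tasks <- config$tasks
  if (is.null(tasks)) tasks <- c("train_moco", "evaluate")

  # --- data ---------------------------------------------------------------
  dataCfg <- config$data
  if (is.null(dataCfg$source)) dataCfg$source <- "synthetic"
  if (dataCfg$source == "synthetic") {
    args <- dataCfg[intersect(names(dataCfg),
                              names(formals(syntheticConfig)))]
    if (is.null(args$seed)) args$seed <- seed
    sCfg <- do.call(syntheticConfig, args)
    dataDir <- if ("generate_data" %in% tasks)
      file.path(outDir, "data") else NULL
    logln("generating synthetic dataset:", sCfg$nClasses, "classes x",
          sCfg$nPerClass)
    dataset <- generateSyntheticEmotionDataset(sCfg, dataDir)
  } else {
    logln("loading dataset from", dataCfg$dir)
    dataset <- loadImageDataset(dataCfg$dir,
                                testFraction = dataCfg$testFraction %||% 0.2,
                                seed = seed)
  }

  encArgs <- config$encoder %||% list()
  encCfg <- do.call(encoderConfig, encArgs)

  # --- pipelines ----------------------------------------------------------
  if ("train_moco" %in% tasks || "evaluate" %in% tasks ||
      "compare" %in% tasks) {
    mocoArgs <- config$moco %||% list()
    if (is.null(mocoArgs$seed)) mocoArgs$seed <- seed
    mocoCfg <- do.call(mocoTrainConfig, mocoArgs)
  }
  mocoRes <- NULL
  if ("train_moco" %in% tasks) {
    logln("training momentum-contrast encoder:", encCfg$arch,
          "epochs", mocoCfg$epochs)
    mocoRes <- trainMoCo(dataset, encCfg, mocoCfg)
    utils::write.csv(mocoRes$history,
                     file.path(outDir, "moco_history.csv"),
                     row.names = FALSE)
    saveCheckpoint(mocoRes$encoder, file.path(outDir, "moco_encoder.rds"))
    plotHistory(file.path(outDir, "moco_history.csv"), outDir)
  }
  if ("evaluate" %in% tasks && !is.null(mocoRes)) {
    knnArgs <- config$knn %||% list()
    knnCfg <- knnConfig(k = knnArgs$k %||% mocoCfg$knnK,
                        temperature = knnArgs$temperature %||%
                          mocoCfg$knnTemperature,
                        numClasses = nClasses(dataset))
    te <- testIndices(dataset)
    tr <- trainIndices(dataset)
    labels <- imageLabels(dataset)
    bank <- memoryBank(encodeImages(mocoRes$encoder, dataset, tr,
                                    mocoCfg$imageResolution),
                       labels[tr], nClasses(dataset))
    qf <- encodeImages(mocoRes$encoder, dataset, te,
                       mocoCfg$imageResolution)
    pred <- knnPredict(qf, bank, knnCfg)
    rep <- classificationReport(pred$labels, labels[te],
                                classNames(dataset))
    logln(sprintf("knn accuracy: %.2f%%", rep@accuracy))
    utils::write.csv(rep@perClass,
                     file.path(outDir, "knn_classification_report.csv"),
                     row.names = FALSE)
  }
  if ("train_simclr" %in% tasks) {
    simArgs <- config$simclr %||% list()
    if (is.null(simArgs$seed)) simArgs$seed <- seed
    simCfg <- do.call(simclrConfig, simArgs)
    logln("training SimCLR-style encoder, epochs", simCfg$totalEpochs)
    simRes <- trainSimCLR(dataset, simCfg)
    utils::write.csv(simRes$history,
                     file.path(outDir, "simclr_history.csv"),
                     row.names = FALSE)
    plotHistory(file.path(outDir, "simclr_history.csv"), outDir)
    if ("embed" %in% tasks) {
      tr <- trainIndices(dataset)
      f <- encodeImages(simRes$encoder, dataset, tr, simCfg$inputSize)
      emb <- tsneEmbed(f, perplexity = min(simCfg$tsnePerplexity,
                                           (length(tr) - 1) / 3 - 1),
                       seed = seed)
      utils::write.csv(data.frame(index = tr,
                                  label = imageLabels(dataset)[tr],
                                  x = emb[, 1], y = emb[, 2]),
                       file.path(outDir, "tsne.csv"), row.names = FALSE)
    }
  }
  if ("train_supervised" %in% tasks) {
    supArgs <- config$supervised %||% list()
    if (is.null(supArgs$seed)) supArgs$seed <- seed
    supCfg <- do.call(supervisedConfig, supArgs)
    logln("training supervised baseline:", supCfg$arch)
    supRes <- trainSupervised(dataset, supCfg)
    utils::write.csv(supRes$history,
                     file.path(outDir, "supervised_history.csv"),
                     row.names = FALSE)
    utils::write.csv(supRes$report@perClass,
                     file.path(outDir, "supervised_report.csv"),
                     row.names = FALSE)
    plotHistory(file.path(outDir, "supervised_history.csv"), outDir)
  }
  if ("compare" %in% tasks) {
    supArgs <- config$supervised %||% list()
    if (is.null(supArgs$seed)) supArgs$seed <- seed
    supCfg <- do.call(supervisedConfig, supArgs)
    logln("running supervised vs momentum-contrast comparison")
    cmp <- compareSupervisedVsUnsupervised(dataset, supCfg, encCfg, mocoCfg)
    utils::write.csv(cmp, file.path(outDir, "comparison.csv"),
                     row.names = FALSE)
  }
  logln("done")
  invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
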
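# Configuration resolution and pipeline orchestration.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its explicit default, in one place.
#' [resolveRunConfig()] merges a config file and overrides on top of these, so
#' a resolved configuration never contains implicit values.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    stages = c("simulate", "classify"),
    seed = 1,
    outDir = NULL,
    logLevel = "info",
    simulate = list(
      nPerClass = 10,
      classes = .cleftClasses,
      params = list(
        matrixLateralSD = 10, clusterSD = 50, nEmittersPerChannel = 100,
        blinksPerEmitter = 2, precisionSD = 15
      )
    ),
    classify = list(
      manifest = NULL,
      pixelSize = 5,
      params = list(
        thetaIn = 50, thetaNear = 100, thetaDiff = 100,
        presenceMin = 10, windowRadius = 300, blurRadius = 2.00,
        profileWidth = 5
      )
    ),
    coloc = list(
      image = NULL,
      phantom = NULL,
      params = list(
        tA = 25, tB = 25, rho = 0.10, connectivity = 8,
        minParticleSize = 1, ratioFloor = 1
      ),
      dapiThreshold = 1,
      nRois = 10,
      roiDiameter = 100,
      pixelSize = 0.1563257
    ),
    stats = list(a = NULL, b = NULL, alpha = 0.05)
  )
}

#' Resolve a pipeline configuration
#'
#' Merge order: package defaults, then a YAML config file, then in-memory
#' overrides; later sources win, merging recursively by name. Validation is
#' fail-fast: stage names and the parameter blocks of the requested stages are
#' checked before any computation.
#'
#' @param file optional YAML configuration path.
#' @param overrides optional nested list of overrides (e.g. from CLI flags).
#' @return resolved configuration list.
#' @export
resolveRunConfig <- function(file = NULL, overrides = list()) {
  cfg <- defaultRunConfig()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    cfg <- .mergeConfig(cfg, yaml::read_yaml(file))
  }
  cfg <- .mergeConfig(cfg, overrides)
  unknown <- setdiff(cfg$stages, c("simulate", "classify", "coloc", "stats"))
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  if ("classify" %in% cfg$stages && !"simulate" %in% cfg$stages &&
      is.null(cfg$classify$manifest)) {
    stop("classify without simulate requires classify$manifest")
  }
  if ("stats" %in% cfg$stages && (is.null(cfg$stats$a) || is.null(cfg$stats$b))) {
    stop("stats stage requires both samples (stats$a, stats$b)")
  }
  # construct the parameter objects now so invalid values fail before any work
  do.call(CleftClassParams, cfg$classify$params)
  do.call(ColocParams, cfg$coloc$params)
  cfg
}

.mergeConfig <- function(base, upd) {
  if (is.null(upd)) return(base)
  for (nm in names(upd)) {
    if (is.list(upd[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(upd[[nm]]))) {
      base[[nm]] <- .mergeConfig(base[[nm]], upd[[nm]])
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

#' Run the pipeline
#'
#' Executes the configured stages and returns a single report keyed by stage;
#' with \code{outDir} set, results and the resolved configuration are also
#' written via [writeResults()]. Reruns with identical configuration and seed
#' produce identical reports.
#'
#' Stages: \code{simulate} generates a labeled synthetic synapse batch;
#' \code{classify} analyzes the simulated batch (or a manifest of localization
#' CSVs) and aggregates the class distribution; \code{coloc} quantifies a
#' section image (a TIFF path, or a phantom simulated from
#' \code{coloc$phantom} parameters); \code{stats} runs the gated two-group
#' comparison on two numeric vectors or single-column CSV paths.
#'
#' @param config resolved configuration from [resolveRunConfig()], a YAML
#'   path, or an overrides list.
#' @return report list with one entry per executed stage plus \code{config}.
#' @examples
#' rep <- runPipeline(list(
#'   stages = c("simulate", "classify"),
#'   simulate = list(nPerClass = 2, classes = c("IN_CLEFT", "ABSENT"))
#' ))
#' rep$classify$distribution
#' @export
runPipeline <- function(config = list()) {
  cfg <- if (is.character(config)) resolveRunConfig(file = config)
         else if (!is.null(config$..resolved)) config
         else resolveRunConfig(overrides = config)
  cfg$..resolved <- TRUE
  report <- list()
  sims <- NULL
  .log(cfg, "starting stages: %s", paste(cfg$stages, collapse = ", "))

  if ("simulate" %in% cfg$stages) {
    sc <- cfg$simulate
    classes <- rep(sc$classes, each = sc$nPerClass)
    sims <- do.call(simulateSynapseBatch,
                    c(list(classes = classes, baseSeed = cfg$seed), sc$params))
    report$simulate <- list(
      n = length(sims),
      truthLabels = vapply(sims, function(s) truthLabel(s$truth), character(1))
    )
    .log(cfg, "simulated %d synapses", length(sims))
  }

  if ("classify" %in% cfg$stages) {
    cc <- cfg$classify
    params <- do.call(CleftClassParams, cc$params)
    rois <- if (!is.null(sims)) sims else {
      manifest <- utils::read.csv(cc$manifest, stringsAsFactors = FALSE)
      if (!"file" %in% names(manifest)) stop("manifest needs a 'file' column")
      lapply(manifest$file, function(f) {
        SynapseROI(localizations = readLocalizationTable(f),
                   pixelSize = cc$pixelSize)
      })
    }
    meas <- tryCatch(
      analyzeSynapses(rois, params, pixelSize = cc$pixelSize),
      error = function(e) stop("stage 'classify': ", conditionMessage(e))
    )
    dist <- aggregateDistribution(meas$cleft_class)
    report$classify <- list(
      measurements = meas,
      distribution = dist,
      n = attr(dist, "n")
    )
    .log(cfg, "classified %d synapses", nrow(meas))
  }

  if ("coloc" %in% cfg$stages) {
    oc <- cfg$coloc
    img <- if (!is.null(oc$image)) {
      a <- readImageStack(oc$image)
      dimnames(a) <- list(NULL, NULL, c("dapi", "markerA", "markerB"))
      attr(a, "pixelSize") <- oc$pixelSize
      a
    } else {
      ph <- simulateConfocalSection(do.call(
        ConfocalPhantomParams,
        .mergeConfig(list(seed = cfg$seed), oc$phantom)
      ))
      ph$image
    }
    q <- tryCatch(
      quantifySection(img, do.call(ColocParams, oc$params),
                      dapiThreshold = oc$dapiThreshold, nRois = oc$nRois,
                      roiDiameter = oc$roiDiameter,
                      pixelSize = attr(img, "pixelSize"), seed = cfg$seed),
      error = function(e) stop("stage 'coloc': ", conditionMessage(e))
    )
    report$coloc <- list(rois = q$rois, perRoi = q$perRoi)
    .log(cfg, "quantified %d edge ROIs", nrow(q$rois))
  }

  if ("stats" %in% cfg$stages) {
    sc <- cfg$stats
    readCol <- function(x) {
      if (is.character(x) && length(x) == 1 && file.exists(x)) {
        utils::read.csv(x)[[1]]
      } else as.numeric(x)
    }
    g <- compareGroups(readCol(sc$a), readCol(sc$b), alpha = sc$alpha)
    report$stats <- list(
      nA = g@nA, nB = g@nB, shapiroPA = g@shapiroPA, shapiroPB = g@shapiroPB,
      test = g@test, statistic = g@statistic, pValue = g@pValue,
      alpha = g@alpha
    )
    .log(cfg, "stats: %s test, p = %.4g", g@test, g@pValue)
  }

  cfg$..resolved <- NULL
  report$config <- cfg
  if (!is.null(cfg$outDir)) {
    objects <- list()
    if (!is.null(report$classify)) {
      objects$measurements <- report$classify$measurements
      objects$distribution <- report$classify$distribution
    }
    if (!is.null(report$coloc)) objects$coloc_per_roi <- report$coloc$perRoi
    if (!is.null(report$stats)) objects$stats <- report$stats
    writeResults(cfg$outDir, objects, config = cfg)
  }
  report
}

.log <- function(cfg, fmt, ...) {
  lvl <- if (is.null(cfg$logLevel)) "info" else cfg$logLevel
  if (lvl %in% c("info", "debug")) {
    message(sprintf(paste0("[cleftQuant] ", fmt), ...))
  }
}
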
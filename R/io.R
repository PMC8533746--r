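# Readers and writers for the pipeline's file formats.

#' Read a localization table from CSV
#'
#' Expects the canonical header \code{channel,x_nm,y_nm,z_nm,frame,photons}
#' (one row per localization); unknown extra columns are retained. Any
#' non-parseable numeric field raises an error naming the offending row and
#' column before any analysis runs.
#'
#' @param path CSV file path.
#' @return a [LocalizationTable-class]; a header-only file yields an empty
#'   table.
#' @seealso [writeLocalizationTable()]
#' @export
readLocalizationTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(.locColumns, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("x_nm", "y_nm", "z_nm", "frame", "photons")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at data row %d: \"%s\"",
                   col, bad[1], df[[col]][bad[1]]))
    }
    df[[col]] <- v
  }
  LocalizationTable(df)
}

#' Write a localization table to CSV
#'
#' @param table a [LocalizationTable-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeLocalizationTable <- function(table, path) {
  stopifnot(is(table, "LocalizationTable"))
  utils::write.csv(locData(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as an image array
#'
#' One page per channel; integer sample values are preserved.
#'
#' @param path TIFF path.
#' @return integer array \code{nx x ny x nchannel} with attribute
#'   \code{bitsPerSample}.
#' @seealso [writeImageStack()]
#' @export
readImageStack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1)))) {
    stop("TIFF pages have differing shapes")
  }
  out <- array(0L, c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) out[, , k] <- as.integer(pages[[k]])
  attr(out, "bitsPerSample") <- attr(pages[[1]], "bits.per.sample")
  out
}

#' Write an image array as a multi-page TIFF
#'
#' @param image integer matrix or \code{nx x ny x nchannel} array of
#'   non-negative integers within the sample depth.
#' @param path output TIFF path.
#' @param bitsPerSample 8 or 16.
#' @return the path, invisibly.
#' @export
writeImageStack <- function(image, path, bitsPerSample = 8) {
  if (!bitsPerSample %in% c(8, 16)) stop("bitsPerSample must be 8 or 16")
  top <- 2^bitsPerSample - 1
  pages <- if (is.matrix(image)) list(image) else {
    lapply(seq_len(dim(image)[3]), function(k) image[, , k])
  }
  if (any(vapply(pages, function(p) any(p < 0 | p > top), logical(1)))) {
    stop("pixel values outside the sample depth")
  }
  tiff::writeTIFF(lapply(pages, function(p) p / top), path,
                  bits.per.sample = bitsPerSample)
  invisible(path)
}

#' Write pipeline results with their provenance
#'
#' Writes each element of \code{objects} under its name (data.frames as CSV,
#' everything else as JSON) plus a \code{config.json} holding the resolved
#' configuration and the package version, so every output is reproducible from
#' the directory contents alone. File naming is deterministic.
#'
#' @param dir output directory (created if needed).
#' @param objects named list of results.
#' @param config resolved configuration list to serialize alongside.
#' @return character vector of written paths, invisibly.
#' @export
writeResults <- function(dir, objects, config = list()) {
  stopifnot(is.list(objects), length(names(objects)) == length(objects))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (is.data.frame(obj)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(obj, p, row.names = FALSE)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    paths <- c(paths, p)
  }
  meta <- list(
    config = config,
    software = list(
      package = "cleftQuant",
      version = as.character(utils::packageVersion("cleftQuant"))
    )
  )
  p <- file.path(dir, "config.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(c(paths, p))
}
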
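#' Read an SBS image stack from a per-FOV directory
#'
#' The on-disk layout is one single-plane 16-bit TIFF per (cycle, channel),
#' named `c{cycle:02d}_{channel}.tif` (e.g. `c01_DAPI.tif`, `c07_A.tif`),
#' plus a `fov.json` file with the stage metadata. Cycles are returned sorted
#' ascending, channels in the canonical order DAPI, G, T, A, C. Intensities
#' are stored as 16-bit unsigned integers on disk and converted to doubles on
#' load.
#'
#' @param stack_dir Directory containing the TIFFs and `fov.json`.
#' @return An [SBSImageStack-class].
#' @seealso [writeImageStack()], [validateStackDir()]
#' @export
readImageStack <- function(stack_dir) {
  fov <- readFOVMetadata(file.path(stack_dir, "fov.json"))
  tifs <- list.files(stack_dir, pattern = "^c[0-9]{2}_[A-Za-z]+\\.tif$")
  if (!length(tifs)) stopWithPath(stack_dir, "inconsistent stack: no TIFFs found")
  cyc <- as.integer(sub("^c([0-9]{2})_.*", "\\1", tifs))
  ch <- sub("^c[0-9]{2}_([A-Za-z]+)\\.tif$", "\\1", tifs)
  bad <- setdiff(unique(ch), SBS_CHANNELS)
  if (length(bad))
    stopWithPath(stack_dir, paste0("bad layout: unknown channel label '",
                                   bad[1], "'"))
  cycles <- sort(unique(cyc))
  px <- NULL
  for (ci in seq_along(cycles)) {
    for (ki in seq_along(SBS_CHANNELS)) {
      f <- file.path(stack_dir,
                     sprintf("c%02d_%s.tif", cycles[ci], SBS_CHANNELS[ki]))
      if (!file.exists(f))
        stopWithPath(f, "inconsistent stack: missing file")
      m <- tiff::readTIFF(f, as.is = TRUE)
      if (is.null(px)) {
        px <- array(0, dim = c(length(cycles), length(SBS_CHANNELS),
                               nrow(m), ncol(m)))
      } else if (!all(dim(m) == dim(px)[3:4])) {
        stopWithPath(f, "inconsistent stack: shape mismatch across cycles")
      }
      px[ci, ki, , ] <- m
    }
  }
  if (dim(px)[3] != fov@height_px || dim(px)[4] != fov@width_px)
    stopWithPath(stack_dir, "inconsistent stack: metadata dimensions disagree")
  SBSImageStack(px, fov = fov)
}

#' Write an SBS image stack to a per-FOV directory
#'
#' Inverse of [readImageStack()]; intensities are clamped to \[0, 65535\] and
#' rounded to 16-bit unsigned. Round-trips are bit-identical for
#' integer-valued stacks in range.
#'
#' @param stack An [SBSImageStack-class].
#' @param stack_dir Output directory (created if missing).
#' @return `stack_dir`, invisibly.
#' @export
writeImageStack <- function(stack, stack_dir) {
  stopifnot(is(stack, "SBSImageStack"))
  dir.create(stack_dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack@pixels)
  for (ci in seq_len(d[1])) {
    for (ki in seq_len(d[2])) {
      m <- round(pmin(pmax(stack@pixels[ci, ki, , ], 0), 65535))
      tiff::writeTIFF(m / 65535,
        file.path(stack_dir, sprintf("c%02d_%s.tif", ci, SBS_CHANNELS[ki])),
        bits.per.sample = 16L, compression = "deflate")
    }
  }
  writeFOVMetadata(stack@fov, file.path(stack_dir, "fov.json"))
  invisible(stack_dir)
}

#' Read / write FOV metadata JSON
#'
#' @param path Path to a `fov.json` file.
#' @return [readFOVMetadata()] returns a [FOVMetadata-class];
#'   [writeFOVMetadata()] returns `path` invisibly.
#' @export
readFOVMetadata <- function(path) {
  if (!file.exists(path)) stopWithPath(path, "inconsistent stack: fov.json missing")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  FOVMetadata(
    fov_id = j$fov_id, well = j$well %||% "A1",
    stage_x_um = j$stage_x_um, stage_y_um = j$stage_y_um,
    pixel_size_um = j$pixel_size_um, magnification = j$magnification %||% "10X",
    height_px = j$height_px, width_px = j$width_px
  )
}

#' @rdname readFOVMetadata
#' @param fov A [FOVMetadata-class].
#' @export
writeFOVMetadata <- function(fov, path) {
  jsonlite::write_json(list(
    fov_id = fov@fov_id, well = fov@well,
    stage_x_um = fov@stage_x_um, stage_y_um = fov@stage_y_um,
    pixel_size_um = fov@pixel_size_um, magnification = fov@magnification,
    height_px = fov@height_px, width_px = fov@width_px,
    layout_version = 1L
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a codebook CSV
#'
#' Expects a CSV with header `sgrna_id,barcode,gene,role` and validates the
#' barcode alphabet (G, C, A, T only), uniqueness and equal length.
#'
#' @param path Path to the CSV.
#' @return A [Codebook-class].
#' @seealso [writeCodebook()], [defaultCodebook()]
#' @export
readCodebook <- function(path) {
  if (!file.exists(path)) stopWithPath(path, "codebook not found")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sgrna_id", "barcode", "gene", "role")
  if (!all(need %in% names(df)))
    stopWithPath(path, paste("codebook must have columns:",
                             paste(need, collapse = ",")))
  Codebook(df$sgrna_id, df$barcode, df$gene, df$role)
}

#' @rdname readCodebook
#' @param codebook A [Codebook-class].
#' @export
writeCodebook <- function(codebook, path) {
  utils::write.csv(codebookTable(codebook), path, row.names = FALSE)
  invisible(path)
}

#' Write / read a result table as CSV
#'
#' Thin CSV wrappers used for every tabular artifact (spots, reads,
#' genotypes, phenotypes, matches, screen results). Values round-trip up to
#' standard decimal float formatting; character columns (including Unicode
#' sgRNA ids) are preserved verbatim.
#'
#' @param table A data.frame with unique column names.
#' @param path Output/input CSV path.
#' @return [readResultTable()] returns a data.frame; [writeResultTable()]
#'   returns `path` invisibly.
#' @export
writeResultTable <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table)))
    stop("result table column names must be unique")
  tryCatch(
    utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stopWithPath(path, conditionMessage(e))
  )
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
  if (!file.exists(path)) stopWithPath(path, "result table not found")
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Validate a stack directory layout
#'
#' Checks that a per-FOV directory can be read as a complete, consistent
#' stack; used by the `ops io validate` command-line entry point.
#'
#' @param stack_dir Directory to check.
#' @return TRUE invisibly on success; otherwise an error describing the
#'   first problem found.
#' @export
validateStackDir <- function(stack_dir) {
  invisible({readImageStack(stack_dir); TRUE})
}
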
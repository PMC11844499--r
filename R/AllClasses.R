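#' @import methods
NULL

#' Canonical SBS channel order
#'
#' Channel order used throughout the package: DAPI first, then the four
#' sequencing-by-synthesis base channels in the order G, T, A, C. Base calls,
#' intensity tensors and tie-breaking all follow this order.
#'
#' @format Character vector of length 5.
#' @export
SBS_CHANNELS <- c("DAPI", "G", "T", "A", "C")

#' Base channels (non-DAPI) in canonical order
#' @format Character vector of length 4.
#' @export
SBS_BASES <- c("G", "T", "A", "C")

#' Field-of-view metadata
#'
#' Stage-level metadata for one field of view (FOV): its identifier, well,
#' stage coordinates in micrometres (referring to the FOV centre), pixel size,
#' magnification label and pixel dimensions. Stage coordinates are the bridge
#' between datasets acquired at different magnifications: a cell's global
#' position is its FOV's stage coordinate plus its centroid offset from the
#' FOV centre, scaled by the pixel size.
#'
#' @slot fov_id character(1), unique within a dataset.
#' @slot well character(1) well label.
#' @slot stage_x_um,stage_y_um numeric(1), stage position of the FOV centre
#'   (micrometres). y grows with the image row index by default.
#' @slot pixel_size_um numeric(1), micrometres per pixel (> 0).
#' @slot magnification character(1) label such as "10X", "20X", "40X".
#' @slot height_px,width_px integer(1), image dimensions in pixels.
#'
#' @seealso [FOVMetadata()] constructor, [toGlobal()]
#' @export
setClass("FOVMetadata",
  representation(
    fov_id = "character",
    well = "character",
    stage_x_um = "numeric",
    stage_y_um = "numeric",
    pixel_size_um = "numeric",
    magnification = "character",
    height_px = "integer",
    width_px = "integer"
  )
)

setValidity("FOVMetadata", function(object) {
  msg <- character()
  if (length(object@fov_id) != 1L || !nzchar(object@fov_id))
    msg <- c(msg, "fov_id must be a non-empty string")
  if (!isTRUE(object@pixel_size_um > 0))
    msg <- c(msg, "pixel_size_um must be > 0")
  if (!isTRUE(object@height_px > 0L) || !isTRUE(object@width_px > 0L))
    msg <- c(msg, "height_px and width_px must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct FOV metadata
#'
#' @param fov_id Unique FOV identifier.
#' @param well Well label.
#' @param stage_x_um,stage_y_um Stage position of the FOV centre (micrometres).
#' @param pixel_size_um Micrometres per pixel.
#' @param magnification Magnification label (e.g. "10X").
#' @param height_px,width_px Image dimensions in pixels.
#' @return A [FOVMetadata-class] object.
#' @examples
#' FOVMetadata("f01", "A1", 0, 0, 0.65, "10X", 256, 256)
#' @export
FOVMetadata <- function(fov_id, well = "A1", stage_x_um = 0, stage_y_um = 0,
                        pixel_size_um = 0.65, magnification = "10X",
                        height_px, width_px) {
  new("FOVMetadata",
    fov_id = as.character(fov_id), well = as.character(well),
    stage_x_um = as.numeric(stage_x_um), stage_y_um = as.numeric(stage_y_um),
    pixel_size_um = as.numeric(pixel_size_um),
    magnification = as.character(magnification),
    height_px = as.integer(height_px), width_px = as.integer(width_px)
  )
}

setMethod("show", "FOVMetadata", function(object) {
  cat(sprintf(
    "FOVMetadata '%s' (well %s, %s): %d x %d px, %.4f um/px, stage (%.1f, %.1f) um\n",
    object@fov_id, object@well, object@magnification,
    object@height_px, object@width_px, object@pixel_size_um,
    object@stage_x_um, object@stage_y_um
  ))
})

#' Multi-cycle multi-channel SBS image stack
#'
#' Raw or registered images for one FOV of an in situ sequencing run, stored
#' as a 4-D array indexed (cycle, channel, row, col) with the fixed channel
#' order DAPI, G, T, A, C. Pixel coordinates are 0-based (row, col) with the
#' origin at the top-left; intensities are finite and non-negative reals
#' (16-bit unsigned on disk).
#'
#' @slot fov A [FOVMetadata-class] object.
#' @slot pixels numeric array, dim = (n_cycles, 5, height, width).
#' @slot channels character(5), always `SBS_CHANNELS`.
#' @slot aligned logical(1), TRUE after [alignStack()].
#' @slot valid_mask logical matrix (height x width) or NULL; FALSE marks
#'   pixels that fell outside the frame in at least one aligned cycle.
#'
#' @seealso [SBSImageStack()], [readImageStack()], [alignStack()]
#' @export
setClass("SBSImageStack",
  representation(
    fov = "FOVMetadata",
    pixels = "array",
    channels = "character",
    aligned = "logical",
    valid_mask = "ANY"
  )
)

setValidity("SBSImageStack", function(object) {
  d <- dim(object@pixels)
  msg <- character()
  if (length(d) != 4L)
    msg <- c(msg, "pixels must be a 4-D array (cycle, channel, row, col)")
  else {
    if (d[2] != length(object@channels))
      msg <- c(msg, "channel dimension does not match channel labels")
    if (d[3] != object@fov@height_px || d[4] != object@fov@width_px)
      msg <- c(msg, "pixel dimensions do not match FOV metadata")
  }
  if (!identical(object@channels, SBS_CHANNELS))
    msg <- c(msg, sprintf("channels must be exactly: %s",
                          paste(SBS_CHANNELS, collapse = ", ")))
  if (anyNA(object@pixels) || any(!is.finite(object@pixels)))
    msg <- c(msg, "intensities must be finite")
  else if (any(object@pixels < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an SBS image stack
#'
#' @param pixels 4-D numeric array (cycle, channel, row, col); channel order
#'   must be DAPI, G, T, A, C.
#' @param fov A [FOVMetadata-class]; if missing, a default is derived from the
#'   array dimensions.
#' @param aligned Whether the stack is already registered across cycles.
#' @param valid_mask Optional logical matrix of per-pixel validity.
#' @return An [SBSImageStack-class].
#' @export
SBSImageStack <- function(pixels, fov = NULL, aligned = FALSE,
                          valid_mask = NULL) {
  d <- dim(pixels)
  if (is.null(fov))
    fov <- FOVMetadata("fov", height_px = d[3], width_px = d[4])
  new("SBSImageStack",
    fov = fov, pixels = pixels, channels = SBS_CHANNELS,
    aligned = aligned, valid_mask = valid_mask
  )
}

#' @rdname SBSImageStack
#' @param x,object An `SBSImageStack`.
#' @export
setGeneric("nCycles", function(x) standardGeneric("nCycles"))

#' @rdname SBSImageStack
#' @export
setMethod("nCycles", "SBSImageStack", function(x) dim(x@pixels)[1])

#' @rdname SBSImageStack
#' @export
setGeneric("stackPixels", function(x) standardGeneric("stackPixels"))

#' @rdname SBSImageStack
#' @export
setMethod("stackPixels", "SBSImageStack", function(x) x@pixels)

#' @rdname SBSImageStack
#' @export
setGeneric("fovMeta", function(x) standardGeneric("fovMeta"))

#' @rdname SBSImageStack
#' @export
setMethod("fovMeta", "SBSImageStack", function(x) x@fov)

#' Extract one (cycle, channel) frame as a matrix
#'
#' @param x An [SBSImageStack-class].
#' @param cycle 1-based cycle index.
#' @param channel Channel name (one of `SBS_CHANNELS`) or index.
#' @return Numeric matrix (height x width).
#' @export
stackFrame <- function(x, cycle, channel) {
  stopifnot(is(x, "SBSImageStack"))
  if (is.character(channel)) {
    ch <- match(channel, x@channels)
    if (is.na(ch)) stop("bad layout: unknown channel label '", channel, "'")
  } else ch <- as.integer(channel)
  x@pixels[cycle, ch, , ]
}

setMethod("show", "SBSImageStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "SBSImageStack: %d cycles x %d channels (%s), %d x %d px [%s]\n",
    d[1], d[2], paste(object@channels, collapse = ","), d[3], d[4],
    if (object@aligned) "aligned" else "raw"
  ))
  show(object@fov)
})

#' Barcode codebook
#'
#' Lookup table from 12-nt sgRNA barcode prefixes to sgRNA identity, target
#' gene and role (targeting, non-targeting control, or safe-targeting
#' control). Barcodes are unique, all of the same length and restricted to
#' the alphabet G, C, A, T.
#'
#' @slot entries data.frame with columns sgrna_id, barcode, gene, role.
#'
#' @seealso [Codebook()], [readCodebook()], [defaultCodebook()]
#' @export
setClass("Codebook", representation(entries = "data.frame"))

CODEBOOK_ROLES <- c("targeting", "non_targeting_control", "safe_targeting")

setValidity("Codebook", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("sgrna_id", "barcode", "gene", "role")
  if (!all(need %in% names(e)))
    return(sprintf("entries must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (anyDuplicated(e$barcode))
      msg <- c(msg, "duplicate barcode")
    if (length(unique(nchar(e$barcode))) > 1L)
      msg <- c(msg, "barcodes must all have the same length")
    if (any(grepl("[^GCAT]", e$barcode)))
      msg <- c(msg, "bad barcode: alphabet restricted to G, C, A, T")
    if (!all(e$role %in% CODEBOOK_ROLES))
      msg <- c(msg, sprintf("role must be one of: %s",
                            paste(CODEBOOK_ROLES, collapse = ", ")))
    if (anyDuplicated(e$sgrna_id))
      msg <- c(msg, "duplicate sgrna_id")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a codebook
#'
#' @param sgrna_id Character vector of sgRNA identifiers.
#' @param barcode Character vector of equal-length GCAT barcodes.
#' @param gene Character vector of target genes.
#' @param role Character vector; each one of `"targeting"`,
#'   `"non_targeting_control"`, `"safe_targeting"`.
#' @return A [Codebook-class].
#' @export
Codebook <- function(sgrna_id, barcode, gene, role = "targeting") {
  e <- data.frame(
    sgrna_id = as.character(sgrna_id), barcode = as.character(barcode),
    gene = as.character(gene),
    role = rep_len(as.character(role), length(sgrna_id)),
    stringsAsFactors = FALSE
  )
  new("Codebook", entries = e)
}

#' @rdname Codebook
#' @param x A `Codebook`.
#' @export
setGeneric("codebookTable", function(x) standardGeneric("codebookTable"))

#' @rdname Codebook
#' @export
setMethod("codebookTable", "Codebook", function(x) x@entries)

#' @rdname Codebook
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname Codebook
#' @export
setMethod("barcodes", "Codebook", function(x) x@entries$barcode)

#' sgRNA ids playing a control role
#'
#' @param x A [Codebook-class].
#' @param roles Which roles count as control; by default both non-targeting
#'   and safe-targeting guides are pooled.
#' @return Character vector of sgRNA ids.
#' @export
controlIds <- function(x, roles = c("non_targeting_control", "safe_targeting")) {
  e <- codebookTable(x)
  e$sgrna_id[e$role %in% roles]
}

setMethod("show", "Codebook", function(object) {
  e <- object@entries
  cat(sprintf("Codebook: %d sgRNAs, %d genes, barcode length %s\n",
              nrow(e), length(unique(e$gene)),
              if (nrow(e)) nchar(e$barcode[1]) else "NA"))
  tab <- table(e$role)
  if (length(tab))
    cat(" roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("length", "Codebook", function(x) nrow(x@entries))
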
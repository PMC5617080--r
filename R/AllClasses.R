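#' @import methods
NULL

#' ROI label codes
#'
#' Integer codes used in label-mask images. 0 marks pixels outside every
#' region. The graft core lies inside the lesioned striatum, so a pixel
#' labelled \code{graft_core} is also part of the lesioned striatum;
#' \code{\link{roiMask}} resolves this containment when binary masks are
#' requested.
#'
#' @return Named integer vector of label codes.
#' @export
#' @examples
#' roiLabels()
roiLabels <- function() {
    c(striatum_ipsi = 1L, striatum_contra = 2L, corpus_callosum = 3L,
      graft_core = 4L, artifact = 5L)
}

#' SectionGeometry: physical geometry of a serial-section series
#'
#' Section thickness and inter-section gap in micrometres, the pixel size of
#' the digitised images, and the image raster dimensions. The centre-to-centre
#' spacing between consecutive mounted sections is \code{thickness + gap}
#' (40 um sections with a 120 um gap give 160 um spacing).
#'
#' @slot thickness section thickness T in um (> 0)
#' @slot gap inter-section gap g in um (>= 0)
#' @slot pixelSize image scale in um/pixel (> 0)
#' @slot width,height raster dimensions in pixels
#'
#' @aliases SectionGeometry-class
#' @export SectionGeometry
#' @exportClass SectionGeometry
SectionGeometry <- setClass("SectionGeometry",
    representation(thickness = "numeric", gap = "numeric",
                   pixelSize = "numeric", width = "integer",
                   height = "integer"))

setValidity("SectionGeometry", function(object) {
    msg <- character()
    if (length(object@thickness) != 1 || !is.finite(object@thickness) ||
        object@thickness <= 0)
        msg <- c(msg, "thickness must be a single positive number (um)")
    if (length(object@gap) != 1 || !is.finite(object@gap) || object@gap < 0)
        msg <- c(msg, "gap must be a single non-negative number (um)")
    if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive number (um/px)")
    if (length(object@width) != 1 || object@width < 1L)
        msg <- c(msg, "width must be >= 1 pixel")
    if (length(object@height) != 1 || object@height < 1L)
        msg <- c(msg, "height must be >= 1 pixel")
    if (length(msg)) msg else TRUE
})

#' Construct a SectionGeometry
#'
#' @param thickness section thickness in um (default 40, a standard freezing-
#'   microtome setting)
#' @param gap gap between mounted sections in um (default 120, i.e. a 1-in-4
#'   spacing of 40-um sections yielding 160 um centre-to-centre)
#' @param pixelSize um per pixel (default 5.16)
#' @param width,height raster size in pixels
#' @return A \linkS4class{SectionGeometry}.
#' @export
#' @examples
#' g <- sectionGeometry(width = 512L, height = 384L)
#' spacing(g)  # 160
sectionGeometry <- function(thickness = 40, gap = 120, pixelSize = 5.16,
                            width = 512L, height = 384L) {
    new("SectionGeometry", thickness = as.numeric(thickness),
        gap = as.numeric(gap), pixelSize = as.numeric(pixelSize),
        width = as.integer(width), height = as.integer(height))
}

#' Phantom: synthetic grafted-striatum scene with analytic ground truth
#'
#' A 3D scene in micrometre coordinates: axis-aligned ellipsoids for the
#' lesioned (ipsilateral) and intact (contralateral) striatum and the graft
#' core, a slab for the corpus callosum, a radially decaying TH-fiber stain
#' field around the core with an optional dorsal bias, and spherical TH-ir
#' cells concentrated at the core border. The \code{truths} slot records the
#' analytic core volume and grid-integrated fiber volume, dorsoventral ratios
#' and cell count so downstream estimators can be validated.
#'
#' Coordinate convention: x is the cutting axis (sections are planes normal to
#' x), y is the image row axis with dorsal = smaller y (smaller row index),
#' z is the image column axis.
#'
#' @slot regions named list of region geometries (ellipsoids / slab)
#' @slot fiber list of fiber-field parameters (amplitude, lambda, beta, ...)
#' @slot cells data.frame with columns x, y, z, diameter (um)
#' @slot truths named list of ground-truth quantities
#' @slot config the resolved configuration the phantom was built from
#'
#' @aliases Phantom-class
#' @export
#' @exportClass Phantom
setClass("Phantom",
    representation(regions = "list", fiber = "list", cells = "data.frame",
                   truths = "list", config = "list"))

setValidity("Phantom", function(object) {
    msg <- character()
    need <- c("striatum_ipsi", "striatum_contra", "corpus_callosum",
              "graft_core")
    if (!all(need %in% names(object@regions)))
        msg <- c(msg, paste("regions must contain",
                            paste(need, collapse = ", ")))
    if (nrow(object@cells) &&
        !all(c("x", "y", "z", "diameter") %in% names(object@cells)))
        msg <- c(msg, "cells must have columns x, y, z, diameter")
    if (length(msg)) msg else TRUE
})

#' SectionDataset: a digitised serial-section series with ROI labels
#'
#' Ordered grayscale section images with one integer label mask per section,
#' the acquisition geometry, and (for synthetic data) the ground-truth record.
#' Sections are ordered along the cutting axis.
#'
#' @slot images list of numeric matrices (raw intensities, dark = more stain)
#' @slot labels list of integer matrices using \code{\link{roiLabels}} codes
#' @slot geometry a \linkS4class{SectionGeometry}
#' @slot bitDepth 8 or 16
#' @slot truth list; ground truth and per-section bookkeeping (may be empty)
#'
#' @aliases SectionDataset-class
#' @export
#' @exportClass SectionDataset
setClass("SectionDataset",
    representation(images = "list", labels = "list",
                   geometry = "SectionGeometry", bitDepth = "integer",
                   truth = "list"))

setValidity("SectionDataset", function(object) {
    msg <- character()
    if (length(object@images) != length(object@labels))
        msg <- c(msg, "one label mask is required per section image")
    if (!length(object@images))
        msg <- c(msg, "dataset must contain at least one section")
    dims <- c(object@geometry@height, object@geometry@width)
    for (i in seq_along(object@images)) {
        if (!identical(dim(object@images[[i]]), as.integer(dims))) {
            msg <- c(msg, sprintf(
                "section %d image dimensions do not match geometry", i))
            break
        }
        if (!identical(dim(object@labels[[i]]), as.integer(dims))) {
            msg <- c(msg, sprintf(
                "section %d mask dimensions do not match its image", i))
            break
        }
    }
    known <- c(0L, unname(roiLabels()))
    for (i in seq_along(object@labels)) {
        if (!all(unique(as.integer(object@labels[[i]])) %in% known)) {
            msg <- c(msg, sprintf("section %d mask has unknown labels", i))
            break
        }
    }
    if (!object@bitDepth %in% c(8L, 16L))
        msg <- c(msg, "bitDepth must be 8 or 16")
    if (length(msg)) msg else TRUE
})

#' ODImage: per-pixel optical density of one section
#'
#' OD(p) = log10(I_ref / I(p)), clipped below at zero, where I_ref is the mean
#' raw intensity inside the reference region (here the TH-negative corpus
#' callosum of the same section). Pixels at least as bright as the reference
#' mean have OD 0; zero intensities are clamped to 1 before the log.
#'
#' @slot od numeric matrix of optical densities (>= 0, finite)
#' @slot referenceMean mean raw intensity of the reference region
#' @slot section section index the OD image belongs to
#'
#' @aliases ODImage-class
#' @export
#' @exportClass ODImage
setClass("ODImage",
    representation(od = "matrix", referenceMean = "numeric",
                   section = "integer"))

setValidity("ODImage", function(object) {
    msg <- character()
    if (any(!is.finite(object@od)))
        msg <- c(msg, "OD values must be finite")
    else if (any(object@od < 0))
        msg <- c(msg, "OD values must be >= 0")
    if (length(object@referenceMean) != 1 || object@referenceMean <= 0)
        msg <- c(msg, "referenceMean must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' FiberSegmentation: thresholded TH-positive pixels of one section
#'
#' Pixels of the analysis region (lesioned striatum minus graft core minus
#' artifacts) whose OD lies strictly above the threshold. Area is the positive
#' pixel count times the squared pixel size.
#'
#' @slot mask logical matrix of positive pixels (subset of the analysis mask)
#' @slot positivePixels number of positive pixels
#' @slot areaUm2 positive area in um^2
#' @slot theta threshold actually applied (OD units)
#' @slot rule human-readable description of the threshold rule
#' @slot empty TRUE when the analysis mask itself was empty
#'
#' @aliases FiberSegmentation-class
#' @export
#' @exportClass FiberSegmentation
setClass("FiberSegmentation",
    representation(mask = "matrix", positivePixels = "integer",
                   areaUm2 = "numeric", theta = "numeric", rule = "character",
                   empty = "logical"))

setValidity("FiberSegmentation", function(object) {
    if (object@positivePixels != sum(object@mask))
        return("positivePixels must equal the number of TRUE mask pixels")
    TRUE
})
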
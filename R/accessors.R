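#' @include AllGenerics.R
NULL

#' @rdname spacing
#' @export
setMethod("spacing", "SectionGeometry", function(object)
    object@thickness + object@gap)

#' @rdname nSections
#' @export
setMethod("nSections", "SectionDataset", function(object)
    length(object@images))

#' @rdname geometry
#' @export
setMethod("geometry", "SectionDataset", function(object) object@geometry)

#' @rdname sectionImage
#' @export
setMethod("sectionImage", "SectionDataset", function(object, i) {
    stopifnot(i >= 1L, i <= length(object@images))
    object@images[[i]]
})

#' @rdname labelImage
#' @export
setMethod("labelImage", "SectionDataset", function(object, i) {
    stopifnot(i >= 1L, i <= length(object@labels))
    object@labels[[i]]
})

#' @rdname roiMask
#' @export
setMethod("roiMask", "SectionDataset", function(object, name, i) {
    codes <- roiLabels()
    if (!name %in% names(codes))
        stop("unknown ROI name '", name, "'; expected one of: ",
             paste(names(codes), collapse = ", "))
    lab <- labelImage(object, i)
    if (name == "striatum_ipsi")
        lab == codes[["striatum_ipsi"]] | lab == codes[["graft_core"]]
    else
        lab == codes[[name]]
})

#' @rdname truths
#' @export
setMethod("truths", "SectionDataset", function(object) object@truth)

#' @rdname truths
#' @export
setMethod("truths", "Phantom", function(object) object@truths)

setMethod("show", "SectionGeometry", function(object) {
    cat(sprintf(
        "SectionGeometry: T = %g um, gap = %g um (spacing %g um), %g um/px, %d x %d px\n",
        object@thickness, object@gap, spacing(object), object@pixelSize,
        object@width, object@height))
})

setMethod("show", "Phantom", function(object) {
    cat("Phantom (um coordinates)\n")
    core <- object@regions$graft_core
    cat(sprintf("  graft core: ellipsoid semi-axes (%g, %g, %g) um\n",
                core$semi[1], core$semi[2], core$semi[3]))
    cat(sprintf("  cells: %d (diameter %g um)\n", nrow(object@cells),
                object@config$cells$diameter))
    tr <- object@truths
    cat(sprintf("  truths: core %.4f mm^3, fibers %.4f mm^3, %d cells, D/V %.3f\n",
                tr$core_volume_mm3, tr$fiber_volume_mm3, tr$cell_count,
                tr$dv_ratio))
})

setMethod("show", "SectionDataset", function(object) {
    cat(sprintf("SectionDataset: %d sections of %d x %d px (%d-bit)\n",
                nSections(object), object@geometry@height,
                object@geometry@width, object@bitDepth))
    show(object@geometry)
    if (length(object@truth))
        cat("  ground truth attached\n")
})

setMethod("show", "ODImage", function(object) {
    cat(sprintf("ODImage (section %d): reference mean %.2f, max OD %.3f\n",
                object@section, object@referenceMean, max(object@od)))
})

setMethod("show", "FiberSegmentation", function(object) {
    cat(sprintf(
        "FiberSegmentation: %d positive px, %.1f um^2 (theta = %.4f, %s)\n",
        object@positivePixels, object@areaUm2, object@theta, object@rule))
})
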
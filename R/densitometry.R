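#' @include AllClasses.R
NULL

#' Per-section optical density referenced to an unstained region
#'
#' OD(p) = log10(I_ref / I(p)) clipped below at zero, with I_ref the mean raw
#' intensity inside the reference mask (the TH-negative corpus callosum of the
#' same section). Zero intensities are clamped to 1 before the log so the OD
#' stays finite. Pixels at least as bright as the reference have OD 0.
#'
#' @param image numeric intensity matrix (dark = more stain)
#' @param referenceMask logical matrix, nonempty
#' @param section section index recorded in the result
#' @return an \linkS4class{ODImage}
#' @export
#' @examples
#' img <- matrix(100, 4, 4); img[1, 1] <- 10
#' od <- sectionOD(img, matrix(TRUE, 4, 4) & col(img) > 2)
sectionOD <- function(image, referenceMask, section = 1L) {
    if (!any(referenceMask))
        stop("reference mask is empty: cannot normalize this section")
    iref <- mean(image[referenceMask])
    od <- log10(iref / pmax(image, 1))
    od[od < 0] <- 0
    new("ODImage", od = od, referenceMean = iref,
        section = as.integer(section))
}

#' Threshold rule for fiber segmentation
#'
#' Either \code{"reference_sd"} — threshold at mean + k * SD of the OD inside
#' a reference region (transfers across staining batches and noise levels) —
#' or \code{"fixed"} — a configured OD value.
#'
#' @param type "reference_sd" or "fixed"
#' @param k SD multiplier for the reference rule (default 3)
#' @param value OD threshold for the fixed rule
#' @return a list of class \code{thresholdRule}
#' @export
thresholdRule <- function(type = c("reference_sd", "fixed"), k = 3,
                          value = NA_real_) {
    type <- match.arg(type)
    if (type == "fixed" && !is.finite(value))
        stop("fixed threshold rule needs a finite 'value'")
    structure(list(type = type, k = k, value = value),
              class = "thresholdRule")
}

#' Resolve a threshold rule to a numeric OD threshold
#'
#' @param odImage an \linkS4class{ODImage}
#' @param rule a \code{\link{thresholdRule}}
#' @param referenceMask logical matrix; required for the reference_sd rule
#' @return numeric threshold theta
#' @export
resolveThreshold <- function(odImage, rule, referenceMask = NULL) {
    if (rule$type == "fixed") return(rule$value)
    if (is.null(referenceMask) || !any(referenceMask))
        stop("reference_sd rule needs a nonempty reference mask")
    v <- odImage@od[referenceMask]
    s <- stats::sd(v)
    if (!is.finite(s)) s <- 0
    mean(v) + rule$k * s
}

ruleLabel <- function(rule, theta) {
    if (rule$type == "fixed") sprintf("fixed OD threshold %.4g", theta)
    else sprintf("reference mean + %g SD (= %.4g)", rule$k, theta)
}

#' Segment TH-positive fiber pixels of one section
#'
#' Pixels of the analysis region whose OD lies strictly above the threshold
#' ("pixels above threshold"); a pixel exactly at the threshold is excluded.
#' The analysis mask must already exclude the graft core and artifacts (see
#' \code{\link{fiberAnalysisMask}}).
#'
#' @param odImage an \linkS4class{ODImage}
#' @param analysisMask logical matrix
#' @param rule a \code{\link{thresholdRule}}
#' @param pixelSize um per pixel
#' @param referenceMask reference region for the reference_sd rule
#' @return a \linkS4class{FiberSegmentation}; an empty analysis mask yields a
#'   zero-area segmentation with a warning and \code{empty = TRUE}
#' @export
segmentFibers <- function(odImage, analysisMask, rule = thresholdRule(),
                          pixelSize, referenceMask = NULL) {
    empty <- !any(analysisMask)
    if (empty) warning("empty analysis mask: fiber area is 0")
    theta <- resolveThreshold(odImage, rule, referenceMask)
    mask <- odImage@od > theta & analysisMask
    count <- sum(mask)
    new("FiberSegmentation", mask = mask, positivePixels = as.integer(count),
        areaUm2 = count * pixelSize^2, theta = theta,
        rule = ruleLabel(rule, theta), empty = empty)
}

#' Mirror a mask across the vertical midline
#'
#' Column c maps to (width - 1 - c) (zero-based), rows unchanged — the
#' horizontal flip used to transfer the lesioned-side outline onto the
#' contralateral hemisphere. An involution that preserves pixel count.
#'
#' @param mask a matrix (logical or numeric)
#' @return the mirrored matrix
#' @export
#' @examples
#' m <- matrix(FALSE, 2, 10); m[1, 4] <- TRUE   # zero-based column 3
#' which(mirrorMask(m)[1, ])                    # column 7 (zero-based 6)
mirrorMask <- function(mask) {
    mask[, rev(seq_len(ncol(mask))), drop = FALSE]
}

#' Analysis mask for fiber measurements of one section
#'
#' Lesioned striatum minus the graft core minus artifacts.
#'
#' @param dataset a \linkS4class{SectionDataset}
#' @param i section index
#' @return logical matrix
#' @export
fiberAnalysisMask <- function(dataset, i) {
    roiMask(dataset, "striatum_ipsi", i) &
        !roiMask(dataset, "graft_core", i) &
        !roiMask(dataset, "artifact", i)
}

#' Fiber density relative to the unlesioned striatum, in percent
#'
#' For every section, the lesioned-side fiber mask is segmented from the OD
#' image (corpus-callosum reference); its horizontal mirror, restricted to the
#' contralateral striatum, selects the matching unlesioned region, which is
#' thresholded with the same rule resolved on the unlesioned side (mirrored
#' reference region). The result pools positive pixels across sections:
#' 100 * mean OD of lesioned-side positive pixels / mean OD of contralateral
#' positive pixels.
#'
#' @param dataset a \linkS4class{SectionDataset}
#' @param rule a \code{\link{thresholdRule}}
#' @return list with \code{percent}, pooled mean ODs and pixel counts, and a
#'   \code{flag} ("ok", "empty_lesioned" or "no_contra_positive"); the percent
#'   is NA (never silently 0) when no contralateral pixel is positive
#' @export
relativeFiberDensity <- function(dataset, rule = thresholdRule()) {
    px <- geometry(dataset)@pixelSize
    sum_les <- 0; n_les <- 0L; sum_con <- 0; n_con <- 0L
    for (i in seq_len(nSections(dataset))) {
        cc <- roiMask(dataset, "corpus_callosum", i)
        if (!any(cc)) next
        od <- sectionOD(sectionImage(dataset, i), cc, i)
        seg <- segmentFibers(od, fiberAnalysisMask(dataset, i), rule, px,
                             referenceMask = cc)
        theta_con <- resolveThreshold(od, rule, mirrorMask(cc))
        mirrored <- mirrorMask(seg@mask) & roiMask(dataset, "striatum_contra", i)
        con_pos <- mirrored & od@od > theta_con
        sum_les <- sum_les + sum(od@od[seg@mask]); n_les <- n_les + sum(seg@mask)
        sum_con <- sum_con + sum(od@od[con_pos]); n_con <- n_con + sum(con_pos)
    }
    flag <- "ok"
    if (n_les == 0L) {
        warning("no positive lesioned-side fiber pixels: density is 0%")
        flag <- "empty_lesioned"
        pct <- 0
    } else if (n_con == 0L) {
        warning("no positive contralateral pixels: relative density undefined")
        flag <- "no_contra_positive"
        pct <- NA_real_
    } else {
        pct <- 100 * (sum_les / n_les) / (sum_con / n_con)
    }
    list(percent = pct,
         mean_od_lesioned = if (n_les) sum_les / n_les else NA_real_,
         mean_od_contra = if (n_con) sum_con / n_con else NA_real_,
         n_lesioned_px = n_les, n_contra_px = n_con,
         pooled = TRUE, flag = flag)
}
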
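#' Frustum (truncated cone) volume between two consecutive sections
#'
#' The interpolated volume between sections n and n+1 assumes both profile
#' areas are circular with radii R = sqrt(A_n / pi) and r = sqrt(A_n+1 / pi):
#' V = h pi/3 (R^2 + R r + r^2), which simplifies to
#' V = h/3 (A_n + sqrt(A_n A_n+1) + A_n+1). Symmetric in the two areas and
#' linear in the spacing h.
#'
#' @param areaN,areaN1 profile areas of two consecutive sections (>= 0, same
#'   unit)
#' @param h spacing between section centres (same length unit as the areas)
#' @return volume in area-unit times h-unit
#' @export
#' @examples
#' frustumVolume(1, 0.25, 0.16)  # 0.09333...
frustumVolume <- function(areaN, areaN1, h) {
    if (any(areaN < 0) || any(areaN1 < 0)) stop("areas must be non-negative")
    if (any(h <= 0)) stop("spacing h must be positive")
    h / 3 * (areaN + sqrt(areaN * areaN1) + areaN1)
}

#' Total volume of a serial-section area series
#'
#' Sums the frustum volumes over the N - 1 consecutive section pairs — no end
#' caps are added beyond the first and last section, which slightly
#' underestimates the true volume of a convex object. A single-section series
#' has no pairs and returns 0 with a warning.
#'
#' @param areas ordered per-section areas
#' @param spacing centre-to-centre spacing h
#' @param areaUnit "um2" or "mm2"
#' @param spacingUnit "um" or "mm"
#' @return volume in mm^3
#' @export
#' @examples
#' seriesVolume(rep(1e6, 5), 160)  # (N-1) * h * A = 0.64 mm^3
seriesVolume <- function(areas, spacing, areaUnit = c("um2", "mm2"),
                         spacingUnit = c("um", "mm")) {
    areaUnit <- match.arg(areaUnit); spacingUnit <- match.arg(spacingUnit)
    if (!length(areas)) stop("area series is empty")
    if (any(areas < 0)) stop("areas must be non-negative")
    a_mm2 <- if (areaUnit == "um2") areas / 1e6 else areas
    h_mm <- if (spacingUnit == "um") spacing / 1e3 else spacing
    if (length(areas) == 1L) {
        warning("single section: no consecutive pair, volume is 0")
        return(0)
    }
    n <- length(a_mm2)
    sum(frustumVolume(a_mm2[-n], a_mm2[-1], h_mm))
}

#' Abercrombie-corrected cell count
#'
#' Profile counts on sections of thickness T overestimate object numbers
#' because any sphere of mean height D intersecting the slab leaves a profile;
#' the corrected estimate is N = n T / (T + D). The result is kept fractional;
#' rounding is left to the reporting layer.
#'
#' @param n raw profile count (>= 0)
#' @param thickness section thickness T in um (> 0)
#' @param meanHeight mean object height D in um (>= 0); 12 um is a typical
#'   TH-ir soma diameter
#' @return list with \code{profiles}, \code{thickness}, \code{meanHeight} and
#'   the corrected \code{estimate}
#' @export
#' @examples
#' abercrombieEstimate(100, 40, 40)$estimate  # 50
abercrombieEstimate <- function(n, thickness, meanHeight = 12) {
    if (thickness <= 0) stop("section thickness must be positive")
    if (n < 0) stop("profile count must be non-negative")
    if (meanHeight < 0) stop("mean object height must be non-negative")
    list(profiles = n, thickness = thickness, meanHeight = meanHeight,
         estimate = n * thickness / (thickness + meanHeight))
}

#' Cell density per graft core volume
#'
#' @param nHat corrected cell count
#' @param coreVolume graft core volume in mm^3 (> 0)
#' @return cells per mm^3
#' @export
cellsPerVolume <- function(nHat, coreVolume) {
    if (coreVolume <= 0) stop("core volume must be positive")
    nHat / coreVolume
}

#' Count cell profiles on one section by connected components
#'
#' TH-ir somata are rendered (and stained) darker than the fiber neuropil, so
#' profiles are the connected components of pixels whose OD exceeds a cell
#' threshold inside the search region. Components smaller than
#' \code{minPixels} are discarded as noise specks.
#'
#' @param odImage an \linkS4class{ODImage}
#' @param searchMask logical matrix (e.g. the lesioned striatum including the
#'   graft core, artifacts excluded)
#' @param threshold OD threshold separating somata from fibers
#' @param minPixels minimum component size in pixels
#' @return integer profile count
#' @export
countCellProfiles <- function(odImage, searchMask, threshold,
                              minPixels = 2L) {
    bin <- odImage@od > threshold & searchMask
    if (!any(bin)) return(0L)
    lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
    sizes <- tabulate(as.integer(lab[lab > 0]))
    sum(sizes >= minPixels)
}
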
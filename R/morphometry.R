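#' Integrated fiber density
#'
#' Compound reinnervation score: total TH-positive fiber area multiplied by
#' the relative optical density within that area (fiber density x area).
#' Bilinear in its two inputs; only relative comparisons between animals are
#' meaningful.
#'
#' @param totalFiberArea summed per-section fiber area (any fixed area unit,
#'   >= 0)
#' @param relDensityPercent relative fiber density in percent (>= 0)
#' @return area-unit times density-fraction score
#' @export
#' @examples
#' integratedFiberDensity(2, 50)  # 1
integratedFiberDensity <- function(totalFiberArea, relDensityPercent) {
    if (any(totalFiberArea < 0) || any(relDensityPercent < 0))
        stop("area and relative density must be non-negative")
    totalFiberArea * relDensityPercent / 100
}

#' Dorsal/ventral ratio of TH-positive fiber pixels
#'
#' A horizontal line is set through the centre of the graft core — the
#' area-weighted centroid row of the core masks pooled over all sections
#' (dorsal = smaller row index) — and positive fiber pixels strictly above the
#' line are ratioed against those strictly below, summed over sections.
#' Pixels exactly on the centre row are split evenly between the two sides.
#' With \code{perSection = TRUE} the centre row is recomputed per section.
#'
#' @param fiberMasks list of logical matrices (positive fiber pixels)
#' @param coreMasks list of logical matrices (graft core), same length
#' @return list with \code{ratio}, \code{center_row}, \code{dorsal_pixels},
#'   \code{ventral_pixels} and a \code{flag}; a zero ventral count yields an
#'   infinite ratio with flag "ventral_empty"
#' @param perSection recompute the core centre per section
#' @export
dorsoventralRatio <- function(fiberMasks, coreMasks, perSection = FALSE) {
    stopifnot(length(fiberMasks) == length(coreMasks))
    coreRows <- unlist(lapply(coreMasks, function(m) row(m)[m]))
    if (!length(coreRows))
        stop("no section has a nonempty graft core mask")
    center_all <- mean(coreRows)
    dorsal <- 0; ventral <- 0
    for (i in seq_along(fiberMasks)) {
        center <- if (perSection) {
            r <- row(coreMasks[[i]])[coreMasks[[i]]]
            if (length(r)) mean(r) else center_all
        } else center_all
        rows <- row(fiberMasks[[i]])[fiberMasks[[i]]]
        dorsal <- dorsal + sum(rows < center) + 0.5 * sum(rows == center)
        ventral <- ventral + sum(rows > center) + 0.5 * sum(rows == center)
    }
    flag <- "ok"
    if (ventral == 0) {
        warning("no ventral fiber pixels: D/V ratio is infinite")
        flag <- "ventral_empty"
    }
    list(ratio = if (ventral > 0) dorsal / ventral else Inf,
         center_row = center_all, dorsal_pixels = dorsal,
         ventral_pixels = ventral, flag = flag)
}

#' Expected number of grafted dopaminergic cells
#'
#' @param cellsTransplanted total transplanted fetal cells (> 0)
#' @param daFraction dopaminergic fraction of the suspension (0 < f <= 1),
#'   about 0.10 for fetal ventral mesencephalon
#' @return expected dopaminergic cell number
#' @export
#' @examples
#' graftedDopamineCells(130000, 0.10)  # 13000
graftedDopamineCells <- function(cellsTransplanted, daFraction) {
    if (any(cellsTransplanted <= 0)) stop("cellsTransplanted must be positive")
    if (any(daFraction <= 0) || any(daFraction > 1))
        stop("daFraction must lie in (0, 1]")
    cellsTransplanted * daFraction
}

#' Survival percentage of grafted dopaminergic neurons
#'
#' 100 x TH-ir cell count / expected grafted dopaminergic cells.
#'
#' @param thCount Abercrombie-corrected TH-ir cell count (>= 0)
#' @param cellsTransplanted total transplanted fetal cells
#' @param daFraction dopaminergic fraction of the suspension
#' @return survival in percent
#' @export
#' @examples
#' survivalPercent(641, 130000, 0.10)  # about 4.93, i.e. ~5 %
survivalPercent <- function(thCount, cellsTransplanted, daFraction) {
    if (any(thCount < 0)) stop("thCount must be non-negative")
    100 * thCount / graftedDopamineCells(cellsTransplanted, daFraction)
}

#' Quantify one animal's graft from its section dataset
#'
#' Runs the full per-animal image analysis: per-section OD normalization to
#' the corpus callosum, fiber segmentation in the lesioned striatum (graft
#' core and artifacts excluded), graft-core and fiber areas, frustum-sum
#' volumes, relative fiber density against the mirrored contralateral
#' striatum, integrated fiber density, dorsoventral outgrowth ratio, and
#' Abercrombie-corrected TH-ir cell count with core density.
#'
#' @param dataset a \linkS4class{SectionDataset}
#' @param rule a \code{\link{thresholdRule}} for fiber segmentation
#' @param abercrombieD mean soma height D in um for the Abercrombie correction
#' @param cellThreshold OD threshold separating somata from fibers
#'   (default 1.2, midway between typical neuropil and soma stain levels)
#' @param extrapolateSeries scale the Abercrombie estimate by spacing /
#'   thickness so that a spaced series (e.g. 1-in-4 sampling at 160 um
#'   spacing of 40 um sections) estimates the whole graft rather than the
#'   sampled slabs only
#' @return list with \code{metrics} (named list: core_volume_mm3,
#'   fiber_volume_mm3, rel_density_percent, integrated_fiber_density,
#'   dv_ratio, profile_count, th_count_series, th_count, cells_per_mm3) and
#'   \code{sections} (per-section data.frame)
#' @export
quantifyGraft <- function(dataset, rule = thresholdRule(), abercrombieD = 12,
                          cellThreshold = NULL, extrapolateSeries = TRUE) {
    geom <- geometry(dataset)
    px <- geom@pixelSize
    h <- spacing(geom)
    ns <- nSections(dataset)
    if (is.null(cellThreshold)) cellThreshold <- 1.2

    core_area <- numeric(ns); fiber_area <- numeric(ns)
    pos_px <- integer(ns); mean_od_pos <- numeric(ns)
    theta <- numeric(ns); refmean <- numeric(ns); profiles <- integer(ns)
    fiberMasks <- vector("list", ns); coreMasks <- vector("list", ns)
    for (i in seq_len(ns)) {
        cc <- roiMask(dataset, "corpus_callosum", i)
        if (!any(cc))
            stop("section ", i, " has no corpus callosum reference region")
        od <- sectionOD(sectionImage(dataset, i), cc, i)
        coreMasks[[i]] <- roiMask(dataset, "graft_core", i)
        core_area[i] <- sum(coreMasks[[i]]) * px^2
        seg <- segmentFibers(od, fiberAnalysisMask(dataset, i), rule, px,
                             referenceMask = cc)
        fiberMasks[[i]] <- seg@mask
        fiber_area[i] <- seg@areaUm2
        pos_px[i] <- seg@positivePixels
        mean_od_pos[i] <- if (seg@positivePixels)
            mean(od@od[seg@mask]) else NA_real_
        theta[i] <- seg@theta
        refmean[i] <- od@referenceMean
        search <- roiMask(dataset, "striatum_ipsi", i) &
            !roiMask(dataset, "artifact", i)
        profiles[i] <- countCellProfiles(od, search, cellThreshold)
    }

    core_volume <- seriesVolume(core_area, h)
    fiber_volume <- seriesVolume(fiber_area, h)
    rel <- relativeFiberDensity(dataset, rule)
    ifd <- if (is.na(rel$percent)) NA_real_ else
        integratedFiberDensity(sum(fiber_area) / 1e6, rel$percent)
    dv <- if (any(vapply(coreMasks, any, logical(1))))
        dorsoventralRatio(fiberMasks, coreMasks) else
        list(ratio = NA_real_, flag = "no_core")
    ab <- abercrombieEstimate(sum(profiles), geom@thickness, abercrombieD)
    th_total <- ab$estimate * if (extrapolateSeries) h / geom@thickness else 1

    list(metrics = list(
             core_volume_mm3 = core_volume,
             fiber_volume_mm3 = fiber_volume,
             rel_density_percent = rel$percent,
             integrated_fiber_density = ifd,
             dv_ratio = dv$ratio,
             profile_count = sum(profiles),
             th_count_series = ab$estimate,
             th_count = th_total,
             cells_per_mm3 = if (core_volume > 0)
                 cellsPerVolume(th_total, core_volume) else NA_real_,
             rel_density_flag = rel$flag,
             dv_flag = dv$flag),
         sections = data.frame(
             section_index = seq_len(ns),
             core_area_um2 = core_area,
             area_um2 = fiber_area,
             positive_pixels = pos_px,
             mean_od_positive = mean_od_pos,
             theta = theta,
             reference_mean = refmean,
             cell_profiles = profiles))
}
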
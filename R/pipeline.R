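#' Charge delivered per stimulation session
#'
#' Charge density = current density x duration, converted from A/m^2 to
#' C/cm^2 (1 m^2 = 10^4 cm^2). 8 A/m^2 for 20 min gives 0.96 C/cm^2.
#'
#' @param currentDensity stimulation current density in A/m^2 (>= 0)
#' @param durationS session duration in seconds (>= 0)
#' @return charge density in C/cm^2
#' @export
#' @examples
#' sessionCharge(8, 20 * 60)  # 0.96
sessionCharge <- function(currentDensity, durationS) {
    if (any(currentDensity < 0) || any(durationS < 0))
        stop("current density and duration must be non-negative")
    currentDensity * durationS / 1e4
}

#' Phantom configuration for simulated cohorts
#'
#' A compact two-hemisphere scene (striatal ellipsoids of semi-axes
#' 320 x 200 x 150 um, graft core 120 x 90 x 75 um, corpus-callosum slab
#' dorsal to both striata) sized so a whole cohort can be rendered and
#' quantified quickly while keeping the paper-scale section geometry
#' (40 um sections, 120 um gap, 5.16 um/px).
#'
#' @param ... overrides passed on to \code{\link{phantomConfig}}
#' @return configuration list
#' @export
cohortPhantomConfig <- function(...) {
    base <- phantomConfig(
        striatum_ipsi = list(center = c(0, 0, -230), semi = c(320, 200, 150)),
        striatum_contra = list(center = c(0, 0, 230), semi = c(320, 200, 150)),
        corpus_callosum = list(lo = c(-320, -300, -410),
                               hi = c( 320, -240,  410)),
        graft_core = list(center = c(0, 0, -230), semi = c(120, 90, 75)),
        fiber = list(amplitude = 0.5, lambda = 40),
        cells = list(n = 40L, shell = 30),
        artifacts = list(n = 1L, radius = 30),
        truth_grid = 20)
    overrides <- list(...)
    if (length(overrides)) base <- utils::modifyList(base, overrides)
    base
}

#' Resolved run configuration for the end-to-end pipeline
#'
#' Bundles every tunable of a pipeline run: the master seed, phantom scene,
#' section geometry, fiber threshold rule, Abercrombie soma height, behavioral
#' inclusion threshold, group design with injected effects (multiplicative
#' core-volume / fiber-amplitude scalings, dorsal bias beta, cell-count
#' scaling), between-animal coefficient of variation, and the
#' behavior-reinnervation coupling. Fully serializable; a run is reproducible
#' from the configuration alone.
#'
#' @param ... named overrides merged into the defaults
#' @return configuration list
#' @export
runConfig <- function(...) {
    cfg <- list(
        seed = 1L,
        phantom = cohortPhantomConfig(),
        geometry = list(thickness = 40, gap = 120, pixel_size = 5.16,
                        width = 160L, height = 128L),
        threshold_rule = list(type = "fixed", k = 3, value = 0.1),
        abercrombie_d = 12,
        inclusion_threshold = 4,
        groups = list(
            sham = list(n = 6L, core_volume_scale = 1.0, amp_scale = 1.0,
                        beta = 0.15, cell_scale = 1.0),
            anodal = list(n = 6L, core_volume_scale = 1.6, amp_scale = 1.3,
                          beta = 1.0, cell_scale = 1.5),
            cathodal = list(n = 6L, core_volume_scale = 1.4, amp_scale = 1.0,
                            beta = 0.7, cell_scale = 0.8)),
        animal_cv = 0.25,
        behavior = list(baseline_mean = 12, baseline_sd = 3,
                        coupling = list(intercept = 6, slope = 20,
                                        sigma = 1.5),
                        week2_fraction = 0.6, week2_sigma = 1),
        tails = "two",
        t_variant = "student")
    overrides <- list(...)
    if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
    cfg
}

resolveRule <- function(r) {
    thresholdRule(type = r$type, k = if (is.null(r$k)) 3 else r$k,
                  value = if (is.null(r$value)) NA_real_ else r$value)
}

#' Simulate a multi-group cohort of sectioned phantoms
#'
#' Applies each group's injected effect to the base phantom configuration,
#' adds lognormal between-animal variability (volume and amplitude CV from
#' \code{animal_cv}), and sections every animal. All randomness derives from
#' the single seed.
#'
#' @param config a \code{\link{runConfig}}
#' @param seed master seed (defaults to the configured one)
#' @return list with \code{animals} (data.frame id, group) and
#'   \code{datasets} (list of \linkS4class{SectionDataset})
#' @export
simulateCohort <- function(config = runConfig(), seed = config$seed) {
    g <- config$geometry
    geom <- sectionGeometry(g$thickness, g$gap, g$pixel_size, g$width,
                            g$height)
    sdlog <- sqrt(log(1 + config$animal_cv^2))
    set.seed(seed)
    ids <- character(); grp <- character(); datasets <- list()
    idx <- 0L
    for (gname in names(config$groups)) {
        ge <- config$groups[[gname]]
        for (a in seq_len(ge$n)) {
            idx <- idx + 1L
            volj <- exp(stats::rnorm(1, 0, sdlog))
            ampj <- exp(stats::rnorm(1, 0, sdlog))
            semi_mult <- (ge$core_volume_scale * volj)^(1 / 3)
            base <- config$phantom
            pcfg <- utils::modifyList(base, list(
                graft_core = list(center = base$graft_core$center,
                                  semi = base$graft_core$semi * semi_mult),
                fiber = list(amplitude = min(base$fiber$amplitude *
                                                 ge$amp_scale * ampj, 1.1),
                             beta = ge$beta),
                cells = list(n = max(0L, as.integer(round(
                    base$cells$n * ge$cell_scale * volj))))))
            aseed <- seed * 1000L + idx
            ph <- generatePhantom(pcfg, seed = aseed)
            datasets[[idx]] <- sectionPhantom(ph, geom, seed = aseed)
            ids[idx] <- sprintf("A%02d", idx)
            grp[idx] <- gname
        }
    }
    if (!idx) stop("empty cohort: no animal simulated")
    list(animals = data.frame(animal_id = ids, group = grp,
                              stringsAsFactors = FALSE),
         datasets = datasets, geometry = geom)
}

contentHash <- function(x) {
    f <- tempfile(fileext = ".rds")
    on.exit(unlink(f))
    saveRDS(x, f, compress = FALSE)
    unname(tools::md5sum(f))
}

ksGatedComparison <- function(x, y, variant = "student") {
    gx <- ksNormality(x); gy <- ksNormality(y)
    normal <- isTRUE(gx$p > 0.05) && isTRUE(gy$p > 0.05)
    if (normal) {
        r <- twoSampleT(x, y, variant = variant, tails = "two")
        list(method = r$method, statistic = r$statistic, df = r$df, p = r$p,
             route = "t")
    } else {
        r <- mannWhitneyU(x, y)
        list(method = r$method, statistic = r$U, Z = r$Z, df = NA_real_,
             p = r$p, route = "mann_whitney")
    }
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates the cohort, quantifies every animal's graft
#' (\code{\link{quantifyGraft}}), generates rotometry data coupled to the
#' measured integrated fiber density, and runs the cohort statistics: for each
#' graft metric a normality-gated two-sample comparison of each active group
#' against sham; a mixed repeated-measures ANOVA of the rotation timecourse
#' per comparison; and an OLS regression of behavioral improvement on
#' integrated fiber density and group (coded sham = 0, anodal = 1,
#' cathodal = 2, coding recorded in the report).
#'
#' @param config a \code{\link{runConfig}}
#' @param seed master seed (defaults to the configured one)
#' @return report list embedding the resolved configuration, a content hash of
#'   the quantified inputs, the per-animal metrics, the rotation table and all
#'   test results
#' @export
runPipeline <- function(config = runConfig(), seed = config$seed) {
    cohort <- simulateCohort(config, seed)
    rule <- resolveRule(config$threshold_rule)
    mets <- lapply(cohort$datasets, quantifyGraft, rule = rule,
                   abercrombieD = config$abercrombie_d)
    metrics <- cbind(cohort$animals, do.call(rbind, lapply(mets, function(m)
        as.data.frame(m$metrics[c("core_volume_mm3", "fiber_volume_mm3",
                                  "rel_density_percent",
                                  "integrated_fiber_density", "dv_ratio",
                                  "th_count", "cells_per_mm3")]))))

    b <- config$behavior
    rot <- generateRotationData(
        rotationConfig(baseline_mean = b$baseline_mean,
                       baseline_sd = b$baseline_sd,
                       inclusion_min = config$inclusion_threshold,
                       coupling = b$coupling,
                       week2_fraction = b$week2_fraction,
                       week2_sigma = b$week2_sigma),
        ifd = metrics$integrated_fiber_density,
        groups = metrics$group, seed = seed + 500L)

    groups <- unique(metrics$group)
    active <- setdiff(groups, "sham")
    metricNames <- c("core_volume_mm3", "fiber_volume_mm3",
                     "rel_density_percent", "integrated_fiber_density",
                     "dv_ratio", "th_count", "cells_per_mm3")
    comparisons <- list()
    for (gname in active) for (m in metricNames) {
        x <- metrics[[m]][metrics$group == "sham"]
        y <- metrics[[m]][metrics$group == gname]
        key <- paste(gname, "vs sham:", m)
        comparisons[[key]] <- tryCatch(
            ksGatedComparison(x, y, config$t_variant),
            error = function(e) list(method = "failed",
                                     note = conditionMessage(e)))
    }

    anovas <- list()
    for (gname in active) {
        sub <- rot[rot$group %in% c("sham", gname), ]
        anovas[[paste(gname, "vs sham")]] <- rmAnovaMixed(sub)
    }

    wide_base <- rot$net_turns_per_min[rot$timepoint == "baseline"]
    wide_w5 <- rot$net_turns_per_min[rot$timepoint == "week5"]
    impr <- improvement(wide_base, wide_w5)
    gcode <- c(sham = 0L, anodal = 1L, cathodal = 2L)[metrics$group]
    regression <- tryCatch(
        olsFit(impr, data.frame(integrated_fiber_density =
                                    metrics$integrated_fiber_density,
                                group = as.integer(gcode))),
        error = function(e) list(flag = "degenerate",
                                 note = conditionMessage(e)))

    list(config = config, seed = seed,
         input_hash = contentHash(list(metrics = metrics, rotation = rot)),
         group_coding = as.list(c(sham = 0L, anodal = 1L, cathodal = 2L)),
         metrics = metrics, rotation = rot,
         group_comparisons = comparisons, rm_anova = anovas,
         regression = regression,
         decisions = list(
             density_pooling = "pooled across sections",
             improvement = "baseline minus week5 (absolute turns/min)",
             threshold_rule = config$threshold_rule))
}

#' Write a pipeline report to JSON
#'
#' @param report list from \code{\link{runPipeline}}
#' @param path output file
#' @return the path, invisibly
#' @export
writeReport <- function(report, path) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    invisible(path)
}
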
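#' Default rotometry cohort configuration
#'
#' Configuration for \code{\link{generateRotationData}}. Baseline
#' amphetamine-induced net rotation rates are drawn from a normal distribution
#' (default mean 12, SD 3 turns/min, ipsiversive positive — typical of a
#' complete unilateral 6-OHDA lesion) and, when \code{ensure_included} is
#' TRUE, resampled until every animal exceeds the inclusion threshold of more
#' than four net turns/min. Behavioral improvement at week 5 is coupled
#' linearly to each animal's integrated fiber density (IFD):
#' improvement = intercept + slope * IFD + N(0, sigma); week-5 rate =
#' baseline - improvement, and the week-2 rate realises a configurable
#' fraction of the improvement (partial recovery at the earlier timepoint).
#'
#' @param ... named overrides merged into the defaults
#' @return configuration list
#' @export
rotationConfig <- function(...) {
    cfg <- list(
        n = 24L,
        groups = c("sham", "anodal", "cathodal"),
        baseline_mean = 12, baseline_sd = 3,
        inclusion_min = 4, ensure_included = TRUE,
        ifd_mean = 1, ifd_sd = 0.3,
        coupling = list(intercept = 8, slope = -0.5, sigma = 1),
        week2_fraction = 0.6, week2_sigma = 1)
    overrides <- list(...)
    if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
    cfg
}

#' Generate a synthetic rotometry dataset coupled to reinnervation
#'
#' Deterministic per seed. Returns one row per animal and timepoint
#' (baseline, week2, week5) with signed net full-body turns/min (positive =
#' ipsilateral to the lesion). The per-animal integrated fiber density, the
#' realised improvement and the resolved configuration are attached as
#' attributes \code{"ifd"}, \code{"improvement"} and \code{"config"}.
#'
#' @param config list from \code{\link{rotationConfig}}
#' @param ifd optional numeric vector of per-animal integrated fiber densities
#'   (e.g. measured from a sectioned cohort); drawn from the configured normal
#'   when NULL
#' @param groups optional character vector of group labels per animal;
#'   defaults to an even split of \code{config$groups}
#' @param seed integer seed
#' @return data.frame with columns animal_id, group, timepoint,
#'   net_turns_per_min
#' @export
#' @examples
#' rot <- generateRotationData(rotationConfig(n = 6L), seed = 1)
#' head(rot)
generateRotationData <- function(config = rotationConfig(), ifd = NULL,
                                 groups = NULL, seed = 1L) {
    if (config$coupling$sigma < 0)
        stop("coupling sigma must be non-negative")
    set.seed(seed)
    n <- if (!is.null(ifd)) length(ifd) else as.integer(config$n)
    if (n < 1) stop("cohort must contain at least one animal")
    if (is.null(ifd)) ifd <- stats::rnorm(n, config$ifd_mean, config$ifd_sd)
    if (is.null(groups))
        groups <- rep(config$groups, length.out = n)
    if (length(groups) != n) stop("groups must have one label per animal")

    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    if (isTRUE(config$ensure_included)) {
        bad <- which(baseline <= config$inclusion_min)
        while (length(bad)) {
            baseline[bad] <- stats::rnorm(length(bad), config$baseline_mean,
                                          config$baseline_sd)
            bad <- which(baseline <= config$inclusion_min)
        }
    }
    impr <- config$coupling$intercept + config$coupling$slope * ifd +
        stats::rnorm(n, 0, config$coupling$sigma)
    week5 <- baseline - impr
    week2 <- baseline - config$week2_fraction * impr +
        stats::rnorm(n, 0, config$week2_sigma)

    ids <- sprintf("A%02d", seq_len(n))
    out <- data.frame(
        animal_id = rep(ids, times = 3),
        group = rep(groups, times = 3),
        timepoint = rep(c("baseline", "week2", "week5"), each = n),
        net_turns_per_min = c(baseline, week2, week5),
        stringsAsFactors = FALSE)
    attr(out, "ifd") <- ifd
    attr(out, "improvement") <- impr
    attr(out, "config") <- config
    out
}

#' Generate a synthetic per-hemisphere BDNF concentration table
#'
#' Emulates an ELISA readout (pg BDNF per ug soluble protein) for stimulated
#' and contralateral striata of sham- and anodal-stimulated naive animals.
#' Contralateral values are drawn from a common normal; the stimulated
#' hemisphere is the contralateral value times a group-specific
#' interhemispheric ratio (sham centred at 1, anodal elevated).
#'
#' @param n_sham,n_anodal group sizes
#' @param contra_mean,contra_sd contralateral concentration (pg/ug)
#' @param ratio_sham,ratio_anodal mean stimulated/contralateral ratios
#' @param ratio_sd_sham,ratio_sd_anodal between-animal SDs of the ratios
#' @param seed integer seed
#' @return data.frame with columns animal_id, group, hemisphere,
#'   bdnf_pg_per_ug
#' @export
generateBdnfData <- function(n_sham = 7L, n_anodal = 9L,
                             contra_mean = 30, contra_sd = 4,
                             ratio_sham = 0.99, ratio_anodal = 1.20,
                             ratio_sd_sham = 0.12, ratio_sd_anodal = 0.32,
                             seed = 1L) {
    set.seed(seed)
    n <- n_sham + n_anodal
    group <- rep(c("sham", "anodal"), c(n_sham, n_anodal))
    contra <- pmax(stats::rnorm(n, contra_mean, contra_sd), 1)
    ratio <- stats::rnorm(n, ifelse(group == "sham", ratio_sham, ratio_anodal),
                          ifelse(group == "sham", ratio_sd_sham,
                                 ratio_sd_anodal))
    ratio <- pmax(ratio, 0.05)
    ids <- sprintf("B%02d", seq_len(n))
    data.frame(
        animal_id = rep(ids, each = 2),
        group = rep(group, each = 2),
        hemisphere = rep(c("stimulated", "contralateral"), times = n),
        bdnf_pg_per_ug = as.vector(rbind(contra * ratio, contra)),
        stringsAsFactors = FALSE)
}
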
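#' Net rotation rate from raw rotometer turn counts
#'
#' Signed net full-body turns per minute: positive values are rotations
#' ipsilateral to the lesion, negative values contralateral
#' (overcompensation).
#'
#' @param ipsiTurns,contraTurns full-body turn counts (>= 0), vectorised
#' @param minutes session duration in minutes (> 0)
#' @return net turns/min
#' @export
#' @examples
#' netRotationRate(900, 0, 90)  # 10
netRotationRate <- function(ipsiTurns, contraTurns, minutes) {
    if (any(minutes <= 0)) stop("minutes must be positive")
    if (any(ipsiTurns < 0) || any(contraTurns < 0))
        stop("turn counts must be non-negative")
    (ipsiTurns - contraTurns) / minutes
}

#' Apply the lesion-severity inclusion rule
#'
#' Animals qualify when their baseline net ipsiversive rate is strictly above
#' the threshold ("more than four full body turns per minute").
#'
#' @param rates named numeric vector of baseline net turns/min
#' @param threshold inclusion threshold, default 4 turns/min
#' @return the included elements of \code{rates} (names preserved)
#' @export
#' @examples
#' applyInclusion(c(a = 12.2, b = 3.0, c = 4.1))
applyInclusion <- function(rates, threshold = 4) {
    keep <- rates > threshold
    if (!any(keep)) warning("no animal passed the inclusion threshold")
    rates[keep]
}

#' Allocate animals to groups balanced on baseline performance
#'
#' Stratified allocation: animals are sorted by baseline rate (descending,
#' ties broken by a seeded shuffle) and dealt to the k groups in serpentine
#' order (1..k, k..1, ...); a greedy pass of mean-balancing pairwise swaps
#' (which preserves group sizes) then tightens the allocation until no single
#' exchange reduces the largest difference between group mean baselines.
#'
#' @param baseline numeric vector of baseline rates
#' @param k number of groups (1 <= k <= length(baseline))
#' @param seed integer seed for tie breaking
#' @return integer vector of group indices (1..k), one per animal, in the
#'   input order
#' @export
#' @examples
#' allocateBalancedGroups(9:1, k = 3)
allocateBalancedGroups <- function(baseline, k, seed = 1L) {
    n <- length(baseline)
    if (k < 1) stop("k must be >= 1")
    if (k > n) stop("more groups (", k, ") than animals (", n, ")")
    set.seed(seed)
    perm <- sample.int(n)                      # seeded tie-break
    ord <- perm[order(-baseline[perm])]        # stable sort, descending
    pattern <- rep_len(c(seq_len(k), rev(seq_len(k))), n)
    g <- integer(n)
    g[ord] <- pattern
    if (k == 1L) return(g)

    spread <- function(gg) {
        m <- vapply(seq_len(k), function(j) mean(baseline[gg == j]),
                    numeric(1))
        max(m) - min(m)
    }
    best <- spread(g)
    repeat {
        improved <- FALSE
        for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
            if (g[i] == g[j]) next
            cand <- g
            cand[c(i, j)] <- g[c(j, i)]
            s <- spread(cand)
            if (s < best - 1e-12) {
                g <- cand; best <- s; improved <- TRUE
            }
        }
        if (!improved) break
    }
    g
}

#' Classify week-5 behavioral recovery
#'
#' Rates at or below zero (no residual ipsiversive rotation, or
#' overcompensation) count as full recovery; positive residual rotation is
#' partial recovery.
#'
#' @param week5Rate signed net turns/min at week 5, vectorised
#' @return character vector: "full recovery/overcompensation" or "partial"
#' @export
classifyRecovery <- function(week5Rate) {
    ifelse(week5Rate <= 0, "full recovery/overcompensation", "partial")
}

#' Behavioral improvement between baseline and week 5
#'
#' Default is the signed difference baseline - week5 in turns/min (larger =
#' more improvement); \code{relative = TRUE} expresses it as percent of
#' baseline instead.
#'
#' @param baseline,week5 net turns/min, vectorised
#' @param relative report percent of baseline instead of the difference
#' @return numeric vector
#' @export
#' @examples
#' improvement(12, -1)  # 13
improvement <- function(baseline, week5, relative = FALSE) {
    d <- baseline - week5
    if (relative) 100 * d / baseline else d
}
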
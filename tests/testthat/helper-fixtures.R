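# Small in-code fixtures shared across test files.

# 160 x 128 px scene, 4 sections: fast enough to regenerate per test.
tinyGeometry <- function(...) {
    sectionGeometry(thickness = 40, gap = 120, pixelSize = 5.16,
                    width = 160L, height = 128L, ...)
}

tinyPhantomConfig <- function(...) cohortPhantomConfig(...)

# Hand-built two-hemisphere section: striata are mirror-image column bands,
# the corpus callosum a top row band spanning both hemispheres. Intensities
# are exact (no rounding) so OD arithmetic is closed-form.
toySection <- function(width = 20L, height = 12L, background = 200,
                       od_ipsi = 0.3, od_contra = 0.3) {
    codes <- roiLabels()
    lab <- matrix(0L, height, width)
    lab[1:2, ] <- codes[["corpus_callosum"]]
    lab[5:10, 3:8] <- codes[["striatum_ipsi"]]
    lab[5:10, (width - 7):(width - 2)] <- codes[["striatum_contra"]]
    img <- matrix(background, height, width)
    img[lab == codes[["striatum_ipsi"]]] <- background * 10^-od_ipsi
    img[lab == codes[["striatum_contra"]]] <- background * 10^-od_contra
    list(image = img, label = lab)
}

toyDataset <- function(n = 2L, width = 20L, height = 12L, bitDepth = 8L,
                       od_ipsi = 0.3, od_contra = 0.3, truth = list()) {
    secs <- lapply(seq_len(n), function(i)
        toySection(width, height, od_ipsi = od_ipsi, od_contra = od_contra))
    new("SectionDataset",
        images = lapply(secs, `[[`, "image"),
        labels = lapply(secs, `[[`, "label"),
        geometry = sectionGeometry(width = width, height = height),
        bitDepth = bitDepth, truth = truth)
}

# Exact Mann-Whitney two-sided p by complete enumeration of group labellings.
mwExactOracle <- function(x, y) {
    nx <- length(x); ny <- length(y); N <- nx + ny
    v <- c(x, y)
    combos <- utils::combn(N, nx)
    r <- rank(v)
    us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
    u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    pl <- mean(us <= u_obs); pg <- mean(us >= u_obs)
    min(1, 2 * min(pl, pg))
}

# Best achievable max pairwise difference of group mean baselines over all
# size-balanced assignments (exhaustive; n <= 9).
balancedAllocationOracle <- function(baseline, k) {
    n <- length(baseline)
    sizes_ok <- function(g) {
        s <- tabulate(g, k)
        max(s) - min(s) <= 1
    }
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
    best <- Inf
    for (i in seq_len(nrow(grid))) {
        g <- grid[i, ]
        if (!sizes_ok(g)) next
        m <- tapply(baseline, g, mean)
        d <- max(m) - min(m)
        if (d < best) best <- d
    }
    best
}

maxGroupMeanDiff <- function(baseline, g) {
    m <- tapply(baseline, g, mean)
    max(m) - min(m)
}
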
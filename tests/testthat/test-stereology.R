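test_that("frustum volume honours its limit cases and symmetry", {
    expect_equal(frustumVolume(2, 2, 0.1), 0.2)          # cylinder: h * A
    expect_equal(frustumVolume(3, 0, 0.3), 0.3)          # cone: h * A / 3
    expect_equal(frustumVolume(1, 0.25, 0.16), 0.0933333, tolerance = 1e-6)
    expect_identical(frustumVolume(1, 0.25, 0.16), frustumVolume(0.25, 1, 0.16))
    expect_equal(frustumVolume(1, 0.25, 0.32), 2 * frustumVolume(1, 0.25, 0.16))
    expect_error(frustumVolume(-1, 1, 0.1), "non-negative")
    expect_error(frustumVolume(1, 1, 0), "positive")
})

test_that("series volume sums consecutive frusta", {
    expect_equal(seriesVolume(rep(1e6, 5), 160), 4 * 0.16)   # (N-1) h A
    expect_warning(v1 <- seriesVolume(1e6, 160), "single section")
    expect_identical(v1, 0)
    expect_equal(seriesVolume(c(1, 0.25), 0.16, areaUnit = "mm2",
                              spacingUnit = "mm"), 0.0933333,
                 tolerance = 1e-6)
    expect_error(seriesVolume(c(1, -1), 160), "non-negative")
    expect_error(seriesVolume(numeric(0), 160), "empty")
})

sphereAreas <- function(h) {
    xm <- seq(-1 + h / 2, 1 - h / 2, by = h)
    pi * pmax(1 - xm^2, 0)
}

test_that("frustum sums converge to the analytic sphere volume", {
    truth <- 4 / 3 * pi
    err <- vapply(c(0.2, 0.1, 0.05, 0.025), function(h)
        abs(seriesVolume(sphereAreas(h), h, areaUnit = "mm2",
                         spacingUnit = "mm") - truth) / truth, numeric(1))
    expect_lt(err[3], 0.01)                  # h = r/20
    expect_lt(err[4], err[1])                # finer sampling is better
    expect_lt(err[2], 0.02)                  # h = r/10
})

test_that("Abercrombie correction matches its closed form", {
    expect_equal(abercrombieEstimate(100, 40, 0)$estimate, 100)
    expect_equal(abercrombieEstimate(100, 40, 40)$estimate, 50)
    est <- abercrombieEstimate(137, 40, 12)
    expect_lte(est$estimate, est$profiles)   # correction only shrinks
    expect_equal(est$estimate, 137 * 40 / 52)
    expect_error(abercrombieEstimate(10, 0, 12), "thickness")
})

test_that("profile sampling is unbiased after Abercrombie correction", {
    # exhaustive 40-um sectioning (no gap) of 500 spheres of 12 um
    g <- sectionGeometry(thickness = 40, gap = 0, width = 8L, height = 8L)
    set.seed(20)
    reps <- 50
    est <- vapply(seq_len(reps), function(r) {
        cells <- data.frame(x = runif(500, 0, 1000), diameter = 12)
        n <- sum(sectionProfileCounts(cells, g, c(0, 1000)))
        abercrombieEstimate(n, 40, 12)$estimate
    }, numeric(1))
    expect_lt(abs(mean(est) - 500) / 500, 0.05)
})

test_that("cell density divides count by core volume", {
    expect_equal(cellsPerVolume(800, 1), 800)
    expect_equal(cellsPerVolume(0, 1), 0)
    expect_equal(cellsPerVolume(645 * 1.37, 1.37), 645)
    expect_error(cellsPerVolume(10, 0), "positive")
})

test_that("profile counter separates discs and rejects specks", {
    odm <- matrix(0, 40, 40)
    d2a <- (row(odm) - 10)^2 + (col(odm) - 10)^2
    d2b <- (row(odm) - 30)^2 + (col(odm) - 30)^2
    odm[d2a <= 4 | d2b <= 4] <- 1.4
    odm[5, 35] <- 1.4                        # single-pixel speck
    od <- new("ODImage", od = odm, referenceMean = 200, section = 1L)
    expect_identical(countCellProfiles(od, matrix(TRUE, 40, 40), 1.2), 2L)
    expect_identical(countCellProfiles(od, matrix(TRUE, 40, 40), 1.2,
                                       minPixels = 1L), 3L)
})

test_that("image-based profile counts track the geometric sampling", {
    cfg <- tinyPhantomConfig(cells = list(n = 25L), artifacts = list(n = 0L),
                             render = list(noise_sd = 0))
    ph <- generatePhantom(cfg, seed = 9)
    ds <- sectionPhantom(ph, tinyGeometry(), seed = 9)
    geometric <- sum(truths(ds)$profile_counts)
    counted <- sum(vapply(seq_len(nSections(ds)), function(i) {
        cc <- roiMask(ds, "corpus_callosum", i)
        od <- sectionOD(sectionImage(ds, i), cc, i)
        countCellProfiles(od, roiMask(ds, "striatum_ipsi", i), 1.2)
    }, integer(1)))
    expect_gt(geometric, 0)
    # rasterisation at 5.16 um/px loses grazing sub-pixel profiles and can
    # merge touching somata; tolerate a moderate undercount
    expect_gte(counted, 0.6 * geometric)
    expect_lte(counted, geometric)
})
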
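test_that("optical density is the clipped log-ratio to the reference mean", {
    img <- matrix(100, 8, 8)
    ref <- col(img) > 6
    od <- sectionOD(img, ref)
    expect_true(all(od@od == 0))                 # uniform image -> OD 0
    img[1, 1] <- 10
    img[2, 2] <- 400                             # brighter than reference
    od <- sectionOD(img, ref)
    expect_equal(od@od[1, 1], 1)                 # log10(100/10)
    expect_identical(od@od[2, 2], 0)             # clipped at zero
    expect_identical(od@referenceMean, 100)
    img[3, 3] <- 0                               # clamped to 1 before log
    expect_equal(sectionOD(img, ref)@od[3, 3], 2)
    expect_error(sectionOD(img, matrix(FALSE, 8, 8)), "reference mask")
})

test_that("fiber segmentation counts strictly supra-threshold pixels", {
    odm <- matrix(0, 50, 50)
    odm[25, 25] <- 0.5
    od <- new("ODImage", od = odm, referenceMean = 200, section = 1L)
    all_mask <- matrix(TRUE, 50, 50)
    seg <- segmentFibers(od, all_mask, thresholdRule("fixed", value = 0.5),
                         pixelSize = 5.16)
    expect_identical(seg@positivePixels, 0L)     # exactly at theta: excluded
    seg <- segmentFibers(od, all_mask, thresholdRule("fixed", value = 0.49),
                         pixelSize = 5.16)
    expect_identical(seg@positivePixels, 1L)
    expect_equal(seg@areaUm2, 5.16^2)
    expect_warning(
        segmentFibers(od, matrix(FALSE, 50, 50),
                      thresholdRule("fixed", value = 0.1), 5.16),
        "empty analysis mask")
})

test_that("a rasterized disc recovers its analytic area within one pixel ring", {
    n <- 101L
    odm <- matrix(0, n, n)
    d2 <- (row(odm) - 51)^2 + (col(odm) - 51)^2
    odm[d2 <= 20^2] <- 1
    od <- new("ODImage", od = odm, referenceMean = 200, section = 1L)
    seg <- segmentFibers(od, matrix(TRUE, n, n),
                         thresholdRule("fixed", value = 0.5), pixelSize = 5.16)
    ring_px <- pi * (20.5^2 - 19.5^2)
    expect_lt(abs(seg@positivePixels - pi * 20^2), ring_px)
    expect_equal(seg@areaUm2, seg@positivePixels * 5.16^2)
})

test_that("reference-anchored thresholds and areas are ratiometric", {
    set.seed(11)
    img <- matrix(runif(400, 80, 200), 20, 20)
    ref <- row(img) <= 3
    rule <- thresholdRule("reference_sd", k = 2)
    odA <- sectionOD(img, ref)
    segA <- segmentFibers(odA, !ref, rule, 5.16, referenceMask = ref)
    odB <- sectionOD(img * 2, ref)               # global rescale
    segB <- segmentFibers(odB, !ref, rule, 5.16, referenceMask = ref)
    expect_equal(odA@od, odB@od, tolerance = 1e-12)
    expect_identical(segA@positivePixels, segB@positivePixels)
})

test_that("segmented area is non-increasing in the threshold", {
    set.seed(12)
    odm <- matrix(abs(rnorm(900, 0.2, 0.2)), 30, 30)
    od <- new("ODImage", od = odm, referenceMean = 200, section = 1L)
    areas <- vapply(seq(0, 0.8, by = 0.05), function(th)
        segmentFibers(od, matrix(TRUE, 30, 30),
                      thresholdRule("fixed", value = th), 1)@areaUm2,
        numeric(1))
    expect_true(all(diff(areas) <= 0))
})

test_that("mirrorMask is an involution that flips columns", {
    m <- matrix(FALSE, 2, 10)
    m[1, 4] <- TRUE                       # zero-based column 3
    mm <- mirrorMask(m)
    expect_true(mm[1, 7])                 # zero-based column 10 - 1 - 3 = 6
    expect_identical(mirrorMask(mm), m)
    expect_identical(sum(mm), sum(m))
    sym <- matrix(c(1, 0, 1), 1, 3) > 0   # symmetric about the midline
    expect_identical(mirrorMask(sym), sym)
})

test_that("relative fiber density is 100% for identical hemispheric stain", {
    ds <- toyDataset(od_ipsi = 0.3, od_contra = 0.3)
    res <- relativeFiberDensity(ds, thresholdRule("fixed", value = 0.05))
    expect_equal(res$percent, 100)
    expect_identical(res$flag, "ok")
})

test_that("halved lesioned stain gives 50% relative density", {
    ds <- toyDataset(od_ipsi = 0.15, od_contra = 0.3)
    res <- relativeFiberDensity(ds, thresholdRule("fixed", value = 0.05))
    expect_equal(res$percent, 50)
})

test_that("empty lesioned fiber mask yields 0% with a warning", {
    ds <- toyDataset(od_ipsi = 0, od_contra = 0.3)
    expect_warning(
        res <- relativeFiberDensity(ds, thresholdRule("fixed", value = 0.05)),
        "no positive lesioned-side")
    expect_identical(res$percent, 0)
    expect_identical(res$flag, "empty_lesioned")
})

test_that("missing contralateral signal is flagged, not silently zero", {
    ds <- toyDataset(od_ipsi = 0.3, od_contra = 0)
    expect_warning(
        res <- relativeFiberDensity(ds, thresholdRule("fixed", value = 0.05)),
        "contralateral")
    expect_true(is.na(res$percent))
    expect_identical(res$flag, "no_contra_positive")
})
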
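test_that("phantom generation is deterministic and validates geometry", {
    cfg <- tinyPhantomConfig()
    p1 <- generatePhantom(cfg, seed = 7)
    p2 <- generatePhantom(cfg, seed = 7)
    expect_identical(p1@cells, p2@cells)
    expect_identical(p1@truths, p2@truths)
    expect_identical(p1@regions, p2@regions)

    bad <- tinyPhantomConfig(graft_core = list(center = c(0, 0, -230),
                                               semi = c(500, 90, 75)))
    expect_error(generatePhantom(bad), "not contained")
})

test_that("analytic core volume matches the ellipsoid closed form", {
    cfg <- phantomConfig(graft_core = list(center = c(0, 0, -620),
                                           semi = c(500, 500, 500)))
    expect_error(generatePhantom(cfg), "not contained")  # 500 > 380 axially
    cfg <- phantomConfig(
        striatum_ipsi = list(center = c(0, 0, -620), semi = c(800, 600, 600)),
        striatum_contra = list(center = c(0, 0, 820), semi = c(100, 100, 100)),
        graft_core = list(center = c(0, 0, -620), semi = c(500, 500, 500)))
    ph <- generatePhantom(cfg, seed = 1)
    expect_equal(truths(ph)$core_volume_mm3, 0.5236, tolerance = 1e-4)
})

test_that("zero configured cells yield an empty cell list", {
    ph <- generatePhantom(tinyPhantomConfig(cells = list(n = 0L)), seed = 1)
    expect_identical(nrow(ph@cells), 0L)
    expect_identical(truths(ph)$cell_count, 0L)
})

test_that("cells stay within the shell-dilated graft core", {
    ph <- generatePhantom(tinyPhantomConfig(cells = list(n = 400L)), seed = 3)
    core <- ph@regions$graft_core
    shell <- ph@config$cells$shell
    u <- sqrt(((ph@cells$x - core$center[1]) / (core$semi[1] + shell))^2 +
              ((ph@cells$y - core$center[2]) / (core$semi[2] + shell))^2 +
              ((ph@cells$z - core$center[3]) / (core$semi[3] + shell))^2)
    expect_true(all(u <= 1 + 1e-9))
})

test_that("dorsal bias produces the configured stain-mass ratio", {
    # symmetric scene about the core centre row: dorsal/ventral stain mass
    # converges to exactly 1 + beta in the noiseless field
    ph0 <- generatePhantom(tinyPhantomConfig(), seed = 1)
    expect_equal(truths(ph0)$dv_mass_ratio, 1, tolerance = 1e-9)
    ph1 <- generatePhantom(tinyPhantomConfig(fiber = list(beta = 1)), seed = 1)
    expect_equal(truths(ph1)$dv_mass_ratio, 2, tolerance = 1e-9)
    expect_gt(truths(ph1)$dv_ratio, 1)
})

test_that("sectioning cuts floor(extent / spacing) sections", {
    # default scene spans 1600 um along the cutting axis; h = 160 -> 10
    ph <- generatePhantom(phantomConfig(cells = list(n = 0L)), seed = 1)
    ds <- sectionPhantom(ph, sectionGeometry(width = 512L, height = 384L))
    expect_identical(nSections(ds), 10L)
    expect_error(
        sectionPhantom(ph, sectionGeometry(thickness = 900, gap = 900,
                                           width = 512L, height = 384L)),
        "shorter than the section spacing")
})

test_that("sectioning is deterministic and masks are pairwise disjoint", {
    cfg <- tinyPhantomConfig()
    ph <- generatePhantom(cfg, seed = 2)
    d1 <- sectionPhantom(ph, tinyGeometry(), seed = 2)
    d2 <- sectionPhantom(ph, tinyGeometry(), seed = 2)
    expect_identical(d1@images, d2@images)
    expect_identical(d1@labels, d2@labels)
    for (i in seq_len(nSections(d1))) {
        ipsi <- labelImage(d1, i) == roiLabels()[["striatum_ipsi"]]
        con <- roiMask(d1, "striatum_contra", i)
        cc <- roiMask(d1, "corpus_callosum", i)
        expect_false(any(ipsi & con))
        expect_false(any(ipsi & cc))
        expect_false(any(con & cc))
    }
})

test_that("flat field with zero noise renders pure background", {
    cfg <- tinyPhantomConfig(
        fiber = list(amplitude = 0, contra_od = 0, core_od = 0),
        cells = list(n = 0L), artifacts = list(n = 0L),
        render = list(noise_sd = 0))
    ph <- generatePhantom(cfg, seed = 1)
    ds <- sectionPhantom(ph, tinyGeometry(), seed = 1)
    expect_true(all(sectionImage(ds, 2) == cfg$render$background))
    cc <- roiMask(ds, "corpus_callosum", 2)
    od <- sectionOD(sectionImage(ds, 2), cc, 2)
    seg <- segmentFibers(od, fiberAnalysisMask(ds, 2),
                         thresholdRule("fixed", value = 0.1),
                         geometry(ds)@pixelSize)
    expect_identical(seg@areaUm2, 0)
})

test_that("Cavalieri sum of core mask areas approximates the true volume", {
    # h = 80 um <= core x-semi-axis / 5 for the default 400 um core
    ph <- generatePhantom(phantomConfig(cells = list(n = 0L),
                                        artifacts = list(n = 0L)), seed = 1)
    g <- sectionGeometry(thickness = 40, gap = 40, width = 512L,
                         height = 384L)
    ds <- sectionPhantom(ph, g, seed = 1)
    px <- g@pixelSize
    areas <- vapply(seq_len(nSections(ds)), function(i)
        sum(roiMask(ds, "graft_core", i)) * px^2, numeric(1))
    cavalieri <- sum(areas) * spacing(g) / 1e9
    expect_equal(cavalieri, truths(ph)$core_volume_mm3, tolerance = 0.05)
})

test_that("rotation generator is deterministic and honours the coupling", {
    cfg <- rotationConfig(n = 12L, coupling = list(intercept = 5, slope = 0,
                                                   sigma = 0))
    r1 <- generateRotationData(cfg, seed = 4)
    r2 <- generateRotationData(cfg, seed = 4)
    expect_identical(r1, r2)
    base <- r1$net_turns_per_min[r1$timepoint == "baseline"]
    w5 <- r1$net_turns_per_min[r1$timepoint == "week5"]
    expect_equal(base - w5, rep(5, 12))          # all improve by exactly a
    expect_true(all(base > 4))                   # inclusion enforced
    expect_error(generateRotationData(
        rotationConfig(coupling = list(intercept = 5, slope = 0,
                                       sigma = -1))),
        "sigma")
})

test_that("BDNF generator produces paired hemispheres per animal", {
    b <- generateBdnfData(n_sham = 4L, n_anodal = 5L, seed = 2)
    expect_identical(nrow(b), 18L)
    expect_identical(sum(b$hemisphere == "stimulated"), 9L)
    ratios <- with(b, bdnf_pg_per_ug[hemisphere == "stimulated"] /
                       bdnf_pg_per_ug[hemisphere == "contralateral"])
    expect_true(all(ratios > 0))
})
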
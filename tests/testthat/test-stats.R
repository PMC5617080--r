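test_that("KS gate rejects uniform data and accepts normal data", {
    set.seed(21)
    expect_lt(ksNormality(runif(500))$p, 0.01)
    ok <- vapply(1:20, function(i) {
        set.seed(100 + i)
        ksNormality(rnorm(500))$p > 0.05
    }, logical(1))
    expect_gte(mean(ok), 0.9)
    expect_warning(r <- ksNormality(rep(1, 10)), "constant")
    expect_true(r$degenerate)
    expect_error(ksNormality(c(1, 2)), "at least 3")
})

test_that("two-sample t matches the pooled-variance hand computation", {
    r <- twoSampleT(c(1, 2, 3, 4), c(2, 3, 4, 5), variant = "student")
    expect_equal(r$statistic, -1.0954451, tolerance = 1e-6)
    expect_equal(r$df, 6)

    same <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$statistic, 0)
    expect_equal(same$p, 1)

    expect_warning(d <- twoSampleT(c(2, 2), c(2, 2)), "undefined")
    expect_identical(d$flag, "degenerate")
})

test_that("t statistic is antisymmetric and Welch df never exceeds Student", {
    set.seed(22)
    for (i in 1:10) {
        x <- rnorm(sample(4:9, 1)); y <- rnorm(sample(4:9, 1), sd = runif(1, 0.5, 2))
        a <- twoSampleT(x, y); b <- twoSampleT(y, x)
        expect_equal(a$statistic, -b$statistic)
        expect_equal(a$p, b$p)
        expect_lte(twoSampleT(x, y, "welch")$df, a$df + 1e-9)
    }
    eq <- twoSampleT(c(1, 2, 3), c(4, 5, 6), "welch")  # equal n, equal var
    expect_equal(eq$df, 4)
})

test_that("upper-tailed t matches the directed one-sided p", {
    set.seed(23)
    x <- rnorm(9, 1.2); y <- rnorm(7)
    two <- twoSampleT(x, y, "welch", tails = "two")
    up <- twoSampleT(x, y, "welch", tails = "upper")
    expect_equal(up$statistic, two$statistic)
    expect_equal(up$p, stats::pt(two$statistic, two$df, lower.tail = FALSE))
})

test_that("Mann-Whitney U statistic and exact p behave as enumerated", {
    r <- mannWhitneyU(c(1, 2), c(3, 4))
    expect_equal(r$U, 0)                         # all x below all y
    expect_equal(r$p, 1 / 3, tolerance = 1e-12)  # 2 of 6 arrangements
    expect_true(r$exact)

    s <- mannWhitneyU(c(5, 6, 7), c(5, 6, 7))
    expect_equal(s$U, 3 * 3 / 2)                 # symmetry midpoint
    expect_false(s$exact)                        # ties: normal approximation
    expect_equal(s$Z, 0)
})

test_that("exact Mann-Whitney p agrees with full enumeration", {
    set.seed(24)
    for (i in 1:12) {
        nx <- sample(2:5, 1); ny <- sample(2:5, 1)
        repeat {
            x <- round(rnorm(nx), 3); y <- round(rnorm(ny), 3)
            if (!anyDuplicated(c(x, y))) break
        }
        r <- mannWhitneyU(x, y)
        expect_true(r$exact)
        expect_equal(r$p, mwExactOracle(x, y), tolerance = 1e-12)
    }
})

test_that("mixed RM-ANOVA decomposes TIME, GROUP and their interaction", {
    # constant over time: no TIME effect at all
    d <- expand.grid(animal_id = sprintf("a%d", 1:8),
                     timepoint = c("baseline", "week2", "week5"),
                     stringsAsFactors = FALSE)
    d$group <- ifelse(as.integer(factor(d$animal_id)) <= 4, "sham", "anodal")
    base <- stats::setNames(1:8 * 1.0, sprintf("a%d", 1:8))
    d$net_turns_per_min <- base[d$animal_id]
    r <- rmAnovaMixed(d)
    tt <- r$anova[r$anova$effect == "TIME", ]
    expect_equal(tt$F, 0)
    expect_equal(tt$p, 1)

    # injected strong time effect is detected
    set.seed(25)
    d2 <- d
    shift <- c(baseline = 0, week2 = -4, week5 = -8)
    d2$net_turns_per_min <- base[d2$animal_id] + shift[d2$timepoint] +
        rnorm(nrow(d2))
    r2 <- rmAnovaMixed(d2)
    expect_lt(r2$anova$p[r2$anova$effect == "TIME"], 0.001)
    expect_identical(nrow(r2$posthoc), 4L)       # 2 groups x 2 timepoints
    expect_true(all(r2$posthoc$p[r2$posthoc$comparison == "week5 vs baseline"] <
                    0.05))
    expect_true(is.na(r2$gg_epsilon) || (r2$gg_epsilon > 0 &&
                                         r2$gg_epsilon <= 1 + 1e-9))

    # incomplete design is rejected
    expect_error(rmAnovaMixed(d2[-1, ]), "incomplete")
})

test_that("OLS reports raw and standardized coefficients, F and R2", {
    x <- 1:10
    r <- olsFit(2 * x, data.frame(x = x))
    expect_equal(r$coefficients$estimate[2], 2)
    expect_equal(r$R2, 1)

    const <- olsFit(rep(3, 10), data.frame(x = x))
    expect_equal(const$coefficients$estimate[2], 0)
    expect_equal(const$R2, 0)
    expect_identical(const$flag, "degenerate")

    set.seed(26)
    z <- rnorm(30); y <- 1 + 0.8 * z + rnorm(30, 0, 0.3)
    a <- olsFit(y, data.frame(z = z))
    b <- olsFit(y, data.frame(z = z * 10))        # rescaled predictor
    expect_equal(a$coefficients$std_estimate[2], b$coefficients$std_estimate[2],
                 tolerance = 1e-10)
    expect_equal(a$coefficients$estimate[2], 10 * b$coefficients$estimate[2],
                 tolerance = 1e-10)

    expect_error(olsFit(y, data.frame(z = z, z2 = 2 * z)),
                 "collinear columns")
    expect_error(olsFit(1:3, data.frame(a = 1:3, b = c(1, 0, 2))),
                 "more observations")
})

test_that("interhemispheric ratio normalizes to the contralateral side", {
    expect_equal(interhemisphericRatio(30, 30), 100)
    expect_equal(interhemisphericRatio(36, 30), 120)
    expect_error(interhemisphericRatio(30, 0), "positive")
})

test_that("BDNF contrast runs Welch upper-tailed on interhemispheric ratios", {
    b <- generateBdnfData(seed = 31)
    stim <- b$bdnf_pg_per_ug[b$hemisphere == "stimulated"]
    con <- b$bdnf_pg_per_ug[b$hemisphere == "contralateral"]
    ratio <- interhemisphericRatio(stim, con)
    grp <- b$group[b$hemisphere == "stimulated"]
    r <- twoSampleT(ratio[grp == "anodal"], ratio[grp == "sham"],
                    variant = "welch", tails = "upper")
    expect_identical(r$tails, "upper")
    expect_gt(r$df, 0)
    expect_lt(r$p, 1)
})
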
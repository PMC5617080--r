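#' Kolmogorov-Smirnov normality gate
#'
#' One-sample KS test of x against a normal with the sample mean and SD, used
#' to decide whether a comparison is routed to the t test or to the
#' Mann-Whitney U test. Because the normal parameters are estimated from the
#' sample, the p value comes from the Lilliefors null distribution (the plain
#' KS p would be badly miscalibrated); for n of 3 or 4, where that
#' approximation is unavailable, the uncorrected KS p is used. A constant
#' sample is degenerate and flagged rather than tested.
#'
#' @param x numeric vector, n >= 3
#' @return list with statistic, p, n, method and a \code{degenerate} flag
#' @export
ksNormality <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3) stop("KS normality test needs at least 3 observations")
    s <- stats::sd(x)
    if (s == 0) {
        warning("constant sample: normality is undefined")
        return(list(statistic = NA_real_, p = NA_real_, n = length(x),
                    method = "one-sample KS vs fitted normal",
                    degenerate = TRUE))
    }
    if (length(x) >= 5) {
        kt <- nortest::lillie.test(x)
        method <- "one-sample KS vs fitted normal (Lilliefors p)"
    } else {
        kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s))
        method <- "one-sample KS vs fitted normal"
    }
    list(statistic = unname(kt$statistic), p = kt$p.value, n = length(x),
         method = method, degenerate = FALSE)
}

#' Two-sample t test (Student or Welch), two- or upper-tailed
#'
#' Student: pooled variance, df = n_x + n_y - 2. Welch: unpooled variances
#' with Welch-Satterthwaite fractional df (never larger than the Student df).
#' \code{tails = "upper"} tests the directed hypothesis that the first sample
#' mean exceeds the second (used for the BDNF contrast, stimulated group
#' first). When both samples have zero variance and equal means the statistic
#' is undefined and flagged.
#'
#' @param x,y numeric vectors with at least 2 observations each
#' @param variant "student" or "welch"
#' @param tails "two" or "upper"
#' @return list with statistic, df, p, tails, method and flag
#' @export
#' @examples
#' twoSampleT(c(1, 2, 3, 4), c(2, 3, 4, 5))$statistic  # -1.095
twoSampleT <- function(x, y, variant = c("student", "welch"),
                       tails = c("two", "upper")) {
    variant <- match.arg(variant); tails <- match.arg(tails)
    if (length(x) < 2 || length(y) < 2)
        stop("each sample needs at least 2 observations")
    method <- sprintf("%s t test (%s-tailed)",
                      if (variant == "student") "Student" else "Welch", tails)
    if (stats::var(x) == 0 && stats::var(y) == 0) {
        if (mean(x) == mean(y)) {
            warning("zero variance in both samples with equal means: ",
                    "t is undefined")
            return(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                        tails = tails, method = method, flag = "degenerate"))
        }
        # zero spread but distinct means: the difference is certain
        return(list(statistic = sign(mean(x) - mean(y)) * Inf,
                    df = length(x) + length(y) - 2, p = 0, tails = tails,
                    method = method, flag = "zero_variance"))
    }
    tt <- stats::t.test(x, y, var.equal = variant == "student",
                        alternative = if (tails == "two") "two.sided"
                                      else "greater")
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, tails = tails, method = method, flag = "ok")
}

#' Mann-Whitney U test with Z statistic
#'
#' Reports the U statistic for the first sample, the tie-corrected
#' normal-approximation Z, and a two-tailed p value: exact by enumeration
#' (no ties, n_x * n_y <= 400) or from the normal approximation otherwise.
#'
#' @param x,y numeric vectors (n >= 1 each)
#' @return list with U, Z, p, exact flag and method
#' @export
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))$p  # 1/3
mannWhitneyU <- function(x, y) {
    nx <- length(x); ny <- length(y)
    if (nx < 1 || ny < 1) stop("both samples must be nonempty")
    r <- rank(c(x, y))
    U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    N <- nx + ny
    ties <- table(c(x, y))
    tiecor <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tiecor)
    Z <- if (sigma2 > 0) (U - nx * ny / 2) / sqrt(sigma2) else 0
    hasTies <- any(ties > 1)
    exact <- !hasTies && nx * ny <= 400
    p <- if (exact)
        stats::wilcox.test(x, y, exact = TRUE)$p.value
    else
        min(1, 2 * stats::pnorm(-abs(Z)))
    list(U = U, Z = Z, p = p, exact = exact,
         method = if (exact) "Mann-Whitney U (exact)"
                  else "Mann-Whitney U (normal approximation)")
}

ggEpsilon <- function(wide) {
    # Greenhouse-Geisser epsilon from the double-centred covariance of the
    # within-subject measures
    S <- stats::cov(wide)
    k <- ncol(S)
    C <- diag(k) - 1 / k
    Sc <- C %*% S %*% C
    (sum(diag(Sc)))^2 / ((k - 1) * sum(Sc^2))
}

#' Mixed-design repeated-measures ANOVA
#'
#' Univariate mixed ANOVA with a within-subject factor (TIME) and a
#' between-subject factor (GROUP), sphericity assumed, as is conventional for
#' rotometry timecourses. The Greenhouse-Geisser epsilon is computed and
#' reported but not applied. Post hoc comparisons are per-group paired t tests
#' of each later timepoint against baseline, deliberately uncorrected for
#' family-wise error.
#'
#' @param data long-format data.frame
#' @param dv name of the dependent-variable column
#' @param within,between,id column names of the time factor, group factor and
#'   subject identifier
#' @param baselineLevel the within level post hocs are compared against
#' @return list with \code{anova} (effect, df1, df2, F, p), \code{posthoc}
#'   (group, comparison, statistic, df, p) and \code{gg_epsilon}
#' @export
rmAnovaMixed <- function(data, dv = "net_turns_per_min", within = "timepoint",
                         between = "group", id = "animal_id",
                         baselineLevel = "baseline") {
    d <- data.frame(y = data[[dv]],
                    time = factor(data[[within]]),
                    grp = factor(data[[between]]),
                    subj = factor(data[[id]]))
    counts <- table(d$subj, d$time)
    if (any(counts != 1L))
        stop("design is incomplete: every subject needs exactly one ",
             "observation per timepoint")
    fit <- stats::aov(y ~ grp * time + Error(subj / time), data = d)
    sm <- summary(fit)
    # sums of squares below numerical noise count as exactly zero
    ss_tol <- 1e-10 * stats::var(d$y) * (nrow(d) - 1) + 1e-20
    pull <- function(stratum, label) {
        tab <- sm[[stratum]][[1]]
        i <- which(trimws(rownames(tab)) == label)[1]
        res <- grep("Residuals", rownames(tab))
        ss <- tab[i, "Sum Sq"]; ssr <- tab[res, "Sum Sq"]
        df1 <- tab[i, "Df"]; df2 <- tab[res, "Df"]
        if (ss <= ss_tol) return(c(df1, df2, 0, 1))   # no effect at all
        Fv <- (ss / df1) / (ssr / df2)
        c(df1, df2, Fv, stats::pf(Fv, df1, df2, lower.tail = FALSE))
    }
    rows <- rbind(GROUP = pull("Error: subj", "grp"),
                  TIME = pull("Error: subj:time", "time"),
                  `GROUP x TIME` = pull("Error: subj:time", "grp:time"))
    anova <- data.frame(effect = rownames(rows), df1 = rows[, 1],
                        df2 = rows[, 2], F = rows[, 3], p = rows[, 4],
                        row.names = NULL)

    wide <- stats::reshape(d[, c("subj", "grp", "time", "y")],
                           idvar = "subj", timevar = "time",
                           direction = "wide")
    ymat <- as.matrix(wide[, grep("^y\\.", names(wide)), drop = FALSE])
    # pool within groups: remove group x time cell means before covariance
    for (g in levels(d$grp)) {
        rowsg <- wide$grp == g
        ymat[rowsg, ] <- scale(ymat[rowsg, , drop = FALSE], scale = FALSE)
    }
    eps <- if (nrow(ymat) > ncol(ymat)) ggEpsilon(ymat) else NA_real_

    lev <- levels(d$time)
    others <- setdiff(lev, baselineLevel)
    ph <- do.call(rbind, lapply(levels(d$grp), function(g) {
        do.call(rbind, lapply(others, function(tp) {
            dg <- d[d$grp == g, ]
            b <- dg$y[dg$time == baselineLevel][order(dg$subj[dg$time == baselineLevel])]
            w <- dg$y[dg$time == tp][order(dg$subj[dg$time == tp])]
            tt <- tryCatch(stats::t.test(w, b, paired = TRUE),
                           error = function(e) NULL)
            data.frame(group = g,
                       comparison = paste(tp, "vs", baselineLevel),
                       statistic = if (is.null(tt)) NA_real_
                                   else unname(tt$statistic),
                       df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
                       p = if (is.null(tt)) NA_real_ else tt$p.value)
        }))
    }))
    list(anova = anova, posthoc = ph, gg_epsilon = eps,
         sphericity_correction_applied = FALSE)
}

#' Ordinary least-squares regression with standardized coefficients
#'
#' OLS with intercept on numeric predictors (encode group factors as
#' documented integers before calling). Reports raw and standardized
#' coefficients (b * sd(x) / sd(y)), per-coefficient t and p, the model F and
#' R-squared. A rank-deficient design is rejected with the collinear columns
#' named; a constant response is flagged degenerate with zero slopes and
#' R-squared 0.
#'
#' @param y numeric response
#' @param predictors data.frame (or matrix) of numeric predictors
#' @return list with coefficients data.frame (term, estimate, std_estimate,
#'   t, p), F, df1, df2, R2, n and flag
#' @export
#' @examples
#' olsFit(2 * (1:10), data.frame(x = 1:10))$R2  # 1
olsFit <- function(y, predictors) {
    X <- as.data.frame(predictors)
    if (!all(vapply(X, is.numeric, logical(1))))
        stop("all predictors must be numeric; encode group factors as ",
             "integers first")
    n <- length(y)
    if (nrow(X) != n) stop("y and predictors disagree in length")
    if (n <= ncol(X) + 1)
        stop("need more observations than predictors plus intercept")
    M <- cbind(`(Intercept)` = 1, as.matrix(X))
    qrM <- qr(M)
    if (qrM$rank < ncol(M)) {
        bad <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
        stop("rank-deficient design; collinear columns: ",
             paste(bad, collapse = ", "))
    }
    dat <- data.frame(y = y, X)
    fit <- stats::lm(y ~ ., data = dat)
    sy <- stats::sd(y)
    sm <- suppressWarnings(summary(fit))
    co <- sm$coefficients
    terms <- rownames(co)
    sdx <- c(NA_real_, vapply(X, stats::sd, numeric(1)))
    std <- ifelse(is.na(sdx) | sy == 0, NA_real_, co[, 1] * sdx / sy)
    degenerate <- sy == 0
    coefs <- data.frame(term = terms, estimate = co[, 1],
                        std_estimate = std, t = co[, 3], p = co[, 4],
                        row.names = NULL)
    fstat <- sm$fstatistic
    list(coefficients = coefs,
         F = if (degenerate || is.null(fstat)) NA_real_
             else unname(fstat[1]),
         df1 = if (is.null(fstat)) NA_real_ else unname(fstat[2]),
         df2 = if (is.null(fstat)) NA_real_ else unname(fstat[3]),
         R2 = if (degenerate) 0 else sm$r.squared,
         n = n, flag = if (degenerate) "degenerate" else "ok")
}

#' Interhemispheric ratio in percent
#'
#' Normalizes a measurement from the stimulated hemisphere to the
#' contralateral one (100 = no interhemispheric difference), as used for
#' striatal BDNF content.
#'
#' @param stimValue value from the stimulated hemisphere
#' @param contraValue value from the contralateral hemisphere (> 0)
#' @return 100 * stim / contra
#' @export
#' @examples
#' interhemisphericRatio(36, 30)  # 120
interhemisphericRatio <- function(stimValue, contraValue) {
    if (any(contraValue <= 0))
        stop("contralateral value must be positive")
    100 * stimValue / contraValue
}
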
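#' @include AllClasses.R
NULL

#' Default phantom configuration
#'
#' Builds the configuration list for \code{\link{generatePhantom}} and merges
#' any overrides into it (nested lists are merged element-wise). Geometry is in
#' micrometres with the convention: x = cutting axis, y = dorsoventral axis
#' (dorsal = smaller y), z = mediolateral axis.
#'
#' Defaults describe a scaled rat-brain coronal scene: two mirror-image
#' striatal ellipsoids, a TH-negative corpus-callosum slab dorsal to them, a
#' graft-core ellipsoid centred in the lesioned (ipsilateral, z < 0) striatum,
#' a DAB-like fiber stain field decaying radially from the core border with
#' decay length \code{lambda} and dorsal bias \code{beta} (dorsal stain is
#' scaled by 1 + beta), a uniformly TH-positive contralateral striatum, and
#' spherical TH-ir cells concentrated at the core border. Stain values are
#' optical densities; rendering converts them to brightfield intensities
#' (darker = more stain).
#'
#' @param ... named overrides, e.g. \code{fiber = list(beta = 1)}
#' @return nested configuration list
#' @export
#' @examples
#' cfg <- phantomConfig(cells = list(n = 100))
#' cfg$cells$n
phantomConfig <- function(...) {
    cfg <- list(
        striatum_ipsi  = list(center = c(0, 0, -620), semi = c(800, 500, 380)),
        striatum_contra = list(center = c(0, 0, 620), semi = c(800, 500, 380)),
        corpus_callosum = list(lo = c(-800, -780, -1300),
                               hi = c( 800, -620,  1300)),
        graft_core = list(center = c(0, 0, -620), semi = c(400, 300, 250)),
        fiber = list(amplitude = 0.6, lambda = 80, beta = 0,
                     stain_threshold = 0.1, contra_od = 0.5, core_od = 1.0,
                     cell_od = 1.4),
        cells = list(n = 500L, diameter = 12, shell = 60, radial_sd = 0.06),
        artifacts = list(n = 2L, radius = 60, od = 1.3),
        render = list(background = 220, noise_sd = 2, bit_depth = 8L),
        truth_grid = 20)
    overrides <- list(...)
    if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
    cfg
}

inEllipsoid <- function(x, y, z, region, dilate = 0) {
    s <- region$semi + dilate
    ((x - region$center[1]) / s[1])^2 + ((y - region$center[2]) / s[2])^2 +
        ((z - region$center[3]) / s[3])^2 <= 1
}

inSlab <- function(x, y, z, region) {
    x >= region$lo[1] & x <= region$hi[1] &
    y >= region$lo[2] & y <= region$hi[2] &
    z >= region$lo[3] & z <= region$hi[3]
}

#' Evaluate the phantom stain field (OD units) at arbitrary points
#'
#' The field is the noiseless, cell-free optical density: uniform
#' \code{core_od} inside the graft core, \code{contra_od} inside the
#' contralateral striatum, zero in the corpus callosum and outside tissue, and
#' in the lesioned striatum outside the core a radially decaying fiber term
#' \code{amplitude * exp(-d / lambda)} where d is the distance from the core
#' border along the normalized ellipsoidal radius (scaled by the mean core
#' semi-axis), multiplied by \code{1 + beta} dorsally of the core centre.
#'
#' @param phantom a \linkS4class{Phantom}
#' @param x,y,z coordinate vectors of equal length (um)
#' @return numeric vector of optical densities
#' @export
stainField <- function(phantom, x, y, z) {
    rg <- phantom@regions
    fb <- phantom@fiber
    od <- numeric(length(x))
    ipsi <- inEllipsoid(x, y, z, rg$striatum_ipsi)
    contra <- inEllipsoid(x, y, z, rg$striatum_contra)
    cc <- inSlab(x, y, z, rg$corpus_callosum)
    core <- inEllipsoid(x, y, z, rg$graft_core)
    od[contra & !cc] <- fb$contra_od
    fibre <- ipsi & !core & !cc
    if (any(fibre)) {
        cs <- rg$graft_core$semi
        cc0 <- rg$graft_core$center
        u <- sqrt(((x[fibre] - cc0[1]) / cs[1])^2 +
                  ((y[fibre] - cc0[2]) / cs[2])^2 +
                  ((z[fibre] - cc0[3]) / cs[3])^2)
        d <- pmax(u - 1, 0) * mean(cs)
        bias <- ifelse(y[fibre] < cc0[2], 1 + fb$beta, 1)
        od[fibre] <- fb$amplitude * exp(-d / fb$lambda) * bias
    }
    od[core] <- fb$core_od
    od
}

boundingBox <- function(regions) {
    lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
    for (r in regions) {
        if (!is.null(r$semi)) {
            lo <- pmin(lo, r$center - r$semi); hi <- pmax(hi, r$center + r$semi)
        } else {
            lo <- pmin(lo, r$lo); hi <- pmax(hi, r$hi)
        }
    }
    list(lo = lo, hi = hi)
}

#' Generate a synthetic grafted-striatum phantom
#'
#' Deterministic for fixed \code{(config, seed)}. Ground truths are computed
#' analytically where a closed form exists (core volume = 4/3 pi abc) and by
#' fine-grid numeric integration otherwise (fiber volume above the configured
#' stain threshold, dorsoventral thresholded-volume and stain-mass ratios,
#' both measured about the core centre with dorsal = smaller y).
#'
#' @param config list from \code{\link{phantomConfig}}
#' @param seed integer seed for cell placement
#' @return a \linkS4class{Phantom}
#' @export
#' @examples
#' ph <- generatePhantom(phantomConfig(cells = list(n = 50)), seed = 1)
#' truths(ph)$core_volume_mm3
generatePhantom <- function(config = phantomConfig(), seed = 1L) {
    set.seed(seed)
    core <- config$graft_core; ipsi <- config$striatum_ipsi
    if (any(abs(core$center - ipsi$center) + core$semi > ipsi$semi))
        stop("inconsistent geometry: graft core is not contained in the ",
             "lesioned striatum")
    if (config$corpus_callosum$lo[2] >= config$corpus_callosum$hi[2])
        stop("inconsistent geometry: corpus callosum slab is empty")

    ncells <- as.integer(config$cells$n)
    if (ncells > 0) {
        shell <- config$cells$shell
        smax <- 1 + shell / max(core$semi)
        # isotropic directions; radial scale ~ N(1, sd) truncated to the
        # shell-dilated core so cells concentrate at the core border
        v <- matrix(stats::rnorm(3 * ncells), ncol = 3)
        v <- v / sqrt(rowSums(v^2))
        s <- stats::rnorm(ncells, 1, config$cells$radial_sd)
        s <- pmin(pmax(s, 0), smax)
        cells <- data.frame(
            x = core$center[1] + s * core$semi[1] * v[, 1],
            y = core$center[2] + s * core$semi[2] * v[, 2],
            z = core$center[3] + s * core$semi[3] * v[, 3],
            diameter = config$cells$diameter)
    } else {
        cells <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                            diameter = numeric())
    }

    ph <- new("Phantom",
              regions = config[c("striatum_ipsi", "striatum_contra",
                                 "corpus_callosum", "graft_core")],
              fiber = config$fiber, cells = cells, truths = list(),
              config = config)

    step <- config$truth_grid
    gx <- seq(ipsi$center[1] - ipsi$semi[1] + step / 2,
              ipsi$center[1] + ipsi$semi[1], by = step)
    gy <- seq(ipsi$center[2] - ipsi$semi[2] + step / 2,
              ipsi$center[2] + ipsi$semi[2], by = step)
    gz <- seq(ipsi$center[3] - ipsi$semi[3] + step / 2,
              ipsi$center[3] + ipsi$semi[3], by = step)
    g <- expand.grid(x = gx, y = gy, z = gz)
    inI <- inEllipsoid(g$x, g$y, g$z, ipsi)
    inC <- inEllipsoid(g$x, g$y, g$z, core)
    f <- stainField(ph, g$x, g$y, g$z)
    fib <- inI & !inC
    pos <- fib & f > config$fiber$stain_threshold
    # grid planes exactly at the core centre are split evenly, matching the
    # downstream centre-row tie-break
    dorsal <- g$y < core$center[2]
    centre <- g$y == core$center[2]
    nd <- sum(pos & dorsal) + 0.5 * sum(pos & centre)
    nv <- sum(pos & !dorsal) - 0.5 * sum(pos & centre)
    md <- sum(f[fib & dorsal]) + 0.5 * sum(f[fib & centre])
    mv <- sum(f[fib & !dorsal]) - 0.5 * sum(f[fib & centre])
    vox <- step^3 / 1e9

    ph@truths <- list(
        core_volume_mm3 = 4 / 3 * pi * prod(core$semi) / 1e9,
        fiber_volume_mm3 = sum(pos) * vox,
        cell_count = ncells,
        dv_ratio = if (nv > 0) nd / nv else NA_real_,
        dv_mass_ratio = if (mv > 0) md / mv else NA_real_,
        stain_threshold = config$fiber$stain_threshold,
        truth_grid_um = step)
    validObject(ph)
    ph
}

#' Count cell profiles produced by slab sectioning of spheres
#'
#' A sphere of diameter D contributes one profile to a slab of thickness T
#' whenever it intersects the slab — the over-counting that the Abercrombie
#' correction (N = n T / (T + D)) undoes.
#'
#' @param cells data.frame with columns \code{x} (centre position along the
#'   cutting axis, um) and \code{diameter} (um)
#' @param geometry a \linkS4class{SectionGeometry}
#' @param xRange numeric length-2: extent sampled along the cutting axis (um)
#' @return integer vector: profile count per section
#' @export
#' @examples
#' g <- sectionGeometry(gap = 0, width = 8L, height = 8L)
#' sectionProfileCounts(data.frame(x = 20, diameter = 12), g, c(0, 120))
sectionProfileCounts <- function(cells, geometry, xRange) {
    h <- spacing(geometry); Tt <- geometry@thickness
    n <- floor(diff(range(xRange)) / h)
    if (n < 1) stop("extent shorter than the section spacing: no sections")
    starts <- min(xRange) + (seq_len(n) - 1) * h
    r <- cells$diameter / 2
    vapply(starts, function(a)
        sum(cells$x + r > a & cells$x - r < a + Tt), integer(1))
}

#' Section a phantom into a serial image stack with ROI masks
#'
#' Cuts slabs of thickness T every h = T + gap um across the phantom extent
#' (one section per slab, \code{floor(extent / h)} sections), rasterising each
#' slab mid-plane at the configured pixel size. Pixel intensity is
#' \code{background * 10^(-OD)} plus Gaussian noise, so darker pixels carry
#' more stain and downstream OD computation recovers the field. ROI masks are
#' rendered from the region geometries (graft core overrides the lesioned
#' striatum label; artifact blobs override both). A cell contributes a
#' circular profile iff its sphere intersects the slab, with the chord radius
#' at the nearest slab face (full radius when the centre lies inside the
#' slab).
#'
#' @param phantom a \linkS4class{Phantom}
#' @param geometry a \linkS4class{SectionGeometry}
#' @param seed integer seed for rendering noise and artifact placement
#' @return a \linkS4class{SectionDataset} with ground truth attached
#' @export
sectionPhantom <- function(phantom, geometry, seed = 1L) {
    set.seed(seed + 1L)
    cfg <- phantom@config
    rnd <- cfg$render
    codes <- roiLabels()
    bb <- boundingBox(phantom@regions)
    h <- spacing(geometry); Tt <- geometry@thickness
    nsec <- floor((bb$hi[1] - bb$lo[1]) / h)
    if (nsec < 1)
        stop("phantom extent (", round(bb$hi[1] - bb$lo[1]),
             " um) is shorter than the section spacing (", h, " um)")
    px <- geometry@pixelSize
    H <- geometry@height; W <- geometry@width
    yv <- (seq_len(H) - (H + 1) / 2) * px
    zv <- (seq_len(W) - (W + 1) / 2) * px
    Y <- matrix(yv, H, W); Z <- matrix(zv, H, W, byrow = TRUE)
    maxval <- 2^rnd$bit_depth - 1

    # artifact blobs: 2D discs on random sections, inside the lesioned
    # striatum but outside the graft core
    nart <- if (is.null(cfg$artifacts)) 0L else as.integer(cfg$artifacts$n)
    art <- NULL
    if (nart > 0) {
        ipsi <- phantom@regions$striatum_ipsi
        art <- data.frame(section = sample.int(nsec, nart, replace = TRUE),
                          y = NA_real_, z = NA_real_)
        for (a in seq_len(nart)) {
            tries <- 0L
            repeat {
                tries <- tries + 1L
                if (tries %% 100L == 0L)  # slab may miss the striatum
                    art$section[a] <- sample.int(nsec, 1L)
                cand <- c(stats::runif(1, -1, 1), stats::runif(1, -1, 1))
                y <- ipsi$center[2] + cand[1] * ipsi$semi[2] * 0.8
                z <- ipsi$center[3] + cand[2] * ipsi$semi[3] * 0.8
                xm <- bb$lo[1] + (art$section[a] - 1) * h + Tt / 2
                if (inEllipsoid(xm, y, z, ipsi) &&
                    !inEllipsoid(xm, y, z, phantom@regions$graft_core,
                                 dilate = cfg$artifacts$radius)) {
                    art$y[a] <- y; art$z[a] <- z
                    break
                }
            }
        }
    }

    images <- vector("list", nsec)
    labels <- vector("list", nsec)
    profile_counts <- integer(nsec)
    rg <- phantom@regions
    for (k in seq_len(nsec)) {
        xa <- bb$lo[1] + (k - 1) * h
        xm <- xa + Tt / 2
        X <- matrix(xm, H, W)
        lab <- matrix(0L, H, W)
        lab[inEllipsoid(X, Y, Z, rg$striatum_contra)] <-
            codes[["striatum_contra"]]
        lab[inEllipsoid(X, Y, Z, rg$striatum_ipsi)] <- codes[["striatum_ipsi"]]
        lab[inSlab(X, Y, Z, rg$corpus_callosum)] <- codes[["corpus_callosum"]]
        lab[inEllipsoid(X, Y, Z, rg$graft_core)] <- codes[["graft_core"]]

        od <- matrix(stainField(phantom, as.vector(X), as.vector(Y),
                                as.vector(Z)), H, W)

        if (nrow(phantom@cells)) {
            r <- phantom@cells$diameter / 2
            hit <- phantom@cells$x + r > xa & phantom@cells$x - r < xa + Tt
            profile_counts[k] <- sum(hit)
            for (ci in which(hit)) {
                dx <- phantom@cells$x[ci] - pmin(pmax(phantom@cells$x[ci], xa),
                                                 xa + Tt)
                rp <- sqrt(r[ci]^2 - dx^2)
                disc <- (Y - phantom@cells$y[ci])^2 +
                        (Z - phantom@cells$z[ci])^2 <= rp^2
                od[disc] <- phantom@fiber$cell_od
            }
        }

        if (!is.null(art)) for (a in which(art$section == k)) {
            disc <- (Y - art$y[a])^2 + (Z - art$z[a])^2 <= cfg$artifacts$radius^2
            od[disc] <- cfg$artifacts$od
            lab[disc] <- codes[["artifact"]]
        }

        img <- rnd$background * 10^(-od)
        if (rnd$noise_sd > 0)
            img <- img + stats::rnorm(length(img), 0, rnd$noise_sd)
        images[[k]] <- matrix(round(pmin(pmax(img, 0), maxval)), H, W)
        labels[[k]] <- lab
    }

    truth <- phantom@truths
    truth$profile_counts <- profile_counts
    truth$n_sections <- nsec
    truth$x_start <- bb$lo[1]
    new("SectionDataset", images = images, labels = labels,
        geometry = geometry, bitDepth = as.integer(rnd$bit_depth),
        truth = truth)
}
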
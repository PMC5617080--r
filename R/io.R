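#' Save a section dataset to a TIFF + JSON directory layout
#'
#' Writes one grayscale TIFF per section (\code{section_NNN.tif}), one integer
#' label-mask TIFF per section (\code{mask_NNN.tif}), a JSON metadata sidecar
#' (\code{metadata.json}: geometry, bit depth, label codes, units) and, when
#' ground truth is attached, \code{truth.json}. Pixel data round-trip
#' bit-exactly.
#'
#' @param dataset a \linkS4class{SectionDataset}
#' @param path directory to create
#' @param overwrite allow writing into an existing non-empty directory
#' @return \code{path}, invisibly
#' @export
saveDataset <- function(dataset, path, overwrite = FALSE) {
    validObject(dataset)
    if (nSections(dataset) < 1) stop("refusing to save an empty dataset")
    if (dir.exists(path) && length(list.files(path)) && !overwrite)
        stop("'", path, "' exists and is not empty; use overwrite = TRUE")
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (file.access(path, mode = 2) != 0) stop("'", path, "' is not writable")
    maxval <- 2^dataset@bitDepth - 1
    g <- geometry(dataset)
    for (i in seq_len(nSections(dataset))) {
        tiff::writeTIFF(sectionImage(dataset, i) / maxval,
                        file.path(path, sprintf("section_%03d.tif", i)),
                        bits.per.sample = dataset@bitDepth)
        tiff::writeTIFF(labelImage(dataset, i) / 255,
                        file.path(path, sprintf("mask_%03d.tif", i)),
                        bits.per.sample = 8L)
    }
    meta <- list(
        n_sections = nSections(dataset),
        bit_depth = dataset@bitDepth,
        geometry = list(thickness_um = g@thickness, gap_um = g@gap,
                        spacing_um = spacing(g), pixel_size_um = g@pixelSize,
                        width_px = g@width, height_px = g@height),
        labels = as.list(roiLabels()),
        units = list(length = "um", area = "um2", volume = "mm3"))
    jsonlite::write_json(meta, file.path(path, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
    if (length(dataset@truth))
        jsonlite::write_json(dataset@truth, file.path(path, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Load a section dataset written by \code{\link{saveDataset}}
#'
#' Sections are ordered by filename index; geometry comes from the sidecar.
#' Missing files, image/mask shape mismatches and unknown mask labels raise
#' descriptive errors.
#'
#' @param path dataset directory
#' @return a \linkS4class{SectionDataset}
#' @export
loadDataset <- function(path) {
    metafile <- file.path(path, "metadata.json")
    if (!file.exists(metafile))
        stop("missing metadata sidecar: ", metafile)
    meta <- jsonlite::read_json(metafile, simplifyVector = TRUE)
    g <- sectionGeometry(thickness = meta$geometry$thickness_um,
                         gap = meta$geometry$gap_um,
                         pixelSize = meta$geometry$pixel_size_um,
                         width = meta$geometry$width_px,
                         height = meta$geometry$height_px)
    maxval <- 2^meta$bit_depth - 1
    n <- meta$n_sections
    images <- vector("list", n); labels <- vector("list", n)
    for (i in seq_len(n)) {
        sf <- file.path(path, sprintf("section_%03d.tif", i))
        mf <- file.path(path, sprintf("mask_%03d.tif", i))
        if (!file.exists(sf)) stop("missing image for section ", i, ": ", sf)
        if (!file.exists(mf)) stop("missing mask for section ", i, ": ", mf)
        img <- round(tiff::readTIFF(sf) * maxval)
        mskraw <- tiff::readTIFF(mf)
        if (!identical(dim(img), dim(mskraw)))
            stop("section ", i, ": image and mask shapes differ")
        msk <- matrix(as.integer(round(mskraw * 255)), nrow = nrow(mskraw))
        bad <- setdiff(unique(as.integer(msk)), c(0L, unname(roiLabels())))
        if (length(bad))
            stop("section ", i, ": unknown mask label(s) ",
                 paste(bad, collapse = ", "))
        images[[i]] <- img; labels[[i]] <- msk
    }
    truth <- list()
    tf <- file.path(path, "truth.json")
    if (file.exists(tf))
        truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    new("SectionDataset", images = images, labels = labels, geometry = g,
        bitDepth = as.integer(meta$bit_depth), truth = as.list(truth))
}

#' Write / read a rotometry table as CSV
#'
#' Columns: animal_id, group, timepoint, net_turns_per_min.
#'
#' @param rotation data.frame from \code{\link{generateRotationData}}
#' @param path CSV file path
#' @return \code{writeRotationCSV}: the path, invisibly;
#'   \code{readRotationCSV}: the data.frame
#' @export
writeRotationCSV <- function(rotation, path) {
    utils::write.csv(rotation, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeRotationCSV
#' @export
readRotationCSV <- function(path) {
    need <- c("animal_id", "group", "timepoint", "net_turns_per_min")
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(need %in% names(d)))
        stop("rotation CSV must have columns: ", paste(need, collapse = ", "))
    d
}
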
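#' @include AllClasses.R
NULL

#' Centre-to-centre spacing between consecutive sections
#'
#' @param object a \linkS4class{SectionGeometry}
#' @return spacing h = thickness + gap, in um
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' Number of sections in a dataset
#' @param object a \linkS4class{SectionDataset}
#' @return integer section count
#' @export
setGeneric("nSections", function(object) standardGeneric("nSections"))

#' Acquisition geometry of a dataset
#' @param object a \linkS4class{SectionDataset}
#' @return the \linkS4class{SectionGeometry}
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' Raw intensity image of one section
#' @param object a \linkS4class{SectionDataset}
#' @param i section index
#' @return numeric matrix
#' @export
setGeneric("sectionImage", function(object, i) standardGeneric("sectionImage"))

#' Integer label mask of one section
#' @param object a \linkS4class{SectionDataset}
#' @param i section index
#' @return integer matrix of \code{\link{roiLabels}} codes
#' @export
setGeneric("labelImage", function(object, i) standardGeneric("labelImage"))

#' Binary ROI mask of one section
#'
#' Resolves region containment: the lesioned striatum
#' (\code{"striatum_ipsi"}) includes graft-core pixels, since the core sits
#' inside it; all other names map to their own label only.
#'
#' @param object a \linkS4class{SectionDataset}
#' @param name one of \code{names(roiLabels())}
#' @param i section index
#' @return logical matrix
#' @export
setGeneric("roiMask", function(object, name, i) standardGeneric("roiMask"))

#' Ground-truth record of a dataset or phantom
#' @param object a \linkS4class{SectionDataset} or \linkS4class{Phantom}
#' @return named list of ground-truth quantities (may be empty)
#' @export
setGeneric("truths", function(object) standardGeneric("truths"))
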
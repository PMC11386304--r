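#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("genoQual", function(x) standardGeneric("genoQual"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("scaffolds", function(x) standardGeneric("scaffolds"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("siteQual", function(x) standardGeneric("siteQual"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("isMonomorphic", function(x) standardGeneric("isMonomorphic"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("isMultiallelic", function(x) standardGeneric("isMultiallelic"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname FoldedSFS-accessors
#' @export
setGeneric("sfsBins", function(x) standardGeneric("sfsBins"))
#' @rdname FoldedSFS-accessors
#' @export
setGeneric("sfsHaploidSize", function(x) standardGeneric("sfsHaploidSize"))
#' @rdname FoldedSFS-accessors
#' @export
setGeneric("sfsL", function(x) standardGeneric("sfsL"))

#' @rdname simulatePedigree
#' @export
setGeneric("truthTracts", function(x, ...) standardGeneric("truthTracts"))
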
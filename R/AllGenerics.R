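#' Accessor generics
#'
#' Small family of accessors for the package's S4 containers; use these
#' instead of reaching into slots.
#'
#' @param x an object.
#' @param ... passed on to methods.
#' @return The corresponding slot content (see methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("tfIds", function(x, ...) standardGeneric("tfIds"))

#' @rdname accessors
#' @export
setGeneric("targetIds", function(x, ...) standardGeneric("targetIds"))

#' @rdname accessors
#' @export
setGeneric("plantedMrs", function(x, ...) standardGeneric("plantedMrs"))

#' @rdname accessors
#' @export
setGeneric("tfCommunities", function(x, ...) standardGeneric("tfCommunities"))

#' @rdname accessors
#' @export
setGeneric("cohortName", function(x, ...) standardGeneric("cohortName"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x, ...) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("shrinkageLambda", function(x, ...) standardGeneric("shrinkageLambda"))

#' @rdname accessors
#' @export
setGeneric("nullScale", function(x, ...) standardGeneric("nullScale"))

#' @rdname accessors
#' @export
setGeneric("cohortSizes", function(x, ...) standardGeneric("cohortSizes"))

#' @rdname accessors
#' @export
setGeneric("regulonTable", function(x, ...) standardGeneric("regulonTable"))

#' @rdname accessors
#' @export
setGeneric("regulonSizes", function(x, ...) standardGeneric("regulonSizes"))

#' @rdname accessors
#' @param tf a single TF identifier.
#' @export
setGeneric("regulonOf", function(x, tf, ...) standardGeneric("regulonOf"))

#' @rdname accessors
#' @export
setGeneric("cohorts", function(x, ...) standardGeneric("cohorts"))

#' @rdname accessors
#' @export
setGeneric("perturbation", function(x, ...) standardGeneric("perturbation"))

#' @rdname accessors
#' @export
setGeneric("clinicalTable", function(x, ...) standardGeneric("clinicalTable"))

#' @rdname accessors
#' @export
setGeneric("mutationTable", function(x, ...) standardGeneric("mutationTable"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x, ...) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setGeneric("studyGeneSets", function(x, ...) standardGeneric("studyGeneSets"))

#' @rdname accessors
#' @export
setGeneric("studyNetwork", function(x, ...) standardGeneric("studyNetwork"))
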
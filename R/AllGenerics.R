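#' @include AllClasses.R
NULL

#' Accessors for quinsar classes
#'
#' Small-surface accessors: prefer these over direct slot access.
#'
#' @param object a quinsar S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("moleculeId", function(object) standardGeneric("moleculeId"))

#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("bonds", function(object) standardGeneric("bonds"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("netCharge", function(object) standardGeneric("netCharge"))

#' @rdname accessors
#' @export
setGeneric("isPrepared", function(object) standardGeneric("isPrepared"))

#' @rdname accessors
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("coreRmsd", function(object) standardGeneric("coreRmsd"))

#' @rdname accessors
#' @export
setGeneric("gridPoints", function(object) standardGeneric("gridPoints"))

#' @rdname accessors
#' @export
setGeneric("fieldBlock", function(object, kind) standardGeneric("fieldBlock"))

#' @rdname accessors
#' @export
setGeneric("keptMask", function(object) standardGeneric("keptMask"))

#' @rdname accessors
#' @export
setGeneric("blockScaling", function(object) standardGeneric("blockScaling"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("modelCoefficients",
           function(object, scale = c("model", "raw"))
             standardGeneric("modelCoefficients"))

#' @rdname accessors
#' @export
setGeneric("modelStatsOf", function(object) standardGeneric("modelStatsOf"))

#' @rdname accessors
#' @export
setGeneric("fieldContributionsOf",
           function(object) standardGeneric("fieldContributionsOf"))

#' @rdname accessors
#' @export
setGeneric("chosenComponents",
           function(object) standardGeneric("chosenComponents"))

#' @rdname accessors
#' @export
setGeneric("q2Scan", function(object) standardGeneric("q2Scan"))

#' @rdname accessors
#' @export
setGeneric("r2Pred", function(object) standardGeneric("r2Pred"))

#' @rdname accessors
#' @export
setGeneric("validationTable",
           function(object) standardGeneric("validationTable"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
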
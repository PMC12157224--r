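#' @include AllClasses.R
NULL

#' @rdname molecularFormula
#' @export
setGeneric("molecularFormula", function(mol) standardGeneric("molecularFormula"))

#' @rdname molecularWeight
#' @export
setGeneric("molecularWeight", function(mol) standardGeneric("molecularWeight"))

#' @rdname atomCounts
#' @export
setGeneric("atomCounts", function(mol) standardGeneric("atomCounts"))

#' @rdname perceiveRings
#' @export
setGeneric("perceiveRings", function(mol) standardGeneric("perceiveRings"))

#' @rdname detectFunctionalGroups
#' @export
setGeneric("detectFunctionalGroups",
           function(mol) standardGeneric("detectFunctionalGroups"))

#' @rdname structuralCensus
#' @export
setGeneric("structuralCensus", function(mol) standardGeneric("structuralCensus"))

#' @rdname tpsa
#' @export
setGeneric("tpsa", function(mol, ...) standardGeneric("tpsa"))

#' @rdname countHBD
#' @export
setGeneric("countHBD", function(mol) standardGeneric("countHBD"))

#' @rdname countHBA
#' @export
setGeneric("countHBA", function(mol) standardGeneric("countHBA"))

#' @rdname crippenLogP
#' @export
setGeneric("crippenLogP", function(mol) standardGeneric("crippenLogP"))

#' @rdname atomPairSet
#' @export
setGeneric("atomPairSet", function(mol) standardGeneric("atomPairSet"))

#' @rdname ocCoef
#' @export
setGeneric("ocCoef", function(r) standardGeneric("ocCoef"))

#' @rdname tcCoef
#' @export
setGeneric("tcCoef", function(r) standardGeneric("tcCoef"))
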
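#' @rdname SNPMarkerCatalog-class
#' @param x,object a \code{SNPMarkerCatalog}
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname SNPMarkerCatalog-class
#' @export
setGeneric("populationLabel", function(x) standardGeneric("populationLabel"))

#' @rdname LogisticRiskModel-class
#' @param x,object a \code{LogisticRiskModel}
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))

#' @rdname LogisticRiskModel-class
#' @export
setGeneric("intercepts", function(x) standardGeneric("intercepts"))

#' @rdname LogisticRiskModel-class
#' @export
setGeneric("baselines", function(x) standardGeneric("baselines"))

#' @rdname LogisticRiskModel-class
#' @export
setGeneric("contributionSum", function(x) standardGeneric("contributionSum"))

#' @rdname GenotypeProfiles-class
#' @param x,object a \code{GenotypeProfiles} or \code{EncodedProfiles}
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname GenotypeProfiles-class
#' @export
setGeneric("stratum", function(x) standardGeneric("stratum"))

#' @rdname GenotypeProfiles-class
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname EncodedProfiles-class
#' @export
setGeneric("encodedX", function(x) standardGeneric("encodedX"))

#' @rdname EncodedProfiles-class
#' @export
setGeneric("nMissing", function(x) standardGeneric("nMissing"))
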
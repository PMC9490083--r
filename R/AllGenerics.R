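#' @rdname PKDataset-class
#' @param object,x a `PKDataset`
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))

#' @rdname PKDataset-class
#' @export
setGeneric("nObservations", function(object) standardGeneric("nObservations"))

#' @rdname PKDataset-class
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' Per-subject covariate table
#'
#' One row per subject with columns ID, CW, BW, GA, PNA, PMA (taken from the
#' subject's first event record; covariates are treated as constant within a
#' subject over the short treatment window).
#'
#' @param object a [PKDataset-class]
#' @return data.frame, one row per subject
#' @export
setGeneric("covariateTable", function(object) standardGeneric("covariateTable"))

#' Extract population parameters from a fit
#'
#' @param object a [FitResult-class]
#' @return a [PopulationParams-class]
#' @export
setGeneric("popParams", function(object) standardGeneric("popParams"))

#' Objective function value of a fit
#' @param object a [FitResult-class]
#' @export
setGeneric("ofv", function(object) standardGeneric("ofv"))

#' Empirical Bayes estimates of a fit
#' @param object a [FitResult-class]
#' @return matrix (subjects x 2) of eta estimates
#' @export
setGeneric("ebes", function(object) standardGeneric("ebes"))

#' Convergence flag of a fit
#' @param object a [FitResult-class]
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
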
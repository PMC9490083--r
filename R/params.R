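#' Create a population parameter set
#'
#' @param theta1 typical volume of distribution, L
#' @param theta2 typical clearance at current weight 2310 g and postnatal age
#'   1 day, L/h
#' @param theta3 allometric current-weight exponent on clearance
#' @param theta4 postnatal-age maturation exponent on clearance
#' @param omega2Cl,omega2V inter-individual variances on the log scale
#' @param sigma2Prop proportional residual variance
#' @return a [PopulationParams-class]
#' @export
populationParams <- function(theta1, theta2, theta3 = 0, theta4 = 0,
                             omega2Cl = 0, omega2V = 0, sigma2Prop = 0) {
  new("PopulationParams", theta1 = theta1, theta2 = theta2, theta3 = theta3,
      theta4 = theta4, omega2Cl = omega2Cl, omega2V = omega2V,
      sigma2Prop = sigma2Prop)
}

#' Reference cefotaxime parameter set for neonates with early-onset sepsis
#'
#' The final population estimates of the neonatal cefotaxime model shipped as
#' a named preset: V = 0.873 L; CL = 0.0803 * (CW/2310)^1.68 * (PNA/1)^0.444
#' L/h; inter-individual variability 20.0\% (CL) and 21.1\% (V) as percent
#' coefficients of variation, i.e. omega2 = (CV/100)^2; proportional residual
#' error 14.2\%. The covariate reference points (2310 g, 1 day) are the study
#' medians and are fixed, not recomputed from loaded data, so the preset is
#' portable across datasets.
#'
#' @return a [PopulationParams-class]
#' @examples
#' p <- cefotaximeParams()
#' individualClearance(p, list(CW = 2310, PNA = 1)) # 0.0803 L/h
#' @export
cefotaximeParams <- function() {
  populationParams(theta1 = 0.873, theta2 = 0.0803, theta3 = 1.68,
                   theta4 = 0.444, omega2Cl = 0.200^2, omega2V = 0.211^2,
                   sigma2Prop = 0.142^2)
}

#' @rdname PopulationParams-class
#' @param object a `PopulationParams`
#' @export
setMethod("show", "PopulationParams", function(object) {
  cat("PopulationParams (one-compartment IV infusion)\n")
  cat(sprintf("  V  = %.4g L\n", object@theta1))
  cat(sprintf("  CL = %.4g * (CW/2310)^%.3g * (PNA/1)^%.3g L/h\n",
              object@theta2, object@theta3, object@theta4))
  cat(sprintf("  IIV CL %.1f%%, IIV V %.1f%%, prop. residual %.1f%%\n",
              100 * sqrt(object@omega2Cl), 100 * sqrt(object@omega2V),
              100 * sqrt(object@sigma2Prop)))
})

#' @describeIn populationParams coerce to a named numeric vector
#' @param p a [PopulationParams-class]
#' @export
paramsToVector <- function(p) {
  c(theta1 = p@theta1, theta2 = p@theta2, theta3 = p@theta3,
    theta4 = p@theta4, omega2Cl = p@omega2Cl, omega2V = p@omega2V,
    sigma2Prop = p@sigma2Prop)
}

#' Read population parameters from YAML
#'
#' The file holds the named parameter fields (theta1..theta4, omega2Cl,
#' omega2V, sigma2Prop); units are L, L/h and variances on the log or
#' proportional scale as documented in [PopulationParams-class].
#'
#' @param path YAML file path
#' @return a [PopulationParams-class]
#' @export
readParams <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(populationParams,
          y[intersect(names(y), names(formals(populationParams)))])
}

#' Write population parameters to YAML
#' @param p a [PopulationParams-class]
#' @param path output path
#' @export
writeParams <- function(p, path) {
  v <- as.list(paramsToVector(p))
  v$units <- list(theta1 = "L", theta2 = "L/h",
                  omega = "variance of log-scale eta",
                  sigma2Prop = "proportional variance")
  yaml::write_yaml(v, path)
  invisible(path)
}
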
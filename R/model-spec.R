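#' Build a structural model specification
#'
#' A model is the one-compartment base (typical volume theta1, typical
#' clearance theta2) plus multiplicative power-function covariate terms
#' `(cov/ref)^exponent` on clearance and/or volume. Exponents are either
#' estimated (with a starting value) or fixed, e.g. at 0.75 for fixed
#' allometric scaling.
#'
#' @param clTerms,vTerms data.frames built by row-binding
#'   [covariateTerm()] results (or NULL for none)
#' @return a [PKModelSpec-class]
#' @examples
#' pkModel(clTerms = rbind(covariateTerm("CW", 2310),
#'                         covariateTerm("PNA", 1, init = 0.5)))
#' @export
pkModel <- function(clTerms = NULL, vTerms = NULL) {
  empty <- data.frame(cov = character(), ref = numeric(),
                      exponent = numeric(), estimated = logical(),
                      stringsAsFactors = FALSE)
  new("PKModelSpec", clTerms = clTerms %||% empty, vTerms = vTerms %||% empty)
}

#' @describeIn pkModel one covariate term; `exponent = NA` (default) means
#'   the exponent is estimated starting from `init`, a number fixes it.
#' @param cov covariate name, one of CW, BW, GA, PNA, PMA
#' @param ref normalization constant (study median of the covariate)
#' @param exponent fixed exponent value, or NA to estimate
#' @param init starting value for an estimated exponent
#' @export
covariateTerm <- function(cov, ref, exponent = NA, init = 1) {
  data.frame(cov = cov, ref = ref,
             exponent = if (is.na(exponent)) init else exponent,
             estimated = is.na(exponent), stringsAsFactors = FALSE)
}

#' @describeIn pkModel covariate-free base model
#' @export
baseModel <- function() pkModel()

#' @describeIn pkModel the final neonatal cefotaxime model: estimated
#'   allometric current-weight exponent (reference 2310 g) and estimated
#'   postnatal-age maturation exponent (reference 1 day) on clearance, no
#'   covariates on volume.
#' @export
finalCefotaximeModel <- function() {
  pkModel(clTerms = rbind(covariateTerm("CW", 2310, init = 1),
                          covariateTerm("PNA", 1, init = 0.5)))
}

#' @rdname PKModelSpec-class
#' @param object a `PKModelSpec`
#' @export
setMethod("show", "PKModelSpec", function(object) {
  fmt <- function(tm) {
    if (nrow(tm) == 0) return("1")
    paste(sprintf("(%s/%g)^%s", tm$cov, tm$ref,
                  ifelse(tm$estimated, "est", format(tm$exponent))),
          collapse = " * ")
  }
  cat("PKModelSpec\n")
  cat("  CL = theta2 *", fmt(object@clTerms), "\n")
  cat("  V  = theta1 *", fmt(object@vTerms), "\n")
})

# add/remove one covariate term; target is "CL" or "V"
.addTerm <- function(model, cov, target, ref, exponent = NA, init = 1) {
  tm <- covariateTerm(cov, ref, exponent, init)
  if (target == "CL") model@clTerms <- rbind(model@clTerms, tm)
  else model@vTerms <- rbind(model@vTerms, tm)
  validObject(model)
  model
}

.dropTerm <- function(model, cov, target) {
  if (target == "CL")
    model@clTerms <- model@clTerms[model@clTerms$cov != cov, , drop = FALSE]
  else
    model@vTerms <- model@vTerms[model@vTerms$cov != cov, , drop = FALSE]
  model
}

.modelTerms <- function(model) {
  rbind(
    if (nrow(model@clTerms) > 0) cbind(model@clTerms, target = "CL"),
    if (nrow(model@vTerms) > 0) cbind(model@vTerms, target = "V"))
}

# names of the estimated quantities, in optimizer order:
# theta1, theta2, estimated exponents (CL terms then V terms), variances
.parNames <- function(model) {
  nm <- c("theta1", "theta2")
  ct <- model@clTerms
  if (nrow(ct) > 0)
    nm <- c(nm, paste0("beta.CL.", ct$cov[ct$estimated]))
  vt <- model@vTerms
  if (nrow(vt) > 0)
    nm <- c(nm, paste0("beta.V.", vt$cov[vt$estimated]))
  c(nm, "omega2Cl", "omega2V", "sigma2Prop")
}

# transform a natural-scale named estimate vector to the unconstrained
# optimizer scale (logs for positives, identity for exponents) and back
.toOpt <- function(est, model) {
  nm <- .parNames(model)
  x <- est[nm]
  pos <- c("theta1", "theta2", "omega2Cl", "omega2V", "sigma2Prop")
  x[pos] <- log(pmax(est[pos], 1e-12))
  x
}

.fromOpt <- function(x, model) {
  nm <- .parNames(model)
  est <- setNames(as.numeric(x), nm)
  pos <- c("theta1", "theta2", "omega2Cl", "omega2V", "sigma2Prop")
  est[pos] <- exp(est[pos])
  est
}

# per-subject typical CL and V given natural-scale estimates
.typicalValues <- function(model, est, covTable) {
  applyTerms <- function(base, terms, betaPrefix) {
    v <- rep(base, nrow(covTable))
    if (nrow(terms) == 0) return(v)
    for (k in seq_len(nrow(terms))) {
      expo <- if (terms$estimated[k])
        est[[paste0(betaPrefix, terms$cov[k])]] else terms$exponent[k]
      v <- v * (covTable[[terms$cov[k]]] / terms$ref[k])^expo
    }
    v
  }
  list(tvcl = applyTerms(est[["theta2"]], model@clTerms, "beta.CL."),
       tvv = applyTerms(est[["theta1"]], model@vTerms, "beta.V."))
}

# default natural-scale starting estimates: naive-pooled (eta = 0) least
# squares on log concentration for the fixed effects, 30% IIV and 20%
# proportional error for the random effects
.defaultStart <- function(data, model) {
  sl <- .subjectList(data)
  nm <- .parNames(model)
  fixedNm <- setdiff(nm, c("omega2Cl", "omega2V", "sigma2Prop"))
  init <- setNames(numeric(length(fixedNm)), fixedNm)
  init["theta1"] <- 0.5
  init["theta2"] <- 0.05
  ct <- model@clTerms
  if (nrow(ct) > 0)
    init[paste0("beta.CL.", ct$cov[ct$estimated])] <- ct$exponent[ct$estimated]
  vt <- model@vTerms
  if (nrow(vt) > 0)
    init[paste0("beta.V.", vt$cov[vt$estimated])] <- vt$exponent[vt$estimated]
  x0 <- init
  x0[c("theta1", "theta2")] <- log(x0[c("theta1", "theta2")])
  obj <- function(x) {
    est <- setNames(as.numeric(x), fixedNm)
    est[c("theta1", "theta2")] <- exp(est[c("theta1", "theta2")])
    tv <- .typicalValues(model, as.list(est), sl$cov)
    s <- 0
    for (i in seq_along(sl$subjects)) {
      si <- sl$subjects[[i]]
      if (length(si$y) == 0) next
      f <- .concProfileCpp(si$t, tv$tvcl[i], tv$tvv[i],
                           si$doseT, si$rate, si$dur)
      s <- s + sum((log(si$y) - log(pmax(f, 1e-12)))^2)
    }
    s
  }
  o <- nlminb(x0, obj, control = list(iter.max = 200, eval.max = 600))
  est <- setNames(as.numeric(o$par), fixedNm)
  est[c("theta1", "theta2")] <- exp(est[c("theta1", "theta2")])
  c(est, omega2Cl = 0.09, omega2V = 0.09, sigma2Prop = 0.04)
}
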
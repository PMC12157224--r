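## Environmental-risk decision rules on LogP and TPSA, and the joint flag.
## Boundary assignment (values exactly at 1, 3, 5, 60, 75, 83, 140) follows
## the closed/half-open intervals documented below; the rules themselves
## follow the screening conventions for bioaccumulation (LogP) and membrane
## permeability (TPSA).
##
##   LogP  class:  > 5 high_bioaccumulation | (3, 5] borderline |
##                 [1, 3] mild | < 1 low_lipophilicity
##   TPSA  class:  > 140 reduced_systemic | (75, 140] higher_safety |
##                 [60, 75] borderline | < 60 concern
##   joint flag :  hazard      iff LogP > 5 and TPSA < 75
##                 investigate iff (LogP > 5 and 75 <= TPSA <= 83) or
##                                 (3 < LogP <= 5 and TPSA < 60)
##                 low_risk    otherwise

#' LogP bioaccumulation class
#'
#' @param logp finite numeric LogP value(s).
#' @return character vector over \{high_bioaccumulation, borderline, mild,
#'   low_lipophilicity\}.
#' @export
classifyLogP <- function(logp) {
  if (any(!is.finite(logp))) stop("LogP must be finite")
  ifelse(logp > 5, "high_bioaccumulation",
         ifelse(logp > 3, "borderline",
                ifelse(logp >= 1, "mild", "low_lipophilicity")))
}

#' TPSA permeability/safety class
#'
#' @param tpsa nonnegative TPSA value(s) in square Angstrom.
#' @return character vector over \{reduced_systemic, higher_safety,
#'   borderline, concern\}.
#' @export
classifyTPSA <- function(tpsa) {
  if (any(!is.finite(tpsa) | tpsa < 0)) stop("TPSA must be finite and >= 0")
  ifelse(tpsa > 140, "reduced_systemic",
         ifelse(tpsa > 75, "higher_safety",
                ifelse(tpsa >= 60, "borderline", "concern")))
}

#' Joint environmental-hazard flag
#'
#' Lipophilic and membrane-permeable molecules (LogP > 5, TPSA < 75) are
#' flagged \code{hazard}; the two screening bands around that rule (high
#' LogP with TPSA 75-83, or borderline LogP with TPSA < 60) are flagged
#' \code{investigate}; everything else is \code{low_risk} (including very
#' polar molecules with TPSA > 140, whose high LogP is offset by their
#' reduced systemic availability).
#'
#' @param logp,tpsa finite numeric vectors (recycled to common length).
#' @return character vector over \{hazard, investigate, low_risk\}.
#' @export
jointFlag <- function(logp, tpsa) {
  if (any(!is.finite(logp)) || any(!is.finite(tpsa)))
    stop("LogP and TPSA must be finite")
  ifelse(logp > 5 & tpsa < 75, "hazard",
         ifelse((logp > 5 & tpsa >= 75 & tpsa <= 83) |
                  (logp > 3 & logp <= 5 & tpsa < 60),
                "investigate", "low_risk"))
}

#' Risk assessment table
#'
#' Applies the LogP class, TPSA class and joint flag to a descriptor table.
#'
#' @param descriptors data.frame with columns \code{cid}, \code{logp},
#'   \code{tpsa} (e.g. from [descriptorTable()] or
#'   [referenceDescriptors()]).
#' @return the input with \code{logp_class}, \code{tpsa_class} and
#'   \code{joint_flag} columns appended.
#' @export
riskTable <- function(descriptors) {
  stopifnot(all(c("cid", "logp", "tpsa") %in% names(descriptors)))
  out <- descriptors
  out$logp_class <- classifyLogP(descriptors$logp)
  out$tpsa_class <- classifyTPSA(descriptors$tpsa)
  out$joint_flag <- jointFlag(descriptors$logp, descriptors$tpsa)
  out
}
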
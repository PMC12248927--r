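# Live-to-carcass conversion at feedlot entry and the carcass-basis
# production ratios. Beef in South Africa trades on a carcass basis, so the
# model converts the live entry weight to an equivalent entry carcass weight
# with a fixed linear dressing relationship.

#' Linear live-to-carcass conversion coefficients
#'
#' Carcass weight at feedlot entry is predicted from shrunk body weight (SBW)
#' as `slope * SBW + intercept`. The default coefficients (0.694, -38.43 kg)
#' are the published relationship for South African feeder calves.
#'
#' @param slope Dimensionless slope (> 0).
#' @param intercept Intercept in kg.
#' @return A list of class `carcass_conversion`.
#' @export
carcass_conversion <- function(slope = 0.694, intercept = -38.43) {
  if (!is.numeric(slope) || slope <= 0)
    abort("slope must be a positive number", class = "fl_domain_error")
  structure(list(slope = slope, intercept = intercept),
            class = "carcass_conversion")
}

#' Carcass weight at feedlot entry
#'
#' Applies the linear conversion to a shrunk body weight. Inputs at or below
#' the root of the linear form (where the predicted carcass weight would be
#' zero or negative, 55.375 kg under the defaults) are rejected.
#'
#' @param sbw Shrunk body weight at entry, kg (vectorised).
#' @param conv A [carcass_conversion()].
#' @return Predicted entry carcass weight, kg.
#' @examples
#' entry_carcass_weight(199.2)
#' @export
entry_carcass_weight <- function(sbw, conv = carcass_conversion()) {
  root <- -conv$intercept / conv$slope
  if (any(sbw <= root))
    abort(sprintf("sbw must exceed %.3f kg for a positive carcass weight", root),
          class = "fl_domain_error")
  conv$slope * sbw + conv$intercept
}

#' Carcass average daily gain
#'
#' @param gain Carcass gain over the feeding period, kg.
#' @param dof Days on feed (> 0).
#' @return Gain per day, kg/d.
#' @export
carcass_adg <- function(gain, dof) {
  if (any(dof <= 0)) abort("dof must be positive", class = "fl_domain_error")
  gain / dof
}

#' Carcass feed conversion ratio
#'
#' Feed consumed per kg of carcass gained. A non-positive gain makes the
#' ratio undefined (an animal that gained nothing has no finite feed
#' conversion) and is an error, not an `Inf`.
#'
#' @param total_intake Total feed consumed, kg.
#' @param gain Carcass gain, kg (> 0).
#' @return kg feed per kg carcass gain.
#' @export
carcass_fcr <- function(total_intake, gain) {
  if (any(gain <= 0))
    abort("carcass gain must be positive for a defined feed conversion ratio",
          class = "fl_domain_error")
  total_intake / gain
}
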
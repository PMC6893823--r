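# Linear QSPR models for the predicted members of the descriptor panel.
# Each model is a pure function of its declared inputs with coefficients
# pinned in a YAML config; the packaged defaults are open substitutes for
# the proprietary predictors (parity is approximate by construction).

#' Load the QSPR model configuration
#'
#' Reads the model config: for each predicted descriptor a named coefficient
#' list (including \code{intercept}), its declared inputs and a citation
#' tag. The packaged default uses the published linear logBB regression in
#' logP and PSA (coefficients 0.152, -0.0148, intercept 0.139), a linear
#' epithelial-permeability surrogate in PSA and logP for Caco-2, an affine
#' map from Caco-2 for MDCK, and a logP-dominated linear model for serum
#' albumin binding.
#'
#' @param path YAML config; defaults to the packaged file.
#' @return named list of model specs.
#' @export
loadQsprConfig <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "qspr_default.yaml", package = "pvlBBB",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  for (need in c("logbb", "caco2", "mdck", "logkhsa")) {
    if (is.null(cfg[[need]]))
      stop("QSPR config is missing the '", need, "' model", call. = FALSE)
    if (is.null(cfg[[need]]$coefficients$intercept))
      stop("QSPR model '", need, "' has no intercept", call. = FALSE)
  }
  cfg
}

# Evaluate a linear model spec on named input vectors.
.predictLinear <- function(model, inputs) {
  co <- model$coefficients
  y <- rep(co$intercept, length(inputs[[1]]))
  for (nm in setdiff(names(co), "intercept")) {
    if (is.null(inputs[[nm]]))
      stop("QSPR model needs input '", nm, "'", call. = FALSE)
    y <- y + co[[nm]] * inputs[[nm]]
  }
  y
}

#' Predict the brain/blood partition coefficient (logBB)
#'
#' Linear regression in logP and polar surface area:
#' \code{logbb = a*logp + b*psa + intercept}. With the default
#' coefficients (0.152, -0.0148, 0.139) this is the published two-variable
#' logBB model; logBB decreases strictly with PSA. The CNS window used for
#' classification is the open interval (-3.00, 1.20).
#'
#' @param logp,psa numeric vectors.
#' @param model model spec from \code{\link{loadQsprConfig}}.
#' @param window CNS classification window.
#' @return data.frame with columns \code{logbb} and \code{cns_window}
#'   (logical: strictly inside the window).
#' @examples
#' predictLogBB(2.0, 50)  # 0.152*2 - 0.0148*50 + 0.139 = -0.297
#' @export
predictLogBB <- function(logp, psa, model = loadQsprConfig()$logbb,
                         window = c(-3.00, 1.20)) {
  logbb <- .predictLinear(model, list(logp = logp, psa = psa))
  data.frame(logbb = logbb,
             cns_window = logbb > window[1] & logbb < window[2])
}

#' Predict Caco-2 and MDCK permeability
#'
#' Caco-2 apparent permeability (log10 cm/s) from a linear model in PSA and
#' logP (strictly decreasing in PSA); MDCK from the configured affine map
#' of the Caco-2 value, so the two rank identically under the defaults.
#'
#' @param psa,logp numeric vectors.
#' @param models QSPR config (uses \code{$caco2} and \code{$mdck}).
#' @return data.frame with columns \code{caco2}, \code{mdck}.
#' @export
predictCellPermeability <- function(psa, logp, models = loadQsprConfig()) {
  caco2 <- .predictLinear(models$caco2, list(psa = psa, logp = logp))
  mdck <- .predictLinear(models$mdck, list(caco2 = caco2))
  data.frame(caco2 = caco2, mdck = mdck)
}

#' Predict serum-albumin binding (logKhsa)
#'
#' Linear model dominated by lipophilicity (positive logP coefficient) with
#' a small flexibility term.
#'
#' @param logp,rotb numeric vectors.
#' @param model model spec from \code{\link{loadQsprConfig}}.
#' @return numeric vector.
#' @export
predictLogKhsa <- function(logp, rotb, model = loadQsprConfig()$logkhsa) {
  .predictLinear(model, list(logp = logp, rotb = rotb))
}
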
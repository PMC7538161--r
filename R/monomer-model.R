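#' Single-fluorophore intensity model
#'
#' Parameterizes the integrated intensity of one fluorescent protein detected
#' on an EMCCD camera. When the fluorophore is emitting, its intensity is
#' log-normal with log-scale location `mu` and scale `sigma`; with
#' probability `nu` the fluorophore is dark (immature or misfolded GFP) and
#' contributes no intensity at all.
#'
#' @param mu Location of the underlying normal variable (natural log of
#'   intensity in ADU).
#' @param sigma Scale of the underlying normal variable; must be positive.
#' @param nu Dark fraction: probability that a fluorophore is non-emitting.
#'   Must lie in `[0, 1)`. Defaults to 0.
#' @return An object of class `monomer_model`.
#' @examples
#' m <- monomer_model(mu = log(500), sigma = 0.35, nu = 0.3)
#' lognormal_pdf(500, m)
#' @export
monomer_model <- function(mu, sigma, nu = 0) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu))
    stop("'mu' must be a single finite number")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a single positive number")
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) ||
      nu < 0 || nu >= 1)
    stop("'nu' must lie in [0, 1)")
  structure(list(mu = mu, sigma = sigma, nu = nu), class = "monomer_model")
}

#' @export
print.monomer_model <- function(x, ...) {
  cat(sprintf(
    "monomer intensity model: mu = %.4f (median %.1f ADU), sigma = %.4f, dark fraction nu = %.3f\n",
    x$mu, exp(x$mu), x$sigma, x$nu))
  invisible(x)
}

#' Log-normal intensity density of a bright fluorophore
#'
#' Density of the integrated spot intensity of a single emitting fluorophore,
#' `1/(x sigma sqrt(2 pi)) exp(-(ln x - mu)^2 / (2 sigma^2))`. The dark
#' fraction of `model` plays no role here: this is the density conditional on
#' the fluorophore being bright.
#'
#' @param x Intensities (ADU); all must be strictly positive.
#' @param model A [monomer_model()].
#' @return Densities (1/ADU), same length as `x`.
#' @export
lognormal_pdf <- function(x, model) {
  stopifnot(inherits(model, "monomer_model"))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("'x' must be strictly positive and finite")
  stats::dlnorm(x, meanlog = model$mu, sdlog = model$sigma)
}

#' Mean intensity of a bright fluorophore
#'
#' Closed-form mean `exp(mu + sigma^2/2)` of the log-normal bright-state
#' intensity.
#'
#' @param model A [monomer_model()].
#' @return Mean intensity in ADU.
#' @export
bright_mean <- function(model) {
  stopifnot(inherits(model, "monomer_model"))
  exp(model$mu + model$sigma^2 / 2)
}
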
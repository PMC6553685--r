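#' Behavioural (social) parameters
#'
#' Container for the constants of the imitation-dynamics behaviour model.
#' Parameters can be supplied in *reduced* form (`beta`, `fmax`) -- the form
#' that enters the replicator right-hand side -- or in *raw* form
#' (`alpha`, `gamma`, `c`, `ftilde_max`), in which case the reduction
#' `beta = alpha - gamma`, `fmax = (c + 1) * ftilde_max` is applied and both
#' representations are stored.
#'
#' @param kappa social learning (sampling) rate, per year. Individuals sample
#'   others at this rate and may imitate a higher-payoff strategy.
#' @param beta net cost of mitigation, `alpha - gamma` (utility units).
#'   Ignored when the raw quadruple is supplied.
#' @param fmax ceiling of the scaled perceived climate-change cost curve
#'   (utility units). Ignored when the raw quadruple is supplied.
#' @param delta strength of social norms: utility bonus for conforming to the
#'   majority behaviour, whichever it is (utility units).
#' @param omega steepness of the perceived-cost sigmoid (per degree C).
#' @param Tc critical temperature anomaly at which perceived costs are most
#'   sensitive (degrees C).
#' @param tf forward extrapolation horizon of the temperature projection
#'   (years; `tf = 0` means decisions use the current anomaly only).
#' @param tp backward window over which the recent temperature trend is taken
#'   (years).
#' @param x0 initial proportion of mitigators when social dynamics start.
#' @param alpha,gamma,c,ftilde_max optional raw-form parameters: cost of
#'   adopting mitigative strategies, cost imposed on non-mitigative behaviour
#'   (e.g. a carbon tax), climate-cost proportionality constant for
#'   mitigators, and the unscaled cost ceiling. Supply all four or none.
#'
#' @return An object of class `social_params` (a named list).
#' @examples
#' p <- social_params()                      # reduced-form defaults
#' q <- social_params(alpha = 1.5, gamma = 0.5, c = 4, ftilde_max = 1)
#' q$beta   # 1
#' q$fmax   # 5
#' @export
social_params <- function(kappa = 0.05, beta = 1, fmax = 5, delta = 1,
                          omega = 3, Tc = 2.5, tf = 40, tp = 10, x0 = 0.05,
                          alpha = NULL, gamma = NULL, c = NULL,
                          ftilde_max = NULL) {
  raw <- list(alpha = alpha, gamma = gamma, c = c, ftilde_max = ftilde_max)
  n_raw <- sum(!vapply(raw, is.null, logical(1)))
  if (n_raw > 0 && n_raw < 4)
    stop("supply all of alpha, gamma, c, ftilde_max, or none", call. = FALSE)
  if (n_raw == 4) {
    beta <- alpha - gamma
    fmax <- (c + 1) * ftilde_max
  }
  p <- list(kappa = kappa, beta = beta, fmax = fmax, delta = delta,
            omega = omega, Tc = Tc, tf = tf, tp = tp, x0 = x0,
            alpha = if (n_raw == 4) alpha else NA_real_,
            gamma = if (n_raw == 4) gamma else NA_real_,
            c = if (n_raw == 4) c else NA_real_,
            ftilde_max = if (n_raw == 4) ftilde_max else NA_real_)
  class(p) <- "social_params"
  validate_social_params(p)
  p
}

validate_social_params <- function(p) {
  stopifnot(inherits(p, "social_params"))
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (nm in c("kappa", "beta", "fmax", "delta", "omega", "Tc", "tf", "tp",
               "x0"))
    if (!num1(p[[nm]]))
      stop("social parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
  if (p$kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (p$omega <= 0) stop("omega must be > 0", call. = FALSE)
  if (p$fmax <= 0)  stop("fmax must be > 0", call. = FALSE)
  if (p$tp <= 0)    stop("tp must be > 0", call. = FALSE)
  if (p$tf < 0)     stop("tf must be >= 0", call. = FALSE)
  if (p$x0 < 0 || p$x0 > 1) stop("x0 must lie in [0, 1]", call. = FALSE)
  if (has_raw_form(p)) {
    if (abs(p$beta - (p$alpha - p$gamma)) > 1e-12 * max(1, abs(p$beta)))
      stop("beta inconsistent with alpha - gamma", call. = FALSE)
    if (p$ftilde_max <= 0) stop("ftilde_max must be > 0", call. = FALSE)
    if (abs(p$fmax - (p$c + 1) * p$ftilde_max) >
        1e-12 * max(1, abs(p$fmax)))
      stop("fmax inconsistent with (c + 1) * ftilde_max", call. = FALSE)
  }
  invisible(p)
}

has_raw_form <- function(p) {
  !any(is.na(c(p$alpha, p$gamma, p$c, p$ftilde_max)))
}

#' @export
print.social_params <- function(x, ...) {
  cat("Social parameters (imitation dynamics with norms)\n")
  cat(sprintf("  kappa = %g /yr   beta = %g   delta = %g\n",
              x$kappa, x$beta, x$delta))
  cat(sprintf("  perceived cost: fmax = %g, omega = %g /C, Tc = %g C\n",
              x$fmax, x$omega, x$Tc))
  cat(sprintf("  projection: tp = %g yr back, tf = %g yr forward\n",
              x$tp, x$tf))
  cat(sprintf("  x0 = %g\n", x$x0))
  if (has_raw_form(x))
    cat(sprintf("  raw form: alpha = %g, gamma = %g, c = %g, ftilde_max = %g\n",
                x$alpha, x$gamma, x$c, x$ftilde_max))
  invisible(x)
}

# replace a subset of fields, revalidating; used by experiments for overrides
modify_social_params <- function(p, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(p))
      stop("unknown social parameter: '", nm, "'", call. = FALSE)
    p[[nm]] <- overrides[[nm]]
  }
  # overriding a reduced-form field invalidates a stored raw form
  if (any(c("beta", "fmax") %in% names(overrides)))
    p[c("alpha", "gamma", "c", "ftilde_max")] <- NA_real_
  validate_social_params(p)
  p
}
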
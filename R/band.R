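#' Continuous dendritic weight profile
#'
#' Represents the weight of the dendrite at continuum index (or ring
#' distance) `x` by a positive, monotone non-increasing function `w(x)`.
#' Supported families: `power_law` (`a / (x + b)^p`), `gaussian`
#' (`amplitude * exp(-x^2 / (2 width^2))`), `tabulated` (linear interpolation
#' of sampled values) and `custom` (arbitrary function).  Power-law and
#' Gaussian profiles invert analytically; tabulated and custom profiles are
#' inverted numerically by monotone bisection.
#'
#' @param family one of `"power_law"`, `"gaussian"`, `"tabulated"`, `"custom"`.
#' @param a,b,p power-law parameters.
#' @param amplitude,width Gaussian parameters.
#' @param x,w samples for the tabulated family.
#' @param fn function of distance for the custom family.
#' @param domain upper end of the index domain `[0, domain]` used for
#'   validation and numeric inversion.
#' @return an object of class `weight_profile`, callable via
#'   [weight_at()] and invertible via [weight_inverse()].
#' @export
weight_profile <- function(family = c("power_law", "gaussian", "tabulated",
                                      "custom"),
                           a = 18, b = 2, p = 2,
                           amplitude = 10, width = 3,
                           x = NULL, w = NULL, fn = NULL,
                           domain = 1000) {
  family <- match.arg(family)
  prof <- switch(family,
    power_law = {
      stopifnot(a > 0, b > 0, p > 0)
      list(fn = function(x) a / (x + b)^p,
           inv = function(y) (a / y)^(1 / p) - b,
           pars = list(a = a, b = b, p = p))
    },
    gaussian = {
      stopifnot(amplitude > 0, width > 0)
      list(fn = function(x) amplitude * exp(-x^2 / (2 * width^2)),
           inv = function(y) width * sqrt(2 * log(amplitude / y)),
           pars = list(amplitude = amplitude, width = width))
    },
    tabulated = {
      stopifnot(!is.null(x), !is.null(w), length(x) == length(w),
                all(w > 0), !is.unsorted(x))
      if (any(diff(w) > 1e-12))
        stop("tabulated weights must be monotone non-increasing")
      f <- stats::approxfun(x, w, rule = 2)
      list(fn = f, inv = NULL, pars = list(x = x, w = w))
    },
    custom = {
      stopifnot(is.function(fn))
      list(fn = fn, inv = NULL, pars = list())
    })
  obj <- list(family = family, fn = prof$fn, inv = prof$inv,
              pars = prof$pars, domain = domain)
  # validate positivity and monotonicity on a coarse sample of the domain
  xs <- seq(0, domain, length.out = 201)
  ws <- obj$fn(xs)
  if (any(!is.finite(ws)) || any(ws <= 0))
    stop("weight profile must be positive and finite on its domain")
  if (any(diff(ws) > 1e-9 * max(ws)))
    stop("weight profile must be monotone non-increasing")
  class(obj) <- "weight_profile"
  obj
}

#' Evaluate a weight profile
#' @param profile a [weight_profile()].
#' @param x distances / continuum indices.
#' @return weights `w(x)`.
#' @export
weight_at <- function(profile, x) {
  stopifnot(inherits(profile, "weight_profile"))
  profile$fn(x)
}

#' Invert a weight profile
#'
#' Returns the index `x` with `w(x) = y`, clamped to `[0, domain]`:
#' values above `w(0)` map to 0 and values below `w(domain)` to `domain`.
#' Analytic for power-law and Gaussian families, monotone bisection
#' otherwise.
#'
#' @param profile a [weight_profile()].
#' @param y weight values (> 0).
#' @return indices in `[0, domain]`.
#' @export
weight_inverse <- function(profile, y) {
  stopifnot(inherits(profile, "weight_profile"), all(y > 0))
  d <- profile$domain
  w0 <- profile$fn(0)
  wd <- profile$fn(d)
  out <- numeric(length(y))
  for (k in seq_along(y)) {
    yy <- y[k]
    if (yy >= w0) out[k] <- 0
    else if (yy <= wd) out[k] <- d
    else if (!is.null(profile$inv)) out[k] <- min(max(profile$inv(yy), 0), d)
    else out[k] <- uniroot(function(x) profile$fn(x) - yy, c(0, d),
                           tol = 1e-10)$root
  }
  out
}

#' Discrete multistable feedback band
#'
#' The summed hysteretic dendritic feedback of an autapse forms a staircase
#' band in the (rate, feedback) plane.  The right edge `Bu(r)` counts (times
#' `beta`) the dendrites whose up threshold has been reached,
#' `beta * #\{i : r >= ru_i\}`; the left edge `Bd(r)` counts the dendrites
#' whose drive still exceeds the down threshold, `beta * #\{i : r > rd_i\}`.
#' Intersections of the band interior with the unity-slope line `r` are the
#' stable persistent rates.
#'
#' @param model an [autapse_model()].
#' @return object of class `band` (type `"discrete"`) with fields `ru`, `rd`
#'   (sorted threshold rates), `beta`, `Nd`, `saturation`.
#' @export
discrete_band <- function(model) {
  stopifnot(inherits(model, "autapse_model"))
  b <- list(type = "discrete",
            ru = sort(model$Tu / model$weights),
            rd = sort(model$Td / model$weights),
            beta = model$beta, Nd = model$Nd,
            saturation = model$beta * model$Nd)
  class(b) <- "band"
  b
}

#' Continuum multistable feedback band
#'
#' Continuum limit of the staircase band for a smooth weight profile: on the
#' middle branch `Bu(r) = beta * w^{-1}(Tu / r)`, saturating at 0 below the
#' first activation threshold and at `beta * Nd` above the last; `Bd` is
#' analogous with `Td`.
#'
#' @param profile a [weight_profile()].
#' @param Tu,Td latch thresholds.
#' @param beta per-dendrite contribution.
#' @param Nd number of dendrites (continuum domain upper end).
#' @return object of class `band` (type `"continuum"`).
#' @export
continuum_band <- function(profile, Tu = 9, Td = 2, beta = 1, Nd) {
  stopifnot(inherits(profile, "weight_profile"), Tu >= Td, Nd > 0)
  prof <- profile
  prof$domain <- Nd
  b <- list(type = "continuum", profile = prof, Tu = Tu, Td = Td,
            beta = beta, Nd = Nd, saturation = beta * Nd)
  class(b) <- "band"
  b
}

#' Evaluate band edges
#'
#' `band_u()` returns the right (up-threshold) edge `Bu(r)` and `band_d()`
#' the left (down-threshold) edge `Bd(r)`.
#'
#' @param band a `band` from [discrete_band()] or [continuum_band()].
#' @param r firing rates (vectorized).
#' @return feedback values in `[0, beta * Nd]`.
#' @export
band_u <- function(band, r) {
  stopifnot(inherits(band, "band"))
  if (band$type == "discrete") {
    band$beta * vapply(r, function(x) sum(x >= band$ru), numeric(1))
  } else {
    out <- numeric(length(r))
    pos <- r > 0
    out[pos] <- band$beta *
      weight_inverse(band$profile, band$Tu / r[pos])
    out
  }
}

#' @rdname band_u
#' @export
band_d <- function(band, r) {
  stopifnot(inherits(band, "band"))
  if (band$type == "discrete") {
    band$beta * vapply(r, function(x) sum(x > band$rd), numeric(1))
  } else {
    out <- numeric(length(r))
    pos <- r > 0
    if (band$Td <= 0) {
      out[pos] <- band$saturation
    } else {
      out[pos] <- band$beta *
        weight_inverse(band$profile, band$Td / r[pos])
    }
    out
  }
}

#' @export
as.data.frame.band <- function(x, row.names = NULL, optional = FALSE,
                               r = NULL, ...) {
  if (is.null(r)) {
    rmax <- if (x$type == "discrete") max(x$ru, x$rd) * 1.2
            else x$saturation * 1.2
    r <- seq(0, rmax, length.out = 400)
  }
  data.frame(r = r, Bu = band_u(x, r), Bd = band_d(x, r))
}
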
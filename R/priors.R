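#' Truncated-normal prior specification
#'
#' One truncated normal per free DDM parameter: `location` and `scale` are the
#' mean and SD of the untruncated normal; `lower`/`upper` are hard bounds.
#' Zero-width bounds (`lower == upper`) pin a parameter at that value.
#'
#' @param location,scale,lower,upper numeric vectors, one entry per parameter;
#'   names are taken from `location` (or `parameters`).
#' @param parameters optional character vector of parameter names.
#' @return data frame with class `"prior_spec"`, one row per parameter.
#' @export
prior_spec <- function(location, scale, lower, upper, parameters = NULL) {
  if (is.null(parameters)) parameters <- names(location)
  if (is.null(parameters)) stop("parameter names are required")
  out <- data.frame(parameter = parameters, location = as.numeric(location),
                    scale = as.numeric(scale), lower = as.numeric(lower),
                    upper = as.numeric(upper), stringsAsFactors = FALSE)
  validate_prior_spec(out)
  class(out) <- c("prior_spec", "data.frame")
  out
}

validate_prior_spec <- function(p) {
  stopifnot(all(c("parameter", "location", "scale", "lower", "upper")
                %in% names(p)))
  if (any(p$lower > p$upper)) stop("prior lower bound exceeds upper bound")
  free <- p$lower < p$upper
  if (any(p$scale[free] <= 0)) stop("prior scale must be > 0")
  invisible(p)
}

#' Multiply prior scales by a constant factor
#'
#' Widens (factor > 1) or narrows (factor < 1) every prior; locations and
#' bounds are unchanged.  A factor of 1.5 is the conventional widening used
#' when transporting priors to a population that may differ from the
#' prior-generation sample.
#'
#' @param priors a [prior_spec()].
#' @param factor positive scale multiplier.
#' @return the rescaled `prior_spec`.
#' @export
scale_priors <- function(priors, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) ||
      factor <= 0)
    stop("'factor' must be a positive scalar")
  priors$scale <- priors$scale * factor
  priors
}

#' Fit a truncated normal to a pool of posterior draws
#'
#' Maximum-likelihood location and scale of a normal truncated to
#' `[lower, upper]`, fitted to pooled posterior samples of one parameter.
#' This is the prior-construction step: individual-level posterior draws from
#' a reference cohort are pooled per parameter and summarized as a truncated
#' normal that becomes the informative prior for new fits.
#'
#' @param x numeric pool of draws (length >= 100).
#' @param lower,upper truncation bounds of the resulting prior.
#' @return named vector `c(location, scale)`.
#' @export
fit_truncated_normal_prior <- function(x, lower, upper) {
  x <- x[is.finite(x)]
  if (length(x) < 100) stop("need at least 100 pooled draws")
  if (sd(x) < 1e-12) stop("degenerate pool: zero variance")
  if (any(x < lower - 1e-9) || any(x > upper + 1e-9))
    stop("pool values fall outside the truncation bounds")
  nll <- function(par) {
    mu <- par[1]; sg <- exp(par[2])
    zl <- pnorm((lower - mu) / sg)
    zu <- pnorm((upper - mu) / sg)
    lz <- log(zu - zl)
    if (!is.finite(lz)) return(1e10)
    -sum(dnorm(x, mu, sg, log = TRUE) - lz)
  }
  fit <- optim(c(mean(x), log(sd(x))), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  c(location = fit$par[1], scale = exp(fit$par[2]))
}

#' Default truncation bounds for each DDM parameter
#'
#' Bounds chosen to cover plausible human RT regimes: drifts in `[-10, 10]`,
#' boundary in `(0, 10]`, `t0` in `[0.05, 1]` s, `st0` in `[0, 1]` s, start
#' point in `(0.1, 0.9)`, contaminant probability in `[0, 0.5]`.
#'
#' @return data frame with `parameter`, `lower`, `upper` for all 16 parameters.
#' @export
ddm_parameter_bounds <- function() {
  per_cond <- data.frame(
    parameter = PAR_NAMES_COND,
    lower = c(-10, -10, -10, 1e-3, 0.05, 0, 0.1, 0),
    upper = c(10, 10, 10, 10, 1, 1, 0.9, 0.5),
    stringsAsFactors = FALSE)
  out <- rbind(per_cond, per_cond)
  out$parameter <- PAR_NAMES_16
  out
}

#' Broad priors used for the prior-emulation (reference) fits
#'
#' Weakly informative truncated normals over [ddm_parameter_bounds()]; used to
#' fit the reference cohort whose pooled posteriors define the shipped
#' informative priors.
#'
#' @return a [prior_spec()].
#' @export
vague_priors <- function() {
  b <- ddm_parameter_bounds()
  loc_cond <- c(1, 1, 1, 1.5, 0.3, 0.2, 0.5, 0.1)
  sc_cond <- c(5, 5, 5, 2, 0.3, 0.3, 0.2, 0.15)
  prior_spec(location = rep(loc_cond, 2), scale = rep(sc_cond, 2),
             lower = b$lower, upper = b$upper, parameters = b$parameter)
}

#' Shipped informative priors
#'
#' Truncated-normal priors obtained by fitting 300 synthetic reference
#' subjects under [vague_priors()], pooling all individual-level posterior
#' draws per parameter, and fitting a truncated normal to each pool (see
#' [emulate_priors()]).  Shipped as a YAML file and versioned with the
#' package.
#'
#' @return a [prior_spec()].
#' @export
default_priors <- function() {
  path <- system.file("extdata", "default_priors.yaml", package = "eeanet")
  if (!nzchar(path)) stop("default prior file not found")
  read_priors(path)
}

#' Read / write a prior specification as YAML
#'
#' @param path file path.
#' @return [read_priors()] returns a [prior_spec()]; `write_priors()` returns
#'   `path` invisibly.
#' @export
read_priors <- function(path) {
  y <- yaml::read_yaml(path)
  prior_spec(location = vapply(y, function(e) e$location, 0),
             scale = vapply(y, function(e) e$scale, 0),
             lower = vapply(y, function(e) e$lower, 0),
             upper = vapply(y, function(e) e$upper, 0),
             parameters = names(y))
}

#' @rdname read_priors
#' @param priors a [prior_spec()].
#' @export
write_priors <- function(priors, path) {
  y <- lapply(seq_len(nrow(priors)), function(i)
    list(location = priors$location[i], scale = priors$scale[i],
         lower = priors$lower[i], upper = priors$upper[i]))
  names(y) <- priors$parameter
  yaml::write_yaml(y, path)
  invisible(path)
}

# log prior density on the natural scale; rows of theta, -Inf outside bounds.
# Includes the truncation normalizing constants so zero-width / widened priors
# compare correctly.
prior_logpdf <- function(priors, theta) {
  n <- nrow(theta)
  lp <- numeric(n)
  for (j in seq_len(nrow(priors))) {
    x <- theta[, j]
    lo <- priors$lower[j]; up <- priors$upper[j]
    if (lo == up) {  # pinned parameter
      lp[x != lo] <- -Inf
      next
    }
    mu <- priors$location[j]; sg <- priors$scale[j]
    lz <- log(pnorm(up, mu, sg) - pnorm(lo, mu, sg))
    out <- dnorm(x, mu, sg, log = TRUE) - lz
    out[x < lo | x > up] <- -Inf
    lp <- lp + out
  }
  lp
}

# draw n parameter vectors from the prior (inverse-CDF truncated normal)
sample_from_prior <- function(priors, n) {
  theta <- matrix(0, n, nrow(priors),
                  dimnames = list(NULL, priors$parameter))
  for (j in seq_len(nrow(priors))) {
    lo <- priors$lower[j]; up <- priors$upper[j]
    if (lo == up) {
      theta[, j] <- lo
      next
    }
    mu <- priors$location[j]; sg <- priors$scale[j]
    plo <- pnorm(lo, mu, sg); pup <- pnorm(up, mu, sg)
    u <- plo + (pup - plo) * runif(n)
    x <- qnorm(u, mu, sg)
    theta[, j] <- pmin(pmax(x, lo + 1e-9 * (up - lo)),
                       up - 1e-9 * (up - lo))
  }
  theta
}
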
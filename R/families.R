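# Bivariate copula families: specs, cdfs, h-functions, densities,
# reflection and Kendall's tau maps.

# family registry: code is the integer tag used by the C++ kernels
.FAMS <- data.frame(
  family = c("indep", "bvn", "t", "gumbel", "sgumbel", "frank"),
  code   = 0:5,
  stringsAsFactors = FALSE
)

# default grid of degrees of freedom for the t family
.T_NU_GRID <- c(2, 3, 5, 7)

#' Parse a family label
#'
#' Accepts the canonical labels `"indep"`, `"bvn"`, `"gumbel"`,
#' `"sgumbel"`, `"frank"`, `"t"` as well as the compact t labels
#' `"t2"`, `"t3"`, `"t5"`, `"t7"` (any positive numeric suffix works).
#'
#' @param label character scalar.
#' @return list with elements `family` and `nu` (`NA` unless Student-t).
#' @export
parse_family <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  lab <- tolower(label)
  if (lab %in% c("independence", "indep")) lab <- "indep"
  if (grepl("^t[0-9.]+$", lab)) {
    nu <- as.numeric(sub("^t", "", lab))
    return(list(family = "t", nu = nu))
  }
  if (!lab %in% .FAMS$family)
    stop("unknown copula family: '", label, "'", call. = FALSE)
  list(family = lab, nu = if (lab == "t") 5 else NA_real_)
}

fam_code <- function(family) .FAMS$code[match(family, .FAMS$family)]

#' Bivariate copula specification
#'
#' Creates a validated specification of a one-parameter bivariate copula
#' used as a building block of the factor tree models.  Parameter
#' domains: BVN and Student-t `theta` in \[-1, 1\]; Gumbel and survival
#' Gumbel `theta >= 1`; Frank `theta` real and nonzero; the independence
#' copula has no parameter.
#'
#' @param family family label (see [parse_family()]); `"t2"` style labels
#'   set `nu` implicitly.
#' @param theta dependence parameter (omit for `"indep"`).
#' @param nu degrees of freedom for the t family.
#' @return object of class `"bicop_spec"`.
#' @examples
#' bicop_spec("gumbel", theta = 2)
#' bicop_spec("t2", theta = 0.5)
#' @export
bicop_spec <- function(family, theta = NULL, nu = NULL) {
  pf <- parse_family(family)
  fam <- pf$family
  if (is.null(nu) && !is.na(pf$nu)) nu <- pf$nu
  if (fam == "t") {
    if (is.null(nu) || !is.finite(nu) || nu <= 0)
      stop("t copula requires degrees of freedom nu > 0", call. = FALSE)
  } else nu <- NA_real_
  if (fam == "indep") {
    theta <- NA_real_
  } else {
    if (is.null(theta) || !is.finite(theta))
      stop("family '", fam, "' requires a finite parameter theta",
           call. = FALSE)
    if (fam %in% c("bvn", "t") && abs(theta) > 1)
      stop(fam, " copula requires theta in [-1, 1]", call. = FALSE)
    if (fam %in% c("gumbel", "sgumbel") && theta < 1)
      stop(fam, " copula requires theta >= 1", call. = FALSE)
    if (fam == "frank" && theta == 0)
      stop("frank copula requires theta != 0 (use 'indep' instead)",
           call. = FALSE)
  }
  structure(list(family = fam, theta = theta, nu = nu,
                 code = fam_code(fam)),
            class = "bicop_spec")
}

#' @export
print.bicop_spec <- function(x, ...) {
  lab <- if (x$family == "t") sprintf("t(nu=%g)", x$nu) else x$family
  if (x$family == "indep") cat("bivariate copula:", lab, "\n")
  else cat(sprintf("bivariate copula: %s, theta = %.4g (tau = %.3f)\n",
                   lab, x$theta, par_to_tau(x)))
  invisible(x)
}

spec_args <- function(spec) {
  list(code = spec$code,
       theta = if (is.na(spec$theta)) 0 else spec$theta,
       nu = if (is.na(spec$nu)) 5 else spec$nu)
}

#' Bivariate copula cdf
#'
#' @param u,v numeric vectors of probabilities in \[0, 1\] (recycled).
#' @param spec a [bicop_spec()].
#' @return `C(u, v; theta)`.
#' @export
pbicop <- function(u, v, spec) {
  stopifnot(inherits(spec, "bicop_spec"))
  a <- spec_args(spec)
  cpp_bicop_cdf(as.numeric(u), as.numeric(v), a$code, a$theta, a$nu)
}

#' Bivariate copula h-function (conditional cdf)
#'
#' Returns the conditional cdf `h(v | u) = dC(u, v)/du`, i.e. the cdf of
#' the second argument given the first (conditioning) argument.
#'
#' @param v numeric vector: argument whose conditional cdf is evaluated.
#' @param u numeric vector: conditioning value in (0, 1).
#' @param spec a [bicop_spec()].
#' @export
hbicop <- function(v, u, spec) {
  stopifnot(inherits(spec, "bicop_spec"))
  a <- spec_args(spec)
  cpp_bicop_hfun(as.numeric(v), as.numeric(u), a$code, a$theta, a$nu)
}

#' Bivariate copula density
#'
#' @inheritParams pbicop
#' @export
dbicop <- function(u, v, spec) {
  stopifnot(inherits(spec, "bicop_spec"))
  a <- spec_args(spec)
  cpp_bicop_pdf(as.numeric(u), as.numeric(v), a$code, a$theta, a$nu)
}

#' Reflected (survival) copula of a specification
#'
#' The reflected copula is the distribution of `(1 - U1, 1 - U2)`; its cdf
#' is `u + v - 1 + C(1 - u, 1 - v)`.  Reflection swaps the Gumbel and
#' survival Gumbel families and leaves the reflection-symmetric families
#' (independence, BVN, t, Frank) unchanged.
#'
#' @param spec a [bicop_spec()].
#' @return the reflected [bicop_spec()].
#' @export
reflect_bicop <- function(spec) {
  stopifnot(inherits(spec, "bicop_spec"))
  fam <- switch(spec$family, gumbel = "sgumbel", sgumbel = "gumbel",
                spec$family)
  if (fam == "indep") return(bicop_spec("indep"))
  bicop_spec(fam, theta = spec$theta, nu = spec$nu)
}

# Debye function D1(x) = (1/x) int_0^x t / (e^t - 1) dt, x > 0
debye1 <- function(x) {
  f <- function(t) ifelse(t < 1e-10, 1 - t / 2, t / expm1(t))
  integrate(f, 0, x, rel.tol = 1e-12)$value / x
}

#' Kendall's tau of a bivariate copula
#'
#' Closed forms: `tau = 1 - 1/theta` for Gumbel and survival Gumbel;
#' `tau = (2/pi) asin(theta)` for BVN and t.  The Frank tau uses the
#' Debye-function formula `tau = 1 - (4/theta)(1 - D1(theta))`.
#'
#' @param spec a [bicop_spec()].
#' @return Kendall's tau.
#' @export
par_to_tau <- function(spec) {
  stopifnot(inherits(spec, "bicop_spec"))
  switch(spec$family,
    indep = 0,
    bvn = ,
    t = 2 / pi * asin(spec$theta),
    gumbel = ,
    sgumbel = 1 - 1 / spec$theta,
    frank = {
      th <- abs(spec$theta)
      sign(spec$theta) * (1 - 4 / th * (1 - debye1(th)))
    })
}

#' Copula parameter from Kendall's tau
#'
#' Inverse of [par_to_tau()].  Attainable ranges: Gumbel/survival Gumbel
#' `tau` in \[0, 1); BVN/t `tau` in (-1, 1); Frank `tau` in (-1, 1)
#' excluding 0 (Frank `theta` is found by root search and is accurate to
#' about 1e-8 in the tau round trip).
#'
#' @param family family label.
#' @param tau target Kendall's tau.
#' @param nu degrees of freedom if `family` is Student-t.
#' @return a [bicop_spec()] with the matching parameter.
#' @export
tau_to_par <- function(family, tau, nu = NULL) {
  pf <- parse_family(family)
  if (is.null(nu) && !is.na(pf$nu)) nu <- pf$nu
  fam <- pf$family
  if (fam == "indep") {
    if (abs(tau) > 1e-12)
      stop("independence copula attains only tau = 0", call. = FALSE)
    return(bicop_spec("indep"))
  }
  switch(fam,
    bvn = ,
    t = {
      if (abs(tau) >= 1)
        stop(fam, ": tau must lie in (-1, 1)", call. = FALSE)
      bicop_spec(fam, theta = sin(pi * tau / 2), nu = nu)
    },
    gumbel = ,
    sgumbel = {
      if (tau < 0 || tau >= 1)
        stop(fam, ": tau must lie in [0, 1)", call. = FALSE)
      bicop_spec(fam, theta = 1 / (1 - tau))
    },
    frank = {
      if (abs(tau) >= 1 || tau == 0)
        stop("frank: tau must lie in (-1, 1) excluding 0", call. = FALSE)
      at <- abs(tau)
      f <- function(th) 1 - 4 / th * (1 - debye1(th)) - at
      th <- uniroot(f, c(1e-6, 500), tol = 1e-12)$root
      bicop_spec("frank", theta = sign(tau) * th)
    })
}
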
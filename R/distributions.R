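#' Parametric distribution specification
#'
#' Builds a validated specification for one of the four distribution
#' families used by the intake model: `triangular` and `pert` (Beta-PERT)
#' for min / most-likely / max elicited inputs, `normal` for pooled means
#' with a standard deviation, and `uniform` for bounded reference ranges.
#'
#' @param family One of `"triangular"`, `"pert"`, `"normal"`, `"uniform"`.
#' @param params Named list of numeric parameters. Required fields:
#'   triangular `a`, `m`, `b`; pert `a`, `m`, `b` (optional `lam`, the PERT
#'   shape weight, default 4); normal `mu`, `sigma`; uniform `a`, `b`.
#'   Extra or missing fields are rejected.
#' @param units Free-text unit label (e.g. `"feeds/day"`, `"mL"`,
#'   `"kcal/dL"`, `"kg"`).
#'
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("triangular", list(a = 8, m = 11, b = 14), "feeds/day")
#' dist_spec("pert", list(a = 30, m = 70, b = 110), "mL")
#' @export
dist_spec <- function(family, params, units = "") {
  family <- match.arg(family, c("triangular", "pert", "normal", "uniform"))
  stopifnot(is.list(params))
  required <- switch(family,
    triangular = c("a", "m", "b"),
    pert       = c("a", "m", "b"),
    normal     = c("mu", "sigma"),
    uniform    = c("a", "b")
  )
  optional <- if (family == "pert") "lam" else character()
  got <- names(params)
  missing <- setdiff(required, got)
  extra <- setdiff(got, c(required, optional))
  if (length(missing))
    stop(sprintf("%s spec is missing parameter(s): %s",
                 family, paste(missing, collapse = ", ")), call. = FALSE)
  if (length(extra))
    stop(sprintf("%s spec has unknown parameter(s): %s",
                 family, paste(extra, collapse = ", ")), call. = FALSE)
  p <- lapply(params, function(x) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("distribution parameters must be finite numeric scalars",
           call. = FALSE)
    as.numeric(x)
  })

  if (family %in% c("triangular", "pert", "uniform")) {
    if (p$a >= p$b)
      stop(sprintf("%s spec requires a < b (got a = %g, b = %g)",
                   family, p$a, p$b), call. = FALSE)
  }
  if (family %in% c("triangular", "pert")) {
    if (p$m < p$a || p$m > p$b)
      stop(sprintf("%s spec requires a <= m <= b (got a = %g, m = %g, b = %g)",
                   family, p$a, p$m, p$b), call. = FALSE)
  }
  if (family == "pert") {
    if (is.null(p$lam)) p$lam <- 4
    if (p$lam <= 0)
      stop("pert spec requires lam > 0", call. = FALSE)
  }
  if (family == "normal" && p$sigma <= 0)
    stop(sprintf("normal spec requires sigma > 0 (got %g)", p$sigma),
         call. = FALSE)

  structure(c(list(family = family), p, list(units = units)),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), c("family", "units"))]
  cat(sprintf("<dist_spec> %s(%s)%s\n", x$family,
              paste(sprintf("%s = %g", names(pars), unlist(pars)),
                    collapse = ", "),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Beta-PERT shape parameters
#'
#' Maps the (min, mode, max, shape-weight) parametrisation of the PERT
#' distribution onto the two shape parameters of the underlying Beta
#' distribution on `[a, b]`:
#' `alpha1 = 1 + lam * (m - a) / (b - a)` and
#' `alpha2 = 1 + lam * (b - m) / (b - a)`.
#'
#' @param a,m,b Minimum, mode and maximum; `a <= m <= b`, `a < b`.
#' @param lam Shape weight (> 0); the conventional value 4 gives the
#'   classic PERT mean `(a + 4 m + b) / 6`.
#' @return Numeric vector `c(alpha1, alpha2)`, both positive.
#' @examples
#' pert_shape_params(30, 70, 110)  # symmetric: c(3, 3)
#' @export
pert_shape_params <- function(a, m, b, lam = 4) {
  if (a >= b) stop("degenerate PERT range: requires a < b", call. = FALSE)
  if (m < a || m > b) stop("PERT mode must satisfy a <= m <= b", call. = FALSE)
  if (lam <= 0) stop("PERT shape weight lam must be > 0", call. = FALSE)
  c(alpha1 = 1 + lam * (m - a) / (b - a),
    alpha2 = 1 + lam * (b - m) / (b - a))
}

#' Draw random variates from a distribution specification
#'
#' Samples i.i.d. draws from the spec's family using R's current random
#' number stream, so results are reproducible under `set.seed()`.
#' Triangular draws use the inverse-CDF transform of a single uniform;
#' PERT draws are Beta variates (shapes from [pert_shape_params()])
#' rescaled to `[a, b]`. Normal draws are untruncated, except that
#' non-positive values — essentially impossible at the model's default
#' parameters but physically meaningless — are resampled with a warning.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws (>= 1).
#' @return Numeric vector of length `n`. Triangular, PERT and uniform
#'   draws always lie in `[a, b]`.
#' @examples
#' set.seed(1)
#' x <- sample_spec(dist_spec("pert", list(a = 30, m = 70, b = 110)), 1000)
#' mean(x)  # close to the PERT mean (a + 4 m + b) / 6 = 70
#' @export
sample_spec <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  switch(spec$family,
    triangular = {
      u <- stats::runif(n)
      fc <- (spec$m - spec$a) / (spec$b - spec$a)
      ifelse(u < fc,
             spec$a + sqrt(u * (spec$b - spec$a) * (spec$m - spec$a)),
             spec$b - sqrt((1 - u) * (spec$b - spec$a) * (spec$b - spec$m)))
    },
    pert = {
      sh <- pert_shape_params(spec$a, spec$m, spec$b, spec$lam)
      spec$a + (spec$b - spec$a) * stats::rbeta(n, sh[[1L]], sh[[2L]])
    },
    uniform = stats::runif(n, spec$a, spec$b),
    normal = {
      x <- stats::rnorm(n, spec$mu, spec$sigma)
      bad <- which(x <= 0)
      if (length(bad)) {
        warning(sprintf(
          "%d non-positive normal draw(s) resampled (mu = %g, sigma = %g)",
          length(bad), spec$mu, spec$sigma), call. = FALSE)
        while (length(bad)) {
          x[bad] <- stats::rnorm(length(bad), spec$mu, spec$sigma)
          bad <- bad[x[bad] <= 0]
        }
      }
      x
    }
  )
}

#' Closed-form mean of a distribution specification
#'
#' Triangular `(a + m + b) / 3`; PERT `(a + lam * m + b) / (lam + 2)`;
#' uniform `(a + b) / 2`; normal `mu`. Used as the analytic oracle for
#' the Monte Carlo engine.
#'
#' @param spec A [dist_spec()].
#' @return The distribution mean.
#' @export
mean_of <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    triangular = (spec$a + spec$m + spec$b) / 3,
    pert       = (spec$a + spec$lam * spec$m + spec$b) / (spec$lam + 2),
    uniform    = (spec$a + spec$b) / 2,
    normal     = spec$mu
  )
}

#' Closed-form variance of a distribution specification
#'
#' Triangular `(a^2 + m^2 + b^2 - ab - am - bm) / 18`; PERT
#' `(mean - a) * (b - mean) / (lam + 3)`; uniform `(b - a)^2 / 12`;
#' normal `sigma^2`.
#'
#' @param spec A [dist_spec()].
#' @return The distribution variance.
#' @export
variance_of <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    triangular = (spec$a^2 + spec$m^2 + spec$b^2 -
                    spec$a * spec$b - spec$a * spec$m - spec$b * spec$m) / 18,
    pert = {
      mu <- mean_of(spec)
      (mu - spec$a) * (spec$b - mu) / (spec$lam + 3)
    },
    uniform = (spec$b - spec$a)^2 / 12,
    normal  = spec$sigma^2
  )
}

# Serialization to/from the plain-list form used in config files:
# list(family = ..., params = list(...), units = ...).
spec_to_list <- function(spec) {
  pars <- spec[setdiff(names(spec), c("family", "units"))]
  list(family = spec$family, params = pars, units = spec$units)
}

spec_from_list <- function(x) {
  for (f in c("family", "params"))
    if (is.null(x[[f]]))
      stop(sprintf("distribution block is missing field '%s'", f),
           call. = FALSE)
  dist_spec(x$family, as.list(x$params),
            units = if (is.null(x$units)) "" else x$units)
}
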
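#' Exponential-decay LDMC transform
#'
#' The transform `exp(-k * ldmc)` that linearises the decaying relationship
#' between community leaf dry matter content (mg g^-1) and livestock
#' productivity. With `k > 0` the value lies in `(0, 1]` for `ldmc >= 0` and
#' is monotone decreasing in LDMC.
#'
#' @param ldmc Community-weighted LDMC (mg g^-1).
#' @param k Decay rate per mg g^-1 (positive).
#' @return `exp(-k * ldmc)`.
#' @export
expDecay <- function(ldmc, k) {
  stopifnot(k > 0)
  exp(-k * ldmc)
}

#' Estimate the LDMC decay rate by nonlinear least squares
#'
#' Fits `productivity = a + b * exp(-k * ldmc)` to pooled plot-year records
#' by nonlinear least squares (random effects are ignored at this stage; the
#' estimated `k` is subsequently frozen and `exp(-k * ldmc)` used as a linear
#' covariate in the mixed models). Initialisation uses the asymptotic
#' regression self-start ([stats::SSasymp]); if that fails, a manual
#' fallback estimates the asymptote from the high-LDMC tail and
#' log-linearises for `k`.
#'
#' @param records Data frame with columns `productivity` and `cwm_ldmc` (or
#'   pass vectors via `productivity`/`ldmc`).
#' @param productivity,ldmc Optional explicit vectors overriding `records`.
#' @return An object of class `decay_transform`: list with `k`, `a`
#'   (asymptote), `b` (range coefficient), `rss`, `n`, `converged`, and the
#'   underlying `nls` fit.
#' @export
fitDecayTransform <- function(records = NULL, productivity = NULL, ldmc = NULL) {
  if (is.null(productivity)) productivity <- records$productivity
  if (is.null(ldmc)) ldmc <- records$cwm_ldmc
  ok <- is.finite(productivity) & is.finite(ldmc)
  y <- productivity[ok]; x <- ldmc[ok]
  if (length(y) < 10L) stop("need at least 10 records to estimate the decay rate")
  if (diff(range(x)) <= 0) stop("cwm_ldmc has zero range; decay rate is unidentifiable")

  df <- data.frame(y = y, x = x)
  fits <- list(
    tryCatch(
      stats::nls(y ~ SSasymp(x, Asym, R0, lrc), data = df,
                 control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
      error = function(e) NULL),
    decayProfileFit(df),
    decayFallbackFit(df))
  fits <- Filter(Negate(is.null), fits)
  # k > 0 is required; among admissible converged fits take the lowest RSS
  fits <- Filter(function(f) is.finite(exp(stats::coef(f)["lrc"])) &&
                   exp(stats::coef(f)["lrc"]) > 0, fits)
  if (!length(fits)) stop("decay-transform fit did not converge")
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  fit <- fits[[which.min(rss)]]

  cf <- stats::coef(fit)
  k <- unname(exp(cf["lrc"]))
  a <- unname(cf["Asym"])
  b <- unname(cf["R0"] - cf["Asym"])
  if (!is.finite(k) || k <= 0) stop("estimated decay rate k = ", k, " is not positive")
  structure(
    list(k = k, a = a, b = b,
         rss = sum(stats::resid(fit)^2), n = length(y),
         converged = TRUE, fit = fit),
    class = "decay_transform"
  )
}

# profiled initialisation: for fixed k the model is linear in (a, b), so the
# RSS can be profiled over a log-spaced k grid; the grid optimum starts nls
decayProfileFit <- function(df) {
  kgrid <- exp(seq(log(1e-4), log(0.5), length.out = 81))
  rss <- vapply(kgrid, function(k) {
    z <- exp(-k * df$x)
    if (stats::sd(z) == 0) return(Inf)
    sum(stats::lm.fit(cbind(1, z), df$y)$residuals^2)
  }, numeric(1))
  k0 <- kgrid[which.min(rss)]
  cf <- stats::lm.fit(cbind(1, exp(-k0 * df$x)), df$y)$coefficients
  tryCatch(
    stats::nls(y ~ Asym + (R0 - Asym) * exp(-exp(lrc) * x), data = df,
               start = list(Asym = cf[1], R0 = cf[1] + cf[2], lrc = log(k0)),
               control = stats::nls.control(maxiter = 500, scaleOffset = 1)),
    error = function(e) NULL)
}

# manual initialisation: asymptote from the high-LDMC tail, then a
# log-linearisation of y - a against x for the decay rate
decayFallbackFit <- function(df) {
  ord <- order(df$x)
  tail_n <- max(3L, ceiling(nrow(df) * 0.1))
  a0 <- mean(df$y[ord][seq(nrow(df) - tail_n + 1L, nrow(df))])
  pos <- df$y - a0 > 0
  if (sum(pos) < 3L) { a0 <- min(df$y) - 0.05 * diff(range(df$y)) - 1e-6; pos <- df$y - a0 > 0 }
  if (sum(pos) < 3L) return(NULL)
  ll <- stats::lm(log(df$y[pos] - a0) ~ df$x[pos])
  k0 <- max(1e-5, -unname(stats::coef(ll)[2]))
  b0 <- exp(unname(stats::coef(ll)[1]))
  tryCatch(
    stats::nls(y ~ Asym + (R0 - Asym) * exp(-exp(lrc) * x), data = df,
               start = list(Asym = a0, R0 = a0 + b0, lrc = log(k0)),
               control = stats::nls.control(maxiter = 500, scaleOffset = 1)),
    error = function(e) NULL)
}

#' @export
print.decay_transform <- function(x, ...) {
  cat("<decay_transform> exp(-k * LDMC), k =", format(x$k, digits = 6),
      "per mg/g\n")
  cat("  asymptote a =", format(x$a, digits = 4),
      " range b =", format(x$b, digits = 4),
      " RSS =", format(x$rss, digits = 4), " n =", x$n, "\n")
  invisible(x)
}

#' @export
predict.decay_transform <- function(object, ldmc, ...) {
  object$a + object$b * expDecay(ldmc, object$k)
}
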
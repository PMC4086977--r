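#' Fit a hierarchical productivity model
#'
#' Fits a linear mixed model of livestock productivity (LU ha^-1 yr^-1) on a
#' chosen set of fixed terms with nested random intercepts, via [nlme::lme]
#' (or [nlme::gls] when the random structure is `"none"`). Fixed terms are
#' drawn from a small vocabulary: `"expLDMC"` (the decay transform
#' `exp(-k * cwm_ldmc)`, with `k` frozen from [fitDecayTransform()]),
#' `"rain"`, `"rain2"` (squared growing-season rainfall), `"temp"`, or any
#' other numeric column of `records` (e.g. trait CWMs or functional-diversity
#' metrics).
#'
#' @param records Data frame with `productivity`, `experiment`, `block`,
#'   `plot`, `year`, weather columns `rain`/`temp`, `cwm_ldmc`, and any
#'   further covariates referenced in `fixed_terms`.
#' @param fixed_terms Character vector of fixed-effect terms (the intercept
#'   is always included; use `character(0)` for intercept-only).
#' @param random One of `"experiment/block/plot"`, `"experiment/plot"`,
#'   `"experiment"`, `"none"`.
#' @param mode `"REML"` (final estimation, random-structure comparison) or
#'   `"ML"` (fixed-structure comparison).
#' @param k Decay rate used by `"expLDMC"`; a number or a
#'   [decay_transform][fitDecayTransform].
#' @return An object of class `prod_model`: list with the `nlme` fit,
#'   `terms`, `random`, `mode`, `k`, `coefficients` (estimate, SE, df, t, p),
#'   `varcomp` (random-effect standard deviations incl. residual), `logLik`,
#'   `AIC`, `n_par`, `fitted`, `residuals` (observed minus innermost fitted),
#'   `data`, and flags `converged` / `boundary` (a variance estimated at the
#'   zero boundary is reported, not an error).
#' @export
fitProductivityModel <- function(records, fixed_terms, random = "experiment/plot",
                                 mode = c("REML", "ML"), k = NULL) {
  mode <- match.arg(mode)
  dat <- prepareModelFrame(records, fixed_terms, k)
  fixed <- fixedFormula(fixed_terms)
  fit <- fitNlme(fixed, dat, random, mode)
  if (is.null(fit$object))
    stop("mixed-model fit failed (random = ", random, "): ", fit$message)
  wrapProdModel(fit$object, fixed_terms, random, mode, dat,
                k = if (inherits(k, "decay_transform")) k$k else k)
}

# term vocabulary -> model-frame columns
prepareModelFrame <- function(records, fixed_terms, k = NULL) {
  dat <- as.data.frame(records)
  need <- c("productivity", "experiment", "plot")
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (is.null(dat$block)) dat$block <- dat$plot
  dat$experiment <- factor(dat$experiment)
  dat$block <- factor(paste(dat$experiment, dat$block, sep = "."))
  dat$plot_f <- factor(paste(dat$block, dat$plot, sep = "."))
  if ("expLDMC" %in% fixed_terms) {
    if (inherits(k, "decay_transform")) k <- k$k
    if (is.null(k)) stop("fixed term 'expLDMC' requires the decay rate k")
    if (is.null(dat$cwm_ldmc)) stop("records lack column 'cwm_ldmc'")
    dat$expLDMC <- expDecay(dat$cwm_ldmc, k)
    attr(dat, "k") <- k
  }
  if ("rain2" %in% fixed_terms) {
    if (is.null(dat$rain)) stop("records lack column 'rain'")
    dat$rain2 <- dat$rain^2
  }
  other <- setdiff(fixed_terms, c("expLDMC", "rain2"))
  miss <- setdiff(other, names(dat))
  if (length(miss)) stop("unknown fixed term(s): ", paste(miss, collapse = ", "))
  dat
}

fixedFormula <- function(fixed_terms, response = "productivity") {
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  stats::as.formula(paste(response, "~", rhs))
}

randomFormula <- function(random) {
  switch(random,
    "experiment/block/plot" = ~ 1 | experiment / block / plot_f,
    "experiment/plot" = ~ 1 | experiment / plot_f,
    "experiment" = ~ 1 | experiment,
    "none" = NULL,
    stop("unsupported random structure: ", random)
  )
}

fitNlme <- function(fixed, dat, random, mode) {
  rf <- randomFormula(random)
  if (is.null(rf)) {
    obj <- tryCatch(nlme::gls(fixed, data = dat, method = mode),
                    error = function(e) e)
    return(if (inherits(obj, "error"))
      list(object = NULL, message = conditionMessage(obj))
      else list(object = obj, message = ""))
  }
  msg <- ""
  for (opt in c("nlminb", "optim")) {
    ctl <- nlme::lmeControl(opt = opt, maxIter = 500, msMaxIter = 500,
                            niterEM = 50, returnObject = FALSE)
    obj <- tryCatch(
      nlme::lme(fixed, random = rf, data = dat, method = mode, control = ctl),
      error = function(e) e)
    if (!inherits(obj, "error")) return(list(object = obj, message = ""))
    msg <- conditionMessage(obj)
  }
  list(object = NULL, message = msg)
}

wrapProdModel <- function(fit, fixed_terms, random, mode, dat, k = NULL) {
  is_lme <- inherits(fit, "lme")
  sm <- summary(fit)
  if (is_lme) {
    tt <- sm$tTable
    coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                        se = tt[, "Std.Error"], df = tt[, "DF"],
                        t = tt[, "t-value"], p = tt[, "p-value"],
                        row.names = NULL)
    vc <- nlme::VarCorr(fit)
    sd_col <- suppressWarnings(as.numeric(vc[, "StdDev"]))
    names(sd_col) <- rownames(vc)
    varcomp <- sd_col[is.finite(sd_col)]
    fitted_in <- stats::fitted(fit, level = max(fit$dims$Q))
  } else {
    tt <- sm$tTable
    coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                        se = tt[, "Std.Error"],
                        df = fit$dims$N - fit$dims$p,
                        t = tt[, "t-value"], p = tt[, "p-value"],
                        row.names = NULL)
    varcomp <- c(Residual = fit$sigma)
    fitted_in <- stats::fitted(fit)
  }
  resid_sd <- unname(varcomp[length(varcomp)])
  boundary <- any(varcomp[-length(varcomp)] < 1e-5 * resid_sd)
  ll <- as.numeric(stats::logLik(fit))
  npar <- attr(stats::logLik(fit), "df")
  structure(
    list(fit = fit, terms = fixed_terms, random = random, mode = mode, k = k,
         coefficients = coefs, varcomp = varcomp,
         logLik = ll, AIC = -2 * ll + 2 * npar, n_par = npar,
         fitted = as.numeric(fitted_in),
         residuals = as.numeric(dat$productivity - fitted_in),
         data = dat, converged = TRUE, boundary = boundary),
    class = "prod_model"
  )
}

#' @export
print.prod_model <- function(x, ...) {
  cat("<prod_model> productivity ~ ",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
      "  [random: ", x$random, ", ", x$mode, "]\n", sep = "")
  cat("  logLik ", format(x$logLik, digits = 6), "  AIC ",
      format(x$AIC, digits = 6),
      if (x$boundary) "  (variance component at boundary)" else "", "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
logLik.prod_model <- function(object, ...) stats::logLik(object$fit)

#' @export
AIC.prod_model <- function(object, ...) object$AIC

#' @export
residuals.prod_model <- function(object, ...) object$residuals

#' Likelihood-ratio test between two nested fits
#'
#' Both fits must share the estimation mode (use ML for fixed-term
#' comparisons). Returns the chi-square statistic, its df (difference in
#' parameter counts) and the p-value.
#'
#' @param full,reduced `prod_model` objects, `reduced` nested in `full`.
#' @return List with `stat`, `df`, `p`.
#' @export
lrTest <- function(full, reduced) {
  if (full$mode != reduced$mode)
    stop("likelihood-ratio test requires a common estimation mode")
  stat <- 2 * (full$logLik - reduced$logLik)
  df <- full$n_par - reduced$n_par
  if (df <= 0) stop("'full' has no more parameters than 'reduced'")
  list(stat = stat, df = df, p = stats::pchisq(max(stat, 0), df, lower.tail = FALSE))
}
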
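#' Resilience test: do absolute residuals shrink with functional diversity?
#'
#' Operationalises resilience as reduced divergence of observed productivity
#' from the trait + weather expectation: the absolute values of the raw
#' residuals from the combined model are regressed on a functional-diversity
#' metric in a mixed model sharing the base fit's random structure. Because
#' the response is itself the output of a previous fit, the denominator
#' degrees of freedom of the slope's t test are revised downward by one
#' before computing the p-value, preventing an overly liberal test. A
#' negative, significant slope indicates that variability in productivity is
#' reduced at high functional diversity.
#'
#' @param base A `prod_model` for the combined trait + weather model.
#' @param predictor Name of the FD-metric column in the base model's data
#'   (e.g. `"rao_ldmc"`).
#' @param mode Estimation mode for the dispersion model (default `"REML"`).
#' @param squared Use squared instead of absolute residuals (sensitivity
#'   variant; default `FALSE`).
#' @return One-row data frame of class `resilience_result`: `predictor`,
#'   `intercept`, `slope`, `se`, `t`, `df_nominal`, `df_adjusted`
#'   (= nominal - 1), two-sided `p` at the adjusted df, one-sided
#'   `p_one_sided` for a negative slope, and `direction`.
#' @export
resilienceTest <- function(base, predictor, mode = c("REML", "ML"),
                           squared = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "prod_model"))
  dat <- base$data
  if (!predictor %in% names(dat)) stop("predictor column absent: ", predictor)
  v <- dat[[predictor]]
  if (!is.numeric(v)) stop("predictor must be numeric")
  dat$.absres <- if (squared) base$residuals^2 else abs(base$residuals)
  dat$.pred <- v
  ok <- is.finite(v)  # FEve rows undefined below 3 present species drop out
  if (!any(ok)) stop("predictor '", predictor, "' has no defined values")
  dat <- dat[ok, , drop = FALSE]
  if (stats::sd(dat$.pred) == 0) stop("constant predictor: ", predictor)
  fixed <- stats::as.formula(".absres ~ .pred")
  f <- fitNlme(fixed, dat, base$random, mode)
  if (is.null(f$object)) stop("resilience model failed to converge: ", f$message)
  disp <- wrapProdModel(f$object, ".pred", base$random, mode, dat)
  co <- disp$coefficients
  i_int <- match("(Intercept)", co$term)
  i_slp <- match(".pred", co$term)
  df_nom <- co$df[i_slp]
  df_adj <- df_nom - 1
  tval <- co$t[i_slp]
  p_adj <- 2 * stats::pt(-abs(tval), df_adj)
  p_one <- stats::pt(tval, df_adj)  # H1: slope < 0
  out <- data.frame(
    predictor = predictor,
    intercept = co$estimate[i_int],
    slope = co$estimate[i_slp],
    se = co$se[i_slp],
    t = tval,
    df_nominal = df_nom,
    df_adjusted = df_adj,
    p = p_adj,
    p_one_sided = p_one,
    direction = ifelse(co$estimate[i_slp] < 0, "negative", "positive")
  )
  class(out) <- c("resilience_result", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "squared") <- squared
  attr(out, "fit") <- disp
  out
}

#' Resilience tests over a predictor set
#'
#' Runs [resilienceTest()] for each predictor and binds the one-row results,
#' optionally adding a Holm-corrected p column across the set (raw p-values
#' remain primary).
#'
#' @inheritParams resilienceTest
#' @param predictors Character vector of FD-metric columns (default the four
#'   metrics `feve_all`, `rao_all`, `feve_ldmc`, `rao_ldmc`).
#' @param holm Add a Holm-adjusted column `p_holm`? Default `FALSE`.
#' @return Data frame, one row per predictor, as in [resilienceTest()].
#' @export
resilienceTable <- function(base, predictors = c("feve_all", "rao_all",
                                                 "feve_ldmc", "rao_ldmc"),
                            mode = "REML", holm = FALSE, squared = FALSE) {
  rows <- lapply(predictors, function(pr)
    resilienceTest(base, pr, mode = mode, squared = squared))
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  class(out) <- c("resilience_result", "data.frame")
  out
}

#' Long-term mean productivity vs mean functional diversity
#'
#' Tests whether long-term grazing patterns leave a signature in functional
#' diversity: plot-level multi-year means of an FD metric are regressed on
#' plot-level mean productivity in a mixed model with experiment random
#' intercepts.
#'
#' @param records Data frame with `experiment`, `plot`, `year`,
#'   `productivity` and the FD metric column.
#' @param fd_metric Name of the FD metric column.
#' @return One-row data frame of class `mean_level_result`: `fd_metric`,
#'   `intercept`, `slope`, `se`, `df`, `t`, `p`, `n_plots`.
#' @export
meanLevelRegression <- function(records, fd_metric) {
  need <- c("experiment", "plot", "year", "productivity", fd_metric)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  key <- paste(records$experiment,
               if (!is.null(records$block)) records$block else "", records$plot,
               sep = ".")
  agg <- stats::aggregate(
    cbind(mean_prod = records$productivity, mean_fd = records[[fd_metric]]),
    by = list(key = key, experiment = records$experiment),
    FUN = function(x) mean(x, na.rm = TRUE))
  if (nrow(agg) < 2L) stop("need at least 2 plots for the mean-level regression")
  if (stats::sd(agg$mean_fd) == 0) stop("FD metric '", fd_metric, "' is constant across plots")
  agg$experiment <- factor(agg$experiment)
  fit <- tryCatch(
    nlme::lme(mean_fd ~ mean_prod, random = ~ 1 | experiment, data = agg,
              method = "REML",
              control = nlme::lmeControl(opt = "optim", returnObject = TRUE)),
    error = function(e) stop("mean-level regression failed: ", conditionMessage(e)))
  tt <- summary(fit)$tTable
  out <- data.frame(
    fd_metric = fd_metric,
    intercept = tt["(Intercept)", "Value"],
    slope = tt["mean_prod", "Value"],
    se = tt["mean_prod", "Std.Error"],
    df = tt["mean_prod", "DF"],
    t = tt["mean_prod", "t-value"],
    p = tt["mean_prod", "p-value"],
    n_plots = nrow(agg)
  )
  class(out) <- c("mean_level_result", "data.frame")
  out
}
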
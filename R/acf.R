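#' Within-plot lag-1 autocorrelation of model residuals
#'
#' Checks the final productivity model for temporal autocorrelation: raw
#' residuals are ordered by year within each plot, lag-1 products are pooled
#' across plots (only consecutive years form pairs), and the empirical
#' correlation `r1 = mean(e_t * e_{t+1}) / mean(e^2)` is compared with the
#' approximate white-noise bound `1.96 / sqrt(n_pairs)`.
#'
#' @param model A `prod_model`, or `NULL` if `residuals` and `keys` are given.
#' @param residuals Optional numeric vector of residuals (one per plot-year).
#' @param keys Optional data frame with `experiment`, `plot`, `year` aligned
#'   with `residuals`; defaults to the model's data.
#' @return List of class `acf_check`: `r1`, `n_pairs`, `bound`,
#'   `significant`, `defined`. When no plot has 3 or more years, or the
#'   residuals have zero variance, `defined` is `FALSE` and `significant`
#'   is `NA`.
#' @export
checkTemporalACF <- function(model = NULL, residuals = NULL, keys = NULL) {
  if (!is.null(model)) {
    stopifnot(inherits(model, "prod_model"))
    if (is.null(residuals)) residuals <- model$residuals
    if (is.null(keys)) keys <- model$data
  }
  need <- c("experiment", "plot", "year")
  if (is.null(keys) || !all(need %in% names(keys)))
    stop("keys must provide experiment, plot, year")
  grp <- paste(keys$experiment, if (!is.null(keys$block)) keys$block else "",
               keys$plot, sep = ".")
  num <- 0; n_pairs <- 0L; max_years <- 0L
  for (g in unique(grp)) {
    i <- which(grp == g)
    i <- i[order(keys$year[i])]
    max_years <- max(max_years, length(i))
    if (length(i) < 2L) next
    consec <- which(diff(keys$year[i]) == 1L)
    if (!length(consec)) next
    e <- residuals[i]
    num <- num + sum(e[consec] * e[consec + 1L])
    n_pairs <- n_pairs + length(consec)
  }
  denom <- mean(residuals^2)
  if (max_years < 3L || n_pairs < 2L || stats::var(residuals) == 0) {
    return(structure(list(r1 = NA_real_, n_pairs = n_pairs, bound = NA_real_,
                          significant = NA, defined = FALSE),
                     class = "acf_check"))
  }
  r1 <- (num / n_pairs) / denom
  bound <- 1.96 / sqrt(n_pairs)
  structure(list(r1 = r1, n_pairs = n_pairs, bound = bound,
                 significant = abs(r1) > bound, defined = TRUE),
            class = "acf_check")
}

#' @export
print.acf_check <- function(x, ...) {
  if (!x$defined) {
    cat("<acf_check> undefined (insufficient years or zero residual variance)\n")
  } else {
    cat("<acf_check> lag-1 r =", format(x$r1, digits = 4),
        "on", x$n_pairs, "pairs; bound", format(x$bound, digits = 4),
        if (x$significant) "-> significant autocorrelation\n"
        else "-> no significant autocorrelation\n")
  }
  invisible(x)
}
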
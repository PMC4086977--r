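#' Join functional-composition profiles onto plot-year records
#'
#' Merges an [fd_profile][fdProfile] onto the record table by the
#' experiment/block/plot/year keys. Every record row must find exactly one
#' profile row.
#'
#' @param records Plot-year record data frame.
#' @param profile An [fd_profile][fdProfile].
#' @return The records with CWM and FD-metric columns appended.
#' @export
joinProfile <- function(records, profile) {
  keys <- c("experiment", "block", "plot", "year")
  miss <- setdiff(keys, names(records))
  if (length(miss)) stop("records lack key column(s): ", paste(miss, collapse = ", "))
  id_r <- plotYearId(records)
  id_p <- plotYearId(profile)
  idx <- match(id_r, id_p)
  if (anyNA(idx))
    stop("no profile row for record(s): ",
         paste(utils::head(id_r[is.na(idx)], 5), collapse = ", "))
  add <- setdiff(names(profile), keys)
  cbind(records, profile[idx, add, drop = FALSE], row.names = NULL)
}

#' Run the full trait-productivity-resilience analysis
#'
#' Orchestrates the whole pipeline in its canonical order on a trait table,
#' community matrix and plot-year record table (or a
#' [synthetic_dataset][simulateGrazingData]):
#' \enumerate{
#'   \item functional-composition profiles (CWM, Rao's Q, FEve) joined to the
#'     records;
#'   \item the exponential-decay LDMC transform estimated by nonlinear least
#'     squares and frozen;
#'   \item REML simplification of the random structure under the full fixed
#'     model (`expLDMC + rain + rain2 + temp`);
#'   \item ML backward elimination of fixed terms, final REML refit — the
#'     combined trait + weather baseline;
#'   \item within-plot lag-1 autocorrelation check of the baseline residuals;
#'   \item forward selection of the four FD metrics on mean productivity
#'     (does functional diversity explain the level of production?);
#'   \item plot-level mean-productivity vs mean-FD regressions;
#'   \item absolute-residual resilience tests with the downward-adjusted df
#'     (does functional diversity explain the variability of production?).
#' }
#' Any stage failure is re-thrown with a stage label. The analysis itself is
#' deterministic: rerunning on the same inputs reproduces every number.
#'
#' @param traits A [trait_table][buildTraitTable], or a `synthetic_dataset`
#'   (in which case the other data arguments are taken from it).
#' @param community A [community_matrix][communityMatrix].
#' @param records Plot-year record data frame (`experiment`, `block`, `plot`,
#'   `year`, `productivity`, `rain`, `temp`).
#' @param alpha Significance level for term addition/removal (default 0.05).
#' @param start_terms Fixed terms of the full model before simplification.
#' @param fd_candidates FD metric columns tested in forward selection and the
#'   resilience analysis.
#' @param holm Add Holm-adjusted p-values to the resilience table?
#' @return List of class `grazefd_analysis` with elements `profile`,
#'   `records` (joined), `transform`, `random_selection`, `fixed_selection`,
#'   `base_model`, `acf`, `h1_forward`, `mean_level`, `h2_resilience`, and
#'   `summary` (a plain list ready for JSON serialisation).
#' @export
runFullAnalysis <- function(traits, community = NULL, records = NULL,
                            alpha = 0.05,
                            start_terms = c("expLDMC", "rain", "rain2", "temp"),
                            fd_candidates = c("feve_all", "rao_all",
                                              "feve_ldmc", "rao_ldmc"),
                            holm = FALSE) {
  if (inherits(traits, "synthetic_dataset")) {
    community <- traits$community
    records <- traits$records
    traits <- traits$traits
  }
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage: ", label, "] ", conditionMessage(e), call. = FALSE))
  }

  profile <- stage("fd-metrics", fdProfile(community, traits))
  rec <- stage("join", joinProfile(records, profile))

  transform <- stage("decay-transform", fitDecayTransform(rec))

  rnd <- stage("random-simplification",
               simplifyRandom(rec, start_terms, k = transform))
  fx <- stage("fixed-simplification",
              simplifyFixed(rec, start_terms, random = rnd$selected,
                            k = transform, alpha = alpha))
  base <- fx$final

  acf_chk <- stage("acf-check", checkTemporalACF(base))

  h1 <- stage("h1-forward-selection",
              forwardSelectFD(base$data, base, candidates = fd_candidates,
                              alpha = alpha))
  mean_level <- stage("mean-level-regressions", {
    do.call(rbind, lapply(fd_candidates, function(m) meanLevelRegression(rec, m)))
  })
  h2 <- stage("h2-resilience",
              resilienceTable(base, predictors = fd_candidates, holm = holm))

  smry <- list(
    n_records = nrow(rec),
    n_experiments = length(unique(rec$experiment)),
    n_species = nrow(traits$values),
    k = transform$k,
    random_selected = rnd$selected,
    fixed_terms = fx$terms,
    coefficients = stats::setNames(base$coefficients$estimate,
                                   base$coefficients$term),
    coefficient_p = stats::setNames(base$coefficients$p,
                                    base$coefficients$term),
    varcomp = as.list(base$varcomp),
    AIC = base$AIC,
    acf_r1 = acf_chk$r1,
    acf_significant = acf_chk$significant,
    h1_any_significant = isTRUE(attr(h1, "any_significant")),
    h1_p = stats::setNames(h1$p, h1$candidate),
    mean_level_slope = stats::setNames(mean_level$slope, mean_level$fd_metric),
    mean_level_p = stats::setNames(mean_level$p, mean_level$fd_metric),
    h2_slope = stats::setNames(h2$slope, h2$predictor),
    h2_p = stats::setNames(h2$p, h2$predictor),
    h2_df_adjusted = stats::setNames(h2$df_adjusted, h2$predictor)
  )

  structure(list(profile = profile, records = rec, transform = transform,
                 random_selection = rnd, fixed_selection = fx,
                 base_model = base, acf = acf_chk, h1_forward = h1,
                 mean_level = mean_level, h2_resilience = h2,
                 summary = smry),
            class = "grazefd_analysis")
}

#' @export
print.grazefd_analysis <- function(x, ...) {
  s <- x$summary
  cat("<grazefd_analysis> ", s$n_records, " plot-years, ",
      s$n_experiments, " experiments\n", sep = "")
  cat("  decay rate k =", format(s$k, digits = 4),
      "| random:", s$random_selected,
      "| fixed:", paste(s$fixed_terms, collapse = " + "), "\n")
  cat("  H1 (FD explains mean productivity): ",
      if (s$h1_any_significant) "some FD term adds power"
      else "no FD term adds power", "\n", sep = "")
  sig <- x$h2_resilience$p < 0.05
  cat("  H2 (FD explains variability): ",
      if (any(sig)) paste0("significant for ",
        paste(x$h2_resilience$predictor[sig], collapse = ", "))
      else "no significant predictor", "\n", sep = "")
  invisible(x)
}
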
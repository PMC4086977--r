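#' Simplify the random-effects structure
#'
#' Compares a ladder of nested random-intercept structures under REML, all
#' with the same (full) fixed model, and returns the AIC-minimal structure.
#' Candidates are ordered simplest first and ties in AIC go to the simpler
#' structure. Candidates that fail to converge are dropped with a note; if
#' every candidate fails the call errors.
#'
#' @inheritParams fitProductivityModel
#' @param candidates Character vector of random structures, simplest first.
#' @return List of class `random_selection`: `selected` (structure name),
#'   `table` (candidate, n_par, logLik, AIC, converged) and `fit` (the REML
#'   fit under the selected structure).
#' @export
simplifyRandom <- function(records, fixed_terms, k = NULL,
                           candidates = c("none", "experiment",
                                          "experiment/plot",
                                          "experiment/block/plot")) {
  dat <- prepareModelFrame(records, fixed_terms, k)
  fixed <- fixedFormula(fixed_terms)
  rows <- lapply(candidates, function(cand) {
    f <- fitNlme(fixed, dat, cand, "REML")
    if (is.null(f$object))
      return(data.frame(candidate = cand, n_par = NA, logLik = NA_real_,
                        AIC = NA_real_, converged = FALSE))
    ll <- stats::logLik(f$object)
    data.frame(candidate = cand, n_par = attr(ll, "df"),
               logLik = as.numeric(ll),
               AIC = -2 * as.numeric(ll) + 2 * attr(ll, "df"),
               converged = TRUE)
  })
  tab <- do.call(rbind, rows)
  if (!any(tab$converged)) stop("no random-structure candidate converged")
  ok <- which(tab$converged)
  best <- ok[which.min(tab$AIC[ok])]  # candidates ordered simple->complex: ties go simple
  sel <- tab$candidate[best]
  fit <- fitProductivityModel(records, fixed_terms, random = sel,
                              mode = "REML", k = k)
  structure(list(selected = sel, table = tab, fit = fit),
            class = "random_selection")
}

#' @export
print.random_selection <- function(x, ...) {
  cat("<random_selection> selected:", x$selected, "\n")
  print(x$table, digits = 6)
  invisible(x)
}

#' Backward elimination of fixed terms
#'
#' Simplifies the fixed model by progressive removal of terms under maximum
#' likelihood: at each step every single-term deletion is evaluated by a
#' likelihood-ratio test against the current model; among the terms whose
#' removal is non-significant at `alpha`, the deletion giving the lowest AIC
#' is applied. Marginality is respected (`rain` is not removable while
#' `rain2` is in the model). Elimination stops when every remaining term is
#' significant, and the final model is refitted by REML.
#'
#' @inheritParams fitProductivityModel
#' @param start_terms Fixed terms of the full model.
#' @param alpha Significance level of the LRT gate (default 0.05).
#' @return List of class `fixed_selection`: `final` (REML `prod_model`),
#'   `terms`, and `ladder` — one row per evaluated deletion (step, term,
#'   logLik, AIC of the reduced model, LRT stat and p, dropped flag).
#' @export
simplifyFixed <- function(records, start_terms, random = "experiment/plot",
                          k = NULL, alpha = 0.05) {
  terms <- start_terms
  current <- fitProductivityModel(records, terms, random, mode = "ML", k = k)
  ladder <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    droppable <- setdiff(terms, protectedTerms(terms))
    if (!length(droppable)) break
    cand <- lapply(droppable, function(tm) {
      red <- tryCatch(
        fitProductivityModel(records, setdiff(terms, tm), random, "ML", k = k),
        error = function(e) NULL)
      if (is.null(red)) return(NULL)
      lrt <- lrTest(current, red)
      data.frame(step = step, term = tm, logLik = red$logLik, AIC = red$AIC,
                 lrt_stat = lrt$stat, p = lrt$p, dropped = FALSE)
    })
    cand <- do.call(rbind, cand)
    if (is.null(cand) || !nrow(cand)) break
    admissible <- which(cand$p > alpha)
    if (!length(admissible)) { ladder[[step]] <- cand; break }
    pick <- admissible[which.min(cand$AIC[admissible])]
    cand$dropped[pick] <- TRUE
    ladder[[step]] <- cand
    terms <- setdiff(terms, cand$term[pick])
    current <- fitProductivityModel(records, terms, random, "ML", k = k)
  }
  final <- fitProductivityModel(records, terms, random, mode = "REML", k = k)
  structure(list(final = final, terms = terms,
                 ladder = if (length(ladder)) do.call(rbind, ladder)
                          else data.frame()),
            class = "fixed_selection")
}

# marginality: a main effect stays while its square is in the model
protectedTerms <- function(terms) {
  prot <- character(0)
  if ("rain2" %in% terms) prot <- c(prot, "rain")
  prot
}

#' @export
print.fixed_selection <- function(x, ...) {
  cat("<fixed_selection> final terms:",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)",
      "\n")
  if (nrow(x$ladder)) print(x$ladder, digits = 5)
  invisible(x)
}

#' Forward selection of functional-diversity terms
#'
#' Tests whether any functional-diversity metric adds explanatory power to
#' the combined trait + weather productivity model. Each candidate column is
#' added singly to the base fixed model and assessed by a maximum-likelihood
#' likelihood-ratio test (1 df) and the change in AIC. A candidate that is
#' (nearly) collinear with the existing covariates is refused with a warning
#' and reported as such rather than tested.
#'
#' @param records Data frame holding the base-model covariates and the
#'   candidate columns.
#' @param base A `prod_model` for the combined trait + weather model (any
#'   mode; it is refitted by ML internally).
#' @param candidates Character vector of candidate column names
#'   (default the four FD metrics `feve_all`, `rao_all`, `feve_ldmc`,
#'   `rao_ldmc`).
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `fd_selection`, one row per candidate:
#'   `candidate`, `estimate` (ML slope), `dAIC` (candidate AIC minus base
#'   AIC; negative = improvement), `lrt_stat`, `p`, `significant`,
#'   `collinear`. Attribute `any_significant` summarises the test.
#' @export
forwardSelectFD <- function(records, base,
                            candidates = c("feve_all", "rao_all",
                                           "feve_ldmc", "rao_ldmc"),
                            alpha = 0.05) {
  stopifnot(inherits(base, "prod_model"))
  base_ml <- if (base$mode == "ML") base else
    fitProductivityModel(records, base$terms, base$random, "ML", k = base$k)
  miss <- setdiff(candidates, names(records))
  if (length(miss)) stop("candidate column(s) absent: ", paste(miss, collapse = ", "))
  rows <- lapply(candidates, function(cl) {
    v <- records[[cl]]
    ok <- is.finite(v)
    # FEve is undefined below 3 present species; such rows are dropped for
    # this candidate and the base refitted on the same subset so the
    # likelihood-ratio comparison stays nested
    rec_c <- records[ok, , drop = FALSE]
    base_c <- if (all(ok)) base_ml else
      fitProductivityModel(rec_c, base_ml$terms, base_ml$random, "ML",
                           k = base_ml$k)
    X <- stats::model.matrix(fixedFormula(base_c$terms), data = base_c$data)
    v <- v[ok]
    if (stats::sd(v) == 0 || collinearWithBase(v, X)) {
      warning("candidate '", cl, "' is collinear with the base model; not tested")
      return(data.frame(candidate = cl, estimate = NA_real_, dAIC = NA_real_,
                        lrt_stat = NA_real_, p = NA_real_,
                        significant = NA, collinear = TRUE))
    }
    ext <- fitProductivityModel(rec_c, c(base_c$terms, cl), base_c$random,
                                "ML", k = base_c$k)
    lrt <- lrTest(ext, base_c)
    est <- ext$coefficients$estimate[ext$coefficients$term == cl]
    data.frame(candidate = cl, estimate = est, dAIC = ext$AIC - base_ml$AIC,
               lrt_stat = lrt$stat, p = lrt$p,
               significant = lrt$p < alpha, collinear = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fd_selection", "data.frame")
  attr(out, "any_significant") <- any(out$significant, na.rm = TRUE)
  attr(out, "alpha") <- alpha
  out
}

collinearWithBase <- function(v, X, tol = 1e-8) {
  fit <- stats::lm.fit(X, v)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((v - mean(v))^2)
  ss_tot == 0 || ss_res / ss_tot < tol
}
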
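#' Construct a community (relative abundance) matrix
#'
#' Rows are plot-year observations, columns are species, entries are relative
#' abundances. Each row must sum to 1 (point-quadrat pin proportions or any
#' other relative-abundance estimate); abundances must be nonnegative.
#'
#' @param abund Numeric matrix (plot-years x species) with species ids as
#'   column names.
#' @param keys Data frame with one row per abundance row carrying the
#'   `experiment`, `block`, `plot`, `year` identifiers.
#' @param tol Tolerance on the row-sum check (default `1e-9`).
#' @param normalise If `TRUE`, rows that do not sum to 1 are renormalised
#'   with a warning instead of erroring.
#' @return An object of class `community_matrix`: list with `abund` and `keys`.
#' @export
communityMatrix <- function(abund, keys, tol = 1e-9, normalise = FALSE) {
  abund <- as.matrix(abund)
  if (is.null(colnames(abund))) stop("abundance matrix needs species column names")
  if (!is.data.frame(keys) || nrow(keys) != nrow(abund))
    stop("keys must be a data frame with one row per community row")
  need <- c("experiment", "block", "plot", "year")
  miss <- setdiff(need, names(keys))
  if (length(miss)) stop("keys lack column(s): ", paste(miss, collapse = ", "))
  if (any(abund < 0)) stop("negative abundances")
  rs <- rowSums(abund)
  off <- which(abs(rs - 1) > tol)
  if (length(off)) {
    if (normalise) {
      if (any(rs[off] <= 0)) stop("row(s) with zero total abundance cannot be normalised")
      warning(length(off), " row(s) did not sum to 1; renormalised")
      abund[off, ] <- abund[off, , drop = FALSE] / rs[off]
    } else {
      stop(length(off), " row(s) do not sum to 1 within ", tol,
           " (first offending row sum: ", format(rs[off[1]], digits = 10), ")")
    }
  }
  rownames(abund) <- plotYearId(keys)
  structure(list(abund = abund, keys = as.data.frame(keys)),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("<community_matrix> ", nrow(x$abund), " plot-year rows x ",
      ncol(x$abund), " species\n", sep = "")
  cat("  experiments:", length(unique(x$keys$experiment)),
      " plots:", nrow(unique(x$keys[c("experiment", "plot")])), "\n")
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$abund)

# canonical plot-year row identifier shared by communities, profiles, records
plotYearId <- function(keys) {
  paste(keys$experiment, keys$block, keys$plot, keys$year, sep = ".")
}
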
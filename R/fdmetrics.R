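#' Weighted Gower dissimilarity on mixed trait types
#'
#' Species x species dissimilarity over a (possibly weighted) trait subset:
#' `d_ij = sum_k w_k |x_ik - x_jk| / range_k / sum_k w_k`, where `range_k` is
#' the trait's range over the *full species pool* so that distances are
#' comparable across plot-years. Coded traits already lie in `[0, 1]`;
#' month-scale traits are rescaled first (see [traitDistanceValues()]).
#' Traits with zero range over the pool carry no information: they contribute
#' 0 and are dropped from the weight normalisation, with a record of which
#' were dropped; if every requested trait is constant the call errors.
#'
#' @param traits A [trait_table][buildTraitTable].
#' @param subset Character vector of trait names (default: all traits).
#' @param weights Named per-trait weights; defaults to the scheme weights.
#' @return A symmetric species x species matrix of class `gower_dist`, values
#'   in `[0, 1]`, with attributes `traits`, `weights` and `constant_traits`.
#' @export
gowerDist <- function(traits, subset = NULL, weights = NULL) {
  stopifnot(inherits(traits, "trait_table"))
  m <- traitDistanceValues(traits, subset)
  if (ncol(m) == 0L) stop("empty trait subset")
  if (is.null(weights)) {
    weights <- traits$weights[colnames(m)]
  } else {
    if (is.null(names(weights))) {
      if (length(weights) != ncol(m)) stop("unnamed weights must match subset length")
      names(weights) <- colnames(m)
    }
    miss <- setdiff(colnames(m), names(weights))
    if (length(miss)) stop("weights missing for trait(s): ", paste(miss, collapse = ", "))
    weights <- weights[colnames(m)]
  }
  if (any(weights <= 0)) stop("trait weights must be positive")

  rng <- apply(m, 2L, function(v) diff(range(v)))
  constant <- colnames(m)[rng == 0]
  keep <- rng > 0
  if (!any(keep)) stop("zero trait variation: all requested traits are constant over the pool")
  m <- m[, keep, drop = FALSE]
  w <- weights[keep]
  rng <- rng[keep]

  S <- nrow(m)
  d <- matrix(0, S, S, dimnames = list(rownames(m), rownames(m)))
  for (k in seq_len(ncol(m))) {
    d <- d + w[k] * abs(outer(m[, k], m[, k], "-")) / rng[k]
  }
  d <- d / sum(w)
  structure(d, class = c("gower_dist", "matrix"),
            traits = colnames(m), weights = w, constant_traits = constant)
}

#' Community-weighted mean of a trait
#'
#' Abundance-weighted average `sum_i p_i x_i` of a trait over the species
#' present in one community row. Log-transformed traits are averaged on their
#' stored (log) scale; month traits on the raw month scale.
#'
#' @param p Relative-abundance vector, named by species or aligned with the
#'   trait table's species order; must sum to 1.
#' @param traits A [trait_table][buildTraitTable].
#' @param trait Trait name.
#' @return The community-weighted mean (scalar).
#' @export
cwm <- function(p, traits, trait) {
  stopifnot(inherits(traits, "trait_table"))
  if (!trait %in% colnames(traits$values)) stop("unknown trait: ", trait)
  x <- traits$values[, trait]
  p <- alignAbundance(p, names(x))
  sum(p * x)
}

#' Rao's quadratic entropy
#'
#' `Q = sum_i sum_j p_i p_j d_ij` over ordered species pairs (`d_ii = 0`),
#' i.e. the expected dissimilarity between two individuals drawn at random
#' with replacement from the community. Equivalently `2 * sum_{i<j} p_i p_j
#' d_ij`. Computed as the quadratic form `p' D p`.
#'
#' @param p Relative-abundance vector (named or aligned with `d`); sums to 1.
#' @param d Species x species dissimilarity matrix (e.g. from [gowerDist()]).
#' @return Rao's Q (scalar, `>= 0` for nonnegative `d`).
#' @export
raoQ <- function(p, d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  p <- alignAbundance(p, rownames(d))
  if (length(p) != nrow(d)) stop("abundance length does not match distance matrix")
  as.numeric(p %*% d %*% p)
}

#' Functional evenness (FEve)
#'
#' Regularity of the abundance distribution along the minimum spanning tree
#' (MST) of the species present in trait space. For each MST branch joining
#' species i and j, the branch's weighted evenness is
#' `EW_l = d_ij / (p_i + p_j)`; with `PEW_l = EW_l / sum(EW)` and `S` present
#' species,
#' `FEve = (sum_l min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`.
#' FEve is bounded in `[0, 1]` and equals 1 when abundance is perfectly even
#' along the tree. It is undefined for fewer than 3 present species: the
#' return value is then `NA` with attribute `defined = FALSE`.
#'
#' Species with zero abundance are excluded before MST construction. Ties
#' between equal-length candidate edges are resolved deterministically in
#' lexicographic species-pair order.
#'
#' @inheritParams raoQ
#' @return FEve in `[0, 1]`, or `NA` (attribute `defined = FALSE`) when fewer
#'   than 3 species are present.
#' @export
feve <- function(p, d) {
  d <- as.matrix(d)
  p <- alignAbundance(p, rownames(d))
  present <- which(p > 0)
  S <- length(present)
  if (S < 3L) return(structure(NA_real_, defined = FALSE, n_present = S))
  dp <- d[present, present, drop = FALSE]
  pp <- p[present]
  edges <- mstEdges(dp)
  ew <- edges$d / (pp[edges$i] + pp[edges$j])
  if (sum(ew) == 0) {
    # all present species functionally identical: no tree length to spread
    return(structure(NA_real_, defined = FALSE, n_present = S))
  }
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  val <- (sum(pmin(pew, thr)) - thr) / (1 - thr)
  structure(val, defined = TRUE, n_present = S)
}

# Minimum spanning tree by Kruskal's algorithm with deterministic tie-break:
# candidate edges sorted by (length, i, j) in lexicographic order.
# Returns a data.frame of S-1 edges with local indices i < j and length d.
mstEdges <- function(d) {
  S <- nrow(d)
  if (S < 2L) stop("MST needs at least 2 nodes")
  ij <- which(upper.tri(d), arr.ind = TRUE)
  len <- d[ij]
  ord <- order(len, ij[, 1L], ij[, 2L])
  parent <- seq_len(S)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  ei <- integer(S - 1L); ej <- integer(S - 1L); ed <- numeric(S - 1L)
  n <- 0L
  for (e in ord) {
    a <- find(ij[e, 1L]); b <- find(ij[e, 2L])
    if (a != b) {
      parent[a] <- b
      n <- n + 1L
      ei[n] <- ij[e, 1L]; ej[n] <- ij[e, 2L]; ed[n] <- len[e]
      if (n == S - 1L) break
    }
  }
  data.frame(i = ei, j = ej, d = ed)
}

# align an abundance vector with a species order; error on mismatch.
# distance matrices without dimnames use positional alignment.
alignAbundance <- function(p, species) {
  if (is.null(species)) {
    if (!is.null(names(p)))
      stop("named abundances need a distance matrix with species names")
    return(as.numeric(p))
  }
  if (!is.null(names(p))) {
    miss <- setdiff(names(p), species)
    if (length(miss))
      stop("abundance names not in species pool: ", paste(miss, collapse = ", "))
    full <- stats::setNames(numeric(length(species)), species)
    full[names(p)] <- p
    return(full)
  }
  if (length(p) != length(species))
    stop("unnamed abundance vector must match species pool length (",
         length(p), " vs ", length(species), ")")
  stats::setNames(as.numeric(p), species)
}

#' Per-plot-year functional composition profile
#'
#' Computes, for every row of a community matrix: the community-weighted mean
#' of each trait; Rao's Q and FEve over the full trait suite (weighted Gower
#' distances); and Rao's Q and FEve for each named single trait (by default
#' the two leaf traits SLA and LDMC). Single-trait metrics use a one-trait
#' Gower distance, i.e. range-normalised absolute differences (in 1-D the MST
#' is the chain through species sorted by trait value); for transparency the
#' single-trait Rao is also reported in raw trait units
#' (`rao_<trait>_raw = rao_<trait> * pool range`).
#'
#' @param community A [community_matrix][communityMatrix].
#' @param traits A [trait_table][buildTraitTable]; must cover every species
#'   column of the community.
#' @param single_traits Traits to profile individually
#'   (default `c("sla", "ldmc")`, intersected with the table's traits).
#' @return A data frame of class `fd_profile`, one row per plot-year: key
#'   columns, `n_present`, `cwm_<trait>` for every trait, `rao_all`,
#'   `feve_all`, and `rao_<t>`, `feve_<t>`, `rao_<t>_raw` for each single
#'   trait. FEve values are `NA` where fewer than 3 species are present.
#' @export
fdProfile <- function(community, traits, single_traits = c("sla", "ldmc")) {
  stopifnot(inherits(community, "community_matrix"), inherits(traits, "trait_table"))
  sp_comm <- colnames(community$abund)
  sp_pool <- traitSpecies(traits)
  extra <- setdiff(sp_comm, sp_pool)
  if (length(extra))
    stop("community species missing from trait table: ", paste(extra, collapse = ", "))
  single_traits <- intersect(single_traits, colnames(traits$values))

  d_all <- gowerDist(traits)
  d_one <- lapply(single_traits, function(tr) gowerDist(traits, subset = tr))
  names(d_one) <- single_traits
  rng_one <- vapply(single_traits, function(tr) {
    diff(range(traitDistanceValues(traits, tr)))
  }, numeric(1))

  n <- nrow(community$abund)
  out <- community$keys
  out$n_present <- apply(community$abund, 1L, function(p) sum(p > 0))
  for (tr in colnames(traits$values)) {
    out[[paste0("cwm_", tr)]] <- apply(community$abund, 1L, cwm,
                                       traits = traits, trait = tr)
  }
  out$rao_all <- NA_real_; out$feve_all <- NA_real_
  for (tr in single_traits) {
    out[[paste0("rao_", tr)]] <- NA_real_
    out[[paste0("feve_", tr)]] <- NA_real_
    out[[paste0("rao_", tr, "_raw")]] <- NA_real_
  }
  for (r in seq_len(n)) {
    p <- stats::setNames(community$abund[r, ], sp_comm)
    out$rao_all[r] <- raoQ(p, d_all)
    out$feve_all[r] <- as.numeric(feve(p, d_all))
    for (tr in single_traits) {
      q1 <- raoQ(p, d_one[[tr]])
      out[[paste0("rao_", tr)]][r] <- q1
      out[[paste0("feve_", tr)]][r] <- as.numeric(feve(p, d_one[[tr]]))
      out[[paste0("rao_", tr, "_raw")]][r] <- q1 * rng_one[[tr]]
    }
  }
  class(out) <- c("fd_profile", "data.frame")
  out
}
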
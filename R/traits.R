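#' Define a trait coding scheme
#'
#' A trait scheme declares how raw database entries for one trait are turned
#' into the numeric value used by the functional-composition metrics: the kind
#' of trait (continuous, ordinal-coded or binary-coded), the label-to-number
#' coding map for coded traits, whether a log transform is applied, and the
#' weight the trait carries in multi-trait Gower distances.
#'
#' @param trait_name Identifier of the trait (e.g. `"ldmc"`).
#' @param kind One of `"continuous"`, `"ordinal-coded"`, `"binary-coded"`.
#' @param coding_map Named numeric vector mapping category labels to codes.
#'   Required for coded kinds; codes must lie in `[0, 1]` except for
#'   month-valued traits (see `month_scale`).
#' @param log_transform Logical; apply a natural log to entry values before
#'   averaging? Only meaningful for continuous traits with positive values.
#' @param weight Positive weight of the trait in multi-trait distances.
#'   Defaults to 1; the two vegetative-spread attributes (rhizome, stolon)
#'   conventionally get 0.5 each so they jointly weigh 1.
#' @param month_scale Logical; `TRUE` for traits measured as a calendar month
#'   (1--12), e.g. start of flowering. Month traits are kept on the raw month
#'   scale in the trait table and rescaled to `[0, 1]` by `(m - 1)/11` when
#'   entering multi-trait distances.
#' @param unit Optional unit string, recorded as metadata.
#'
#' @return An object of class `trait_scheme`.
#' @seealso [defaultTraitSchemes()] for the standard grassland response-trait
#'   suite, [codeTrait()], [buildTraitTable()].
#' @export
traitScheme <- function(trait_name, kind = c("continuous", "ordinal-coded", "binary-coded"),
                        coding_map = NULL, log_transform = FALSE, weight = 1,
                        month_scale = FALSE, unit = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(is.character(trait_name), length(trait_name) == 1L, nzchar(trait_name))
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) || weight <= 0)
    stop("trait '", trait_name, "': weight must be a positive number")
  if (kind != "continuous") {
    if (is.null(coding_map) || is.null(names(coding_map)))
      stop("trait '", trait_name, "': coded kinds require a named coding_map")
    lo <- 0; hi <- if (month_scale) 12 else 1
    if (any(coding_map < lo | coding_map > hi))
      stop("trait '", trait_name, "': coded values must lie in [", lo, ", ", hi, "]")
    if (log_transform)
      stop("trait '", trait_name, "': log transform applies to continuous traits only")
  }
  structure(
    list(trait_name = trait_name, kind = kind, coding_map = coding_map,
         log_transform = isTRUE(log_transform), weight = weight,
         month_scale = isTRUE(month_scale), unit = unit),
    class = "trait_scheme"
  )
}

#' @export
print.trait_scheme <- function(x, ...) {
  cat("<trait_scheme> ", x$trait_name, " (", x$kind,
      if (x$log_transform) ", log-transformed" else "",
      "), weight ", format(x$weight), "\n", sep = "")
  if (!is.null(x$coding_map)) {
    cat("  coding:", paste(names(x$coding_map), "=", x$coding_map, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Standard grassland response-trait schemes
#'
#' The eleven response traits routinely used to characterise grazed grassland
#' vegetation, with their conventional codings: bud height (life-form) coded
#' 0 (geophyte/therophyte) to 1 (phanerophyte); canopy structure coded rosette
#' 0, hemirosette 0.5, erosulate 1; leafing period (evergreen 0, summer green
#' 1); life span (annual 0, biennial 0.5, perennial 1); start of flowering as
#' month 1--12; canopy height (m) and leaf size (mm^2) log-transformed; leaf
#' dry matter content (LDMC, mg g^-1) and specific leaf area (SLA,
#' mm^2 mg^-1) continuous; and the two vegetative-spread attributes (rhizome,
#' stolon) each binary with weight 0.5 so that vegetative spread as a whole
#' carries the same weight as every other trait.
#'
#' @return Named list of [trait_scheme][traitScheme] objects.
#' @export
defaultTraitSchemes <- function() {
  schemes <- list(
    traitScheme("life_form", "ordinal-coded",
                coding_map = c("Geophyte" = 0, "Therophyte" = 0,
                               "Hemicryptophyte" = 0.333, "Chamaephyte" = 0.667,
                               "Phanerophyte" = 1)),
    traitScheme("canopy_height", "continuous", log_transform = TRUE, unit = "m"),
    traitScheme("canopy_structure", "ordinal-coded",
                coding_map = c("Rosette" = 0, "Hemirosette" = 0.5, "Erosulate" = 1)),
    traitScheme("flowering_start", "ordinal-coded",
                coding_map = stats::setNames(1:12, month.name), month_scale = TRUE,
                unit = "month"),
    traitScheme("ldmc", "continuous", unit = "mg/g"),
    traitScheme("leaf_size", "continuous", log_transform = TRUE, unit = "mm2"),
    traitScheme("leafing_period", "binary-coded",
                coding_map = c("Evergreen" = 0, "Summer green" = 1)),
    traitScheme("life_span", "ordinal-coded",
                coding_map = c("Annual" = 0, "Biennial" = 0.5, "Perennial" = 1)),
    traitScheme("sla", "continuous", unit = "mm2/mg"),
    traitScheme("rhizome", "binary-coded", weight = 0.5,
                coding_map = c("Not rhizomatous" = 0, "Rhizomatous" = 1)),
    traitScheme("stolon", "binary-coded", weight = 0.5,
                coding_map = c("Not stoloniferous" = 0, "Stoloniferous" = 1))
  )
  stats::setNames(schemes, vapply(schemes, `[[`, "", "trait_name"))
}

#' Code a single raw trait entry
#'
#' Applies a scheme to one raw database entry: looks up the numeric code for
#' category labels, passes continuous values through, and applies the natural
#' log where the scheme requires it.
#'
#' @param value Raw entry value: a number for continuous traits, a category
#'   label (or an already-valid code) for coded traits.
#' @param scheme A [trait_scheme][traitScheme].
#' @return The coded numeric value.
#' @examples
#' sch <- defaultTraitSchemes()
#' codeTrait("Chamaephyte", sch$life_form)   # 0.667
#' codeTrait(0.1, sch$canopy_height)         # log(0.1)
#' @export
codeTrait <- function(value, scheme) {
  stopifnot(inherits(scheme, "trait_scheme"))
  if (scheme$kind == "continuous") {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v) || !is.finite(v))
      stop("trait '", scheme$trait_name, "': non-numeric value '", value,
           "' for a continuous trait")
    if (scheme$log_transform) {
      if (v <= 0)
        stop("trait '", scheme$trait_name, "': value ", v,
             " must be positive under a log transform")
      return(log(v))
    }
    return(v)
  }
  # coded kinds: accept a label from the map, or a numeric already in range
  if (is.character(value) || is.factor(value)) {
    lab <- as.character(value)
    if (!lab %in% names(scheme$coding_map))
      stop("trait '", scheme$trait_name, "': unknown category label '", lab, "'")
    return(unname(scheme$coding_map[lab]))
  }
  v <- as.numeric(value)
  hi <- if (scheme$month_scale) 12 else 1
  if (is.na(v) || v < 0 || v > hi)
    stop("trait '", scheme$trait_name, "': coded value ", value,
         " outside [0, ", hi, "]")
  v
}

#' Replication-weighted species trait mean
#'
#' Database trait compilations usually hold several entries per species and
#' trait, each backed by a different number of underlying measurements. The
#' species value is the weighted mean of the (coded) entries, with the
#' replication count of each entry as its weight.
#'
#' @param values Numeric vector of coded entry values for one species x trait.
#' @param replication Positive integer vector of per-entry replication counts.
#' @return `sum(values * replication) / sum(replication)`.
#' @examples
#' speciesTraitMean(c(200, 300), c(1, 3))  # 275
#' @export
speciesTraitMean <- function(values, replication = rep(1, length(values))) {
  if (length(values) == 0L) stop("no entries to average")
  if (length(replication) != length(values))
    stop("values and replication lengths differ")
  if (any(!is.finite(values))) stop("non-finite entry values")
  if (any(!is.finite(replication)) || any(replication < 1))
    stop("replication counts must be >= 1")
  sum(values * replication) / sum(replication)
}

#' Build a coded species x trait table
#'
#' Turns long-format raw entries (species, trait, value, replication) into the
#' immutable species x trait matrix used by all downstream metrics: each entry
#' is coded under its scheme (including any log transform), entries for the
#' same species and trait are averaged with replication weights, and coverage
#' is checked — a missing (species, trait) cell is a hard error listing every
#' gap, since the metrics require complete trait coverage for the species pool.
#'
#' @param entries Data frame with columns `species_id`, `trait_name`, `value`,
#'   and optionally `replication` (default 1).
#' @param schemes Named list of [trait_scheme][traitScheme] objects; defaults
#'   to [defaultTraitSchemes()] restricted to the traits present in `entries`.
#' @return An object of class `trait_table`: a list with elements
#'   `values` (species x trait numeric matrix, log-transformed traits stored
#'   post-transform), `schemes`, `weights` (named per-trait vector) and
#'   `n_entries` (per-cell provenance counts).
#' @export
buildTraitTable <- function(entries, schemes = NULL) {
  req <- c("species_id", "trait_name", "value")
  if (!all(req %in% names(entries)))
    stop("entries must have columns: ", paste(req, collapse = ", "))
  if (is.null(entries$replication)) entries$replication <- 1
  if (any(!is.finite(entries$replication)) || any(entries$replication < 1))
    stop("replication counts must be >= 1")
  if (is.null(schemes)) {
    schemes <- defaultTraitSchemes()
    schemes <- schemes[intersect(names(schemes), unique(entries$trait_name))]
  }
  unknown <- setdiff(unique(entries$trait_name), names(schemes))
  if (length(unknown))
    stop("entries reference traits with no scheme: ", paste(unknown, collapse = ", "))

  species <- sort(unique(as.character(entries$species_id)))
  traits <- names(schemes)
  vals <- matrix(NA_real_, length(species), length(traits),
                 dimnames = list(species, traits))
  n_entries <- matrix(0L, length(species), length(traits),
                      dimnames = list(species, traits))

  for (tr in traits) {
    sub <- entries[entries$trait_name == tr, , drop = FALSE]
    if (nrow(sub) == 0L) next
    coded <- vapply(sub$value, codeTrait, numeric(1), scheme = schemes[[tr]])
    for (sp in unique(as.character(sub$species_id))) {
      i <- as.character(sub$species_id) == sp
      vals[sp, tr] <- speciesTraitMean(coded[i], sub$replication[i])
      n_entries[sp, tr] <- sum(i)
    }
  }

  gaps <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(gaps)) {
    msg <- apply(gaps, 1L, function(g) paste0(species[g[1]], ":", traits[g[2]]))
    stop("missing trait coverage for ", nrow(gaps), " (species, trait) cell(s): ",
         paste(msg, collapse = ", "))
  }

  structure(
    list(values = vals, schemes = schemes,
         weights = vapply(schemes, `[[`, numeric(1), "weight"),
         n_entries = n_entries,
         log_base = "natural"),
    class = "trait_table"
  )
}

#' @export
print.trait_table <- function(x, ...) {
  cat("<trait_table> ", nrow(x$values), " species x ", ncol(x$values),
      " traits\n", sep = "")
  cat("  traits:", paste(colnames(x$values), collapse = ", "), "\n")
  logged <- names(Filter(function(s) s$log_transform, x$schemes))
  if (length(logged))
    cat("  stored on natural-log scale:", paste(logged, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trait_table <- function(x) dim(x$values)

#' Species identifiers of a trait table
#' @param traits A [trait_table][buildTraitTable].
#' @return Character vector of species ids.
#' @export
traitSpecies <- function(traits) rownames(traits$values)

#' Trait values on the distance scale
#'
#' Returns the trait matrix as used inside multi-trait Gower distances:
#' identical to the stored values except that month-scale traits (start of
#' flowering) are rescaled from months 1--12 to `[0, 1]` by `(m - 1)/11`, so
#' that every coded axis enters range normalisation on a comparable footing.
#'
#' @param traits A [trait_table][buildTraitTable].
#' @param subset Optional character vector of trait names.
#' @return Numeric species x trait matrix.
#' @export
traitDistanceValues <- function(traits, subset = NULL) {
  stopifnot(inherits(traits, "trait_table"))
  m <- traits$values
  if (!is.null(subset)) {
    bad <- setdiff(subset, colnames(m))
    if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
    m <- m[, subset, drop = FALSE]
  }
  for (tr in colnames(m)) {
    if (isTRUE(traits$schemes[[tr]]$month_scale)) m[, tr] <- (m[, tr] - 1) / 11
  }
  m
}
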
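#' Read long-format raw trait entries
#'
#' Expects a CSV with columns `species_id`, `trait_name`, `value`,
#' `replication` (replication optional, default 1).
#'
#' @param path CSV path.
#' @return Data frame of raw entries, ready for [buildTraitTable()].
#' @export
readTraitEntries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "trait_name", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trait entry file lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$replication)) df$replication <- 1
  df
}

#' Write / read a coded trait table
#'
#' The table is written as a wide CSV (species rows, trait columns) with a
#' JSON sidecar (`<path>.meta.json`) recording each trait's scheme: kind,
#' coding map, log transform (natural log), month scaling and weight, so the
#' table can be reconstructed losslessly.
#'
#' @param traits A [trait_table][buildTraitTable].
#' @param path CSV path for the wide table.
#' @return `writeTraitTable` returns `path` invisibly; `readTraitTable`
#'   returns a `trait_table`.
#' @export
writeTraitTable <- function(traits, path) {
  stopifnot(inherits(traits, "trait_table"))
  df <- data.frame(species_id = rownames(traits$values), traits$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- lapply(traits$schemes, function(s) {
    list(trait_name = s$trait_name, kind = s$kind,
         coding_map = as.list(s$coding_map),
         log_transform = s$log_transform, weight = s$weight,
         month_scale = s$month_scale, unit = s$unit)
  })
  jsonlite::write_json(list(log_base = traits$log_base, schemes = meta),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTraitTable
#' @export
readTraitTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$species_id
  schemes <- lapply(meta$schemes, function(s) {
    traitScheme(s$trait_name, s$kind,
                coding_map = if (length(s$coding_map)) unlist(s$coding_map),
                log_transform = isTRUE(s$log_transform), weight = s$weight,
                month_scale = isTRUE(s$month_scale),
                unit = if (is.null(s$unit)) NA_character_ else s$unit)
  })
  names(schemes) <- vapply(schemes, `[[`, "", "trait_name")
  schemes <- schemes[colnames(vals)]
  structure(list(values = vals, schemes = schemes,
                 weights = vapply(schemes, `[[`, numeric(1), "weight"),
                 n_entries = matrix(NA_integer_, nrow(vals), ncol(vals),
                                    dimnames = dimnames(vals)),
                 log_base = meta$log_base),
            class = "trait_table")
}

#' Write / read a community matrix
#'
#' Wide CSV: key columns `experiment`, `block`, `plot`, `year`, then one
#' relative-abundance column per species.
#'
#' @param community A [community_matrix][communityMatrix].
#' @param path CSV path.
#' @param traits Optional [trait_table][buildTraitTable]; if supplied, the
#'   community's species set is checked against it and a mismatch errors,
#'   naming the symmetric difference.
#' @param normalise Passed to [communityMatrix()] on read: renormalise rows
#'   with a warning instead of erroring.
#' @return `writeCommunityMatrix` returns `path` invisibly;
#'   `readCommunityMatrix` returns a `community_matrix`.
#' @export
writeCommunityMatrix <- function(community, path) {
  stopifnot(inherits(community, "community_matrix"))
  df <- cbind(community$keys, as.data.frame(community$abund, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCommunityMatrix
#' @export
readCommunityMatrix <- function(path, traits = NULL, normalise = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  keycols <- c("experiment", "block", "plot", "year")
  miss <- setdiff(keycols, names(df))
  if (length(miss))
    stop("community file lacks key column(s): ", paste(miss, collapse = ", "))
  abund <- as.matrix(df[, setdiff(names(df), keycols), drop = FALSE])
  if (!is.null(traits)) {
    pool <- traitSpecies(traits)
    extra <- setdiff(colnames(abund), pool)
    absent <- setdiff(pool, colnames(abund))
    if (length(extra) || length(absent))
      stop("species mismatch between community and trait table; ",
           "in community only: [", paste(extra, collapse = ", "),
           "]; in trait table only: [", paste(absent, collapse = ", "), "]")
  }
  communityMatrix(abund, df[keycols], normalise = normalise)
}

#' Write / read plot-year records
#'
#' CSV with unit-suffixed measurement headers (`productivity_lu_ha_yr`,
#' `rain_mm`, `temp_c`) to prevent silent unit drift; in memory the columns
#' are the bare `productivity`, `rain`, `temp`.
#'
#' @param records Plot-year record data frame.
#' @param path CSV path.
#' @return `writeRecords` returns `path` invisibly; `readRecords` the data
#'   frame.
#' @export
writeRecords <- function(records, path) {
  need <- c("experiment", "block", "plot", "year", "productivity", "rain", "temp")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  out <- records[need]
  names(out) <- c("experiment", "block", "plot", "year",
                  "productivity_lu_ha_yr", "rain_mm", "temp_c")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecords
#' @export
readRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment", "block", "plot", "year",
            "productivity_lu_ha_yr", "rain_mm", "temp_c")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("record file lacks column(s): ", paste(miss, collapse = ", "))
  names(df)[match(c("productivity_lu_ha_yr", "rain_mm", "temp_c"), names(df))] <-
    c("productivity", "rain", "temp")
  if (any(df$productivity < 0)) stop("negative productivity values")
  if (any(df$rain < 0)) stop("negative rainfall values")
  df
}

#' Write an FD profile as tidy CSV
#'
#' One row per plot-year, key columns followed by every metric column.
#'
#' @param profile An [fd_profile][fdProfile].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeFDProfile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write the machine-readable run summary of an analysis
#'
#' Serialises the `summary` element of a [grazefd_analysis][runFullAnalysis]
#' to JSON. Identical analyses produce byte-identical files.
#'
#' @param analysis A `grazefd_analysis`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeRunSummary <- function(analysis, path) {
  stopifnot(inherits(analysis, "grazefd_analysis"))
  jsonlite::write_json(analysis$summary, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a generator configuration from YAML or JSON
#'
#' Fields mirror the arguments of [generatorConfig()]; unknown fields error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated [generator_config][generatorConfig].
#' @export
readGeneratorConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(generatorConfig))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown generator config field(s): ", paste(unknown, collapse = ", "))
  do.call(generatorConfig, cfg)
}
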
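# fixtures built in code; no data files

# minimal trait table from explicit continuous values (one entry per cell)
makeTraitTable <- function(values, log_transform = FALSE, weights = NULL) {
  # values: named list trait -> numeric vector over species sp1..spN
  S <- length(values[[1]])
  sp <- sprintf("sp%d", seq_len(S))
  entries <- do.call(rbind, lapply(names(values), function(tr) {
    data.frame(species_id = sp, trait_name = tr, value = values[[tr]],
               replication = 1)
  }))
  schemes <- lapply(names(values), function(tr)
    traitScheme(tr, "continuous", log_transform = log_transform,
                weight = if (is.null(weights)) 1 else weights[[tr]]))
  names(schemes) <- names(values)
  buildTraitTable(entries, schemes)
}

# community matrix over the species of a trait table
makeCommunity <- function(abund, traits, years = NULL) {
  abund <- rbind(abund)
  colnames(abund) <- traitSpecies(traits)
  n <- nrow(abund)
  keys <- data.frame(experiment = "e1", block = "b1", plot = "p1",
                     year = if (is.null(years)) seq_len(n) + 2000 else years)
  communityMatrix(abund, keys)
}

# brute-force Rao's Q: explicit O(S^2) double sum, the independent oracle
raoBrute <- function(p, d) {
  q <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) q <- q + p[i] * p[j] * d[i, j]
  q
}

# random abundance vector summing to 1
randAbund <- function(S) { x <- stats::runif(S); x / sum(x) }

# quick synthetic records without FD profiles (uses ground-truth CWM)
quickRecords <- function(seed = 1, ...) {
  ds <- simulateGrazingData(generatorConfig(seed = seed, ...))
  rec <- ds$records
  rec$cwm_ldmc <- ds$truth$cwm_ldmc
  rec$rao_ldmc <- ds$truth$rao_ldmc
  list(records = rec, truth = ds$truth, dataset = ds)
}
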
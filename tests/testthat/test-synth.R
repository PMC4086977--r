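test_that("generator configurations are validated", {
  expect_s3_class(generatorConfig(), "generator_config")
  expect_error(generatorConfig(k = -0.01), "positive")
  expect_error(generatorConfig(years_range = c(2, 10)), "years_range")
  expect_error(generatorConfig(years_range = c(4, 20)), "years_range")
  expect_error(generatorConfig(sigma0 = -1), "sigma0")
  expect_error(generatorConfig(coupling = 1.5), "coupling")
})

test_that("identical configurations reproduce identical datasets", {
  d1 <- simulateGrazingData(generatorConfig(seed = 42))
  d2 <- simulateGrazingData(generatorConfig(seed = 42))
  expect_identical(d1$traits$values, d2$traits$values)
  expect_identical(d1$community$abund, d2$community$abund)
  expect_identical(d1$records, d2$records)
  d3 <- simulateGrazingData(generatorConfig(seed = 43))
  expect_false(identical(d1$records$productivity, d3$records$productivity))
})

test_that("species pool marginals match the grassland design", {
  pool <- generateSpeciesPool(generatorConfig(n_species = 1000), seed = 8)
  ldmc <- pool$values[, "ldmc"]
  expect_equal(mean(ldmc), 250, tolerance = 10 / 250)
  expect_true(all(ldmc > 0))
  expect_lt(cor(ldmc, pool$values[, "sla"]), 0)   # leaf economics axis
  expect_equal(dim(pool), c(1000L, 11L))
})

test_that("community rows are simplex points over the trait-table species", {
  ds <- simulateGrazingData(generatorConfig(seed = 9))
  expect_true(all(abs(rowSums(ds$community$abund) - 1) < 1e-9))
  expect_true(all(ds$community$abund >= 0))
  expect_identical(colnames(ds$community$abund), traitSpecies(ds$traits))
  yrs <- table(ds$community$keys$experiment) /
    ds$config$plots_per_experiment
  expect_true(all(yrs >= 4 & yrs <= 15))
})

test_that("fertility-diversity coupling is off at 0 and strong at 1", {
  plotMeans <- function(coupling) {
    ds <- simulateGrazingData(generatorConfig(seed = 77, coupling = coupling,
                                              plots_per_experiment = 23))
    q <- apply(ds$community$abund, 1, raoQ, d = gowerDist(ds$traits, "ldmc"))
    pk <- paste(ds$community$keys$experiment, ds$community$keys$plot)
    list(f = tapply(attr(ds$community, "fertility"), pk, mean),
         q = tapply(q, pk, mean))
  }
  null <- plotMeans(0)
  expect_gte(length(null$f), 200)
  expect_lt(abs(cor(null$f, null$q)), 0.15)
  full <- plotMeans(1)
  expect_lte(cor(full$f, full$q, method = "spearman"), -0.5)
})

test_that("records follow the declared mean and dispersion structure", {
  cfg <- generatorConfig(seed = 10)
  ds <- simulateGrazingData(cfg)
  tru <- ds$truth
  expect_equal(tru$sd_eps, cfg$sigma0 * exp(-cfg$gamma * tru$rao_ldmc))
  # standardised residual draws have unit spread
  expect_equal(sd(tru$eps / tru$sd_eps), 1, tolerance = 0.15)
  expect_true(all(ds$records$productivity >= 0))
  expect_gte(tru$n_truncated, 0)
  # weather is shared across plots within an experiment-year
  wx <- unique(ds$records[c("experiment", "year", "rain")])
  expect_equal(nrow(wx), nrow(unique(ds$records[c("experiment", "year")])))
})

test_that("a fully deterministic configuration reproduces the plugged mean", {
  cfg <- generatorConfig(seed = 11, sigma_exp = 0, sigma_plot = 0,
                         sigma0 = 0, gamma = 0)
  ds <- simulateGrazingData(cfg)
  mu <- cfg$beta0 + cfg$beta1 * expDecay(ds$truth$cwm_ldmc, cfg$k) +
    cfg$beta_rain * ds$records$rain
  expect_equal(ds$records$productivity, pmax(0, mu), tolerance = 1e-12)
  # the printed-coefficient spot value: CWM 200 mg/g, 600 mm rain
  expect_equal(cfg$beta0 + cfg$beta1 * expDecay(200, cfg$k) +
                 cfg$beta_rain * 600, 3.574, tolerance = 1e-3)
})

test_that("noise-free data are fitted with essentially zero residual error", {
  # constant rainfall so the pooled decay regression sees a pure curve
  cfg <- generatorConfig(seed = 12, sigma_exp = 0, sigma_plot = 0,
                         sigma0 = 0, gamma = 0, rain_sd = 0,
                         rain_mean_range = c(600, 600))
  ds <- simulateGrazingData(cfg)
  rec <- ds$records; rec$cwm_ldmc <- ds$truth$cwm_ldmc
  ft <- fitDecayTransform(rec)
  expect_equal(ft$k, cfg$k, tolerance = 1e-6)
  # rainfall is constant here, so its contribution sits in the intercept;
  # zero-noise data legitimately give a singular-precision warning
  m <- suppressWarnings(
    fitProductivityModel(rec, "expLDMC", "experiment/plot",
                         "REML", k = cfg$k))
  expect_lt(sum(m$residuals^2), 1e-8)
})

test_that("the full pipeline recovers the decay rate within 20 percent", {
  hits <- 0L
  for (s in 1:10) {
    qr <- quickRecords(seed = 900 + s)
    k_hat <- fitDecayTransform(qr$records)$k
    if (abs(k_hat - 0.017) / 0.017 <= 0.2) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
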
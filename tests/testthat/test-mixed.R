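simpleRecords <- function(n_exp = 4, n_plot = 3, n_year = 8, seed = 1,
                          sd_exp = 0, sd_plot = 0, sd_eps = 0.1,
                          b0 = 1, b_rain = 0.002) {
  set.seed(seed)
  g <- expand.grid(experiment = sprintf("e%d", 1:n_exp),
                   plot = sprintf("p%d", 1:n_plot),
                   year = 2000 + 1:n_year, stringsAsFactors = FALSE)
  g$block <- g$plot
  g$rain <- runif(nrow(g), 300, 800)
  g$temp <- rnorm(nrow(g), 12, 1)
  g$cwm_ldmc <- runif(nrow(g), 150, 350)
  ue <- setNames(rnorm(n_exp, 0, sd_exp), sprintf("e%d", 1:n_exp))
  up <- setNames(rnorm(n_exp * n_plot, 0, sd_plot),
                 as.vector(outer(1:n_exp, 1:n_plot,
                                 function(e, p) paste0("e", e, ".p", p))))
  g$productivity <- b0 + b_rain * g$rain + ue[g$experiment] +
    up[paste0(g$experiment, ".", g$plot)] + rnorm(nrow(g), 0, sd_eps)
  g
}

test_that("zero grouping variance reduces the fit to ordinary least squares", {
  rec <- simpleRecords(sd_exp = 0, sd_plot = 0)
  m <- fitProductivityModel(rec, "rain", random = "experiment/plot", mode = "REML")
  ols <- coef(lm(productivity ~ rain, data = rec))
  expect_equal(unname(m$coefficients$estimate), unname(ols), tolerance = 1e-6)
  expect_true(m$boundary)   # variance components at the zero boundary, flagged
})

test_that("the stored AIC obeys -2 logLik + 2 npar under the fit's own mode", {
  rec <- simpleRecords(sd_exp = 0.3, sd_plot = 0.2)
  for (mode in c("REML", "ML")) {
    m <- fitProductivityModel(rec, "rain", random = "experiment/plot", mode = mode)
    expect_equal(m$AIC, -2 * m$logLik + 2 * m$n_par)
    expect_equal(m$residuals, rec$productivity - m$fitted)
  }
})

test_that("REML and ML fixed coefficients agree on a large balanced design", {
  rec <- simpleRecords(n_exp = 8, n_plot = 4, n_year = 12,
                       sd_exp = 0.3, sd_plot = 0.2, seed = 2)
  m1 <- fitProductivityModel(rec, "rain", random = "experiment/plot", mode = "REML")
  m2 <- fitProductivityModel(rec, "rain", random = "experiment/plot", mode = "ML")
  expect_equal(m1$coefficients$estimate, m2$coefficients$estimate,
               tolerance = 0.01)
})

test_that("the quadratic rainfall term recovers the response vertex", {
  # mean structure peaking at 0.00234 / (2 * 1.47e-6) = 795.9 mm
  set.seed(3)
  rec <- simpleRecords(n_exp = 6, n_plot = 3, n_year = 12, sd_eps = 0)
  rec$rain <- runif(nrow(rec), 300, 1100)
  rec$productivity <- 0.229 + 0.00234 * rec$rain - 1.47e-6 * rec$rain^2 +
    rnorm(nrow(rec), 0, 0.02)
  m <- fitProductivityModel(rec, c("rain", "rain2"), random = "experiment",
                            mode = "REML")
  co <- setNames(m$coefficients$estimate, m$coefficients$term)
  vertex <- -co["rain"] / (2 * co["rain2"])
  expect_equal(unname(vertex), 795.9, tolerance = 0.02)
})

test_that("the expLDMC term uses the frozen decay rate", {
  rec <- simpleRecords()
  rec$productivity <- rec$productivity + 90 * exp(-0.017 * rec$cwm_ldmc)
  m <- fitProductivityModel(rec, c("expLDMC", "rain"),
                            random = "experiment/plot", k = 0.017)
  expect_equal(m$k, 0.017)
  co <- setNames(m$coefficients$estimate, m$coefficients$term)
  expect_equal(unname(co["expLDMC"]), 90, tolerance = 0.05)
  expect_error(fitProductivityModel(rec, "expLDMC", random = "experiment"),
               "requires the decay rate")
})

test_that("likelihood-ratio tests compare nested maximum-likelihood fits", {
  rec <- simpleRecords(sd_exp = 0.3)
  full <- fitProductivityModel(rec, c("rain", "temp"), "experiment/plot", "ML")
  red <- fitProductivityModel(rec, "rain", "experiment/plot", "ML")
  lrt <- lrTest(full, red)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$p, 0); expect_lte(lrt$p, 1)
  expect_error(lrTest(red, full), "no more parameters")
  remL <- fitProductivityModel(rec, "rain", "experiment/plot", "REML")
  expect_error(lrTest(full, remL), "common estimation mode")
})

test_that("unknown fixed terms and missing columns are rejected", {
  rec <- simpleRecords()
  expect_error(fitProductivityModel(rec, "soil_ph", "experiment"), "soil_ph")
  expect_error(fitProductivityModel(rec[, setdiff(names(rec), "productivity")],
                                    "rain", "experiment"), "productivity")
})
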
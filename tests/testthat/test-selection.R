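test_that("the random ladder selects the true experiment/plot nesting", {
  qr <- quickRecords(seed = 101)
  rs <- simplifyRandom(qr$records, c("expLDMC", "rain", "rain2", "temp"),
                       k = 0.017)
  expect_equal(rs$selected, "experiment/plot")
  expect_equal(nrow(rs$table), 4L)
  expect_true(all(c("none", "experiment", "experiment/plot",
                    "experiment/block/plot") %in% rs$table$candidate))
  expect_s3_class(rs$fit, "prod_model")
  expect_equal(rs$fit$mode, "REML")
})

test_that("without grouping variance the ladder prefers simpler structures", {
  hits <- 0L
  for (s in 1:12) {
    qr <- quickRecords(seed = 200 + s, sigma_exp = 0, sigma_plot = 0)
    rs <- simplifyRandom(qr$records, c("expLDMC", "rain"), k = 0.017)
    if (rs$selected %in% c("none", "experiment")) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("backward elimination drops null terms and keeps real ones", {
  qr <- quickRecords(seed = 301)
  fs <- simplifyFixed(qr$records, c("expLDMC", "rain", "rain2", "temp"),
                      random = "experiment/plot", k = 0.017)
  expect_true(all(c("expLDMC", "rain") %in% fs$terms))
  expect_false("temp" %in% fs$terms)
  expect_equal(fs$final$mode, "REML")
  expect_true(all(c("step", "term", "AIC", "p", "dropped") %in%
                  names(fs$ladder)))
})

test_that("marginality keeps rain while its square is in the model", {
  qr <- quickRecords(seed = 302)
  fs <- simplifyFixed(qr$records, c("expLDMC", "rain", "rain2", "temp"),
                      random = "experiment/plot", k = 0.017)
  lad <- fs$ladder
  steps_with_rain2 <- unique(lad$step[lad$term == "rain2"])
  expect_false(any(lad$term == "rain" & lad$step %in% steps_with_rain2))
})

test_that("pure-noise slopes are all eliminated", {
  set.seed(9)
  rec <- data.frame(
    experiment = rep(sprintf("e%d", 1:5), each = 40),
    block = "b1", plot = rep(sprintf("p%d", 1:4), 50),
    year = rep(2001:2010, 20),
    rain = runif(200, 300, 800), temp = rnorm(200, 12),
    cwm_ldmc = runif(200, 150, 350))
  rec$productivity <- 2 + rnorm(200, 0, 0.2)
  fs <- simplifyFixed(rec, c("rain", "temp"), random = "experiment", k = NULL)
  expect_length(fs$terms, 0L)
})

test_that("forward selection tests each FD candidate by likelihood ratio", {
  qr <- quickRecords(seed = 401)
  rec <- joinProfile(qr$dataset$records,
                     fdProfile(qr$dataset$community, qr$dataset$traits))
  base <- fitProductivityModel(rec, c("expLDMC", "rain"), "experiment/plot",
                               "REML", k = 0.017)
  sel <- forwardSelectFD(base$data, base)
  expect_equal(sel$candidate, c("feve_all", "rao_all", "feve_ldmc", "rao_ldmc"))
  expect_true(all(sel$p >= 0 & sel$p <= 1, na.rm = TRUE))
  expect_type(attr(sel, "any_significant"), "logical")
})

test_that("a strong injected RaoQ_LDMC fixed effect is detected", {
  hits <- 0L
  for (s in 1:8) {
    ds <- simulateGrazingData(generatorConfig(seed = 500 + s, gamma = 0,
                                              fd_effect = c(rao_ldmc = 4)))
    rec <- joinProfile(ds$records, fdProfile(ds$community, ds$traits))
    base <- fitProductivityModel(rec, c("expLDMC", "rain"), "experiment/plot",
                                 "REML", k = 0.017)
    sel <- forwardSelectFD(base$data, base)
    if (isTRUE(sel$significant[sel$candidate == "rao_ldmc"])) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("a candidate collinear with the base model is refused", {
  qr <- quickRecords(seed = 601)
  rec <- qr$records
  rec$exp_copy <- exp(-0.017 * rec$cwm_ldmc)   # duplicates the expLDMC column
  base <- fitProductivityModel(rec, c("expLDMC", "rain"), "experiment/plot",
                               "REML", k = 0.017)
  expect_warning(sel <- forwardSelectFD(base$data, base,
                                        candidates = "exp_copy"),
                 "collinear")
  expect_true(sel$collinear[1])
  expect_true(is.na(sel$p[1]))
})
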
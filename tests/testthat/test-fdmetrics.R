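test_that("Gower distance matches hand values on simple configurations", {
  # one trait, two species at the range endpoints
  t1 <- makeTraitTable(list(ldmc = c(100, 300)))
  d1 <- gowerDist(t1)
  expect_equal(unname(d1[1, 2]), 1)
  expect_equal(unname(diag(d1)), c(0, 0))

  # identical species
  t2 <- makeTraitTable(list(ldmc = c(200, 200, 350)))
  expect_equal(unname(gowerDist(t2)[1, 2]), 0)

  # two traits, weights (1, 0.5), normalised gaps (1, 0) between sp1 and sp2
  t3 <- makeTraitTable(list(a = c(0, 1, 0.5), b = c(5, 5, 9)),
                       weights = c(a = 1, b = 0.5))
  d3 <- gowerDist(t3)
  expect_equal(unname(d3[1, 2]), 1 / 1.5, tolerance = 1e-12)
})

test_that("Gower distance is symmetric, bounded and pool-range normalised", {
  set.seed(3)
  tt <- makeTraitTable(list(x = runif(8), y = runif(8, 10, 40), z = runif(8)))
  d <- gowerDist(tt)
  expect_equal(as.numeric(d), as.numeric(t(d)))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("constant traits are dropped with a record; all-constant errors", {
  tt <- makeTraitTable(list(x = c(1, 2, 3), y = c(5, 5, 5)))
  d <- gowerDist(tt)
  expect_equal(attr(d, "constant_traits"), "y")
  expect_equal(unname(d[1, 3]), 1)
  t_const <- makeTraitTable(list(y = c(5, 5, 5)))
  expect_error(gowerDist(t_const), "zero trait variation")
})

test_that("Gower agrees with cluster::daisy on mixed weighted traits", {
  skip_if_not_installed("cluster")
  set.seed(11)
  tt <- makeTraitTable(list(a = runif(10), b = runif(10, 100, 400),
                            c = runif(10)),
                       weights = c(a = 1, b = 0.5, c = 2))
  d <- gowerDist(tt)
  ref <- as.matrix(cluster::daisy(as.data.frame(tt$values), metric = "gower",
                                  weights = c(1, 0.5, 2)))
  expect_equal(as.numeric(d), as.numeric(ref), tolerance = 1e-10)
})

test_that("community-weighted means are abundance-weighted trait averages", {
  tt <- makeTraitTable(list(ldmc = c(200, 300)))
  expect_equal(cwm(c(1, 0), tt, "ldmc"), 200)            # one-species community
  expect_equal(cwm(c(0.25, 0.75), tt, "ldmc"), 275)
  t3 <- makeTraitTable(list(ldmc = rep(240, 4)))
  expect_equal(cwm(rep(0.25, 4), t3, "ldmc"), 240)       # constant trait
  expect_error(cwm(c(sp9 = 1), tt, "ldmc"), "not in species pool")
  expect_error(cwm(c(0.5, 0.5), tt, "height"), "unknown trait")
})

test_that("Rao's Q equals the brute-force double sum and known values", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2)
  expect_equal(raoQ(c(0.5, 0.5), d2), 0.2)               # 2 * 0.25 * 0.4
  expect_equal(raoQ(c(1, 0), d2), 0)
  expect_equal(raoQ(randAbund(5), matrix(0, 5, 5)), 0)
  expect_error(raoQ(c(0.5, 0.5), matrix(0, 3, 3)), "match")

  set.seed(21)
  for (i in 1:50) {
    S <- sample(2:20, 1)
    m <- matrix(runif(S * S), S); m <- (m + t(m)) / 2; diag(m) <- 0
    p <- randAbund(S)
    expect_equal(raoQ(p, m), raoBrute(p, m), tolerance = 1e-12)
  }
})

test_that("two-species Rao's Q is maximised at even abundances", {
  d <- matrix(c(0, 0.7, 0.7, 0), 2)
  grid <- seq(0.01, 0.99, by = 0.01)
  q <- vapply(grid, function(p) raoQ(c(p, 1 - p), d), numeric(1))
  expect_equal(grid[which.max(q)], 0.5)
})

test_that("FEve reproduces the hand-derived 1-D configurations", {
  # equally spaced, equal abundances: perfectly even
  for (S in c(3, 5, 8)) {
    tt <- makeTraitTable(list(x = seq_len(S)))
    expect_equal(as.numeric(feve(rep(1 / S, S), gowerDist(tt))), 1,
                 tolerance = 1e-12)
  }
  # positions (0, 1, 4), equal abundances: PEW = (0.25, 0.75) -> FEve = 0.5
  tt <- makeTraitTable(list(x = c(0, 1, 4)))
  expect_equal(as.numeric(feve(rep(1 / 3, 3), gowerDist(tt))), 0.5,
               tolerance = 1e-12)
})

test_that("FEve is undefined below 3 present species and flagged", {
  tt <- makeTraitTable(list(x = c(0, 1, 4)))
  d <- gowerDist(tt)
  v2 <- feve(c(0.5, 0.5, 0), d)
  expect_true(is.na(v2))
  expect_false(attr(v2, "defined"))
  expect_equal(attr(v2, "n_present"), 2L)
})

test_that("FEve is bounded and invariant to uniform distance rescaling", {
  set.seed(31)
  for (i in 1:30) {
    S <- sample(3:15, 1)
    m <- matrix(runif(S * S), S); m <- (m + t(m)) / 2; diag(m) <- 0
    p <- randAbund(S)
    v <- feve(p, m)
    expect_gte(as.numeric(v), 0); expect_lte(as.numeric(v), 1)
    expect_equal(as.numeric(feve(p, 0.37 * m)), as.numeric(v),
                 tolerance = 1e-12)
  }
})

test_that("1-D MST is the sorted chain with total length max - min", {
  set.seed(41)
  for (i in 1:20) {
    x <- runif(sample(3:12, 1), 0, 100)
    d <- abs(outer(x, x, "-"))
    edges <- grazefd:::mstEdges(d)
    expect_equal(sum(edges$d), max(x) - min(x), tolerance = 1e-12)
  }
})

test_that("MST total length agrees with vegan::spantree", {
  skip_if_not_installed("vegan")
  set.seed(51)
  for (i in 1:10) {
    S <- sample(4:15, 1)
    m <- matrix(runif(S * S), S); m <- (m + t(m)) / 2; diag(m) <- 0
    ours <- sum(grazefd:::mstEdges(m)$d)
    ref <- sum(vegan::spantree(as.dist(m))$dist)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("profiles carry all metrics and are relabelling-invariant", {
  set.seed(61)
  tt <- makeTraitTable(list(sla = runif(6, 10, 35), ldmc = runif(6, 150, 350)))
  ab <- rbind(randAbund(6), randAbund(6), c(0.6, 0.4, 0, 0, 0, 0))
  comm <- makeCommunity(ab, tt)
  prof <- fdProfile(comm, tt)
  expect_equal(nrow(prof), 3L)
  expect_true(all(c("cwm_ldmc", "rao_all", "feve_all", "rao_ldmc",
                    "feve_ldmc", "rao_ldmc_raw") %in% names(prof)))
  # single-trait Rao, two species at normalised gap 1, p = (0.5, 0.5)
  t2 <- makeTraitTable(list(ldmc = c(100, 300)))
  pr2 <- fdProfile(makeCommunity(c(0.5, 0.5), t2), t2)
  expect_equal(pr2$rao_ldmc, 0.5)
  expect_equal(pr2$rao_ldmc_raw, 0.5 * 200)
  # FEve undefined at 2 present species propagates as NA
  expect_true(is.na(prof$feve_all[3]))
  expect_equal(prof$n_present[3], 2)

  # permuting species columns (with matching trait rows) changes nothing
  perm <- c(4, 1, 6, 2, 5, 3)
  tt_p <- tt; tt_p$values <- tt$values[perm, ]
  tt_p$n_entries <- tt$n_entries[perm, ]
  comm_p <- comm; comm_p$abund <- comm$abund[, perm]
  prof_p <- fdProfile(comm_p, tt_p)
  for (cl in c("cwm_ldmc", "rao_all", "feve_all", "rao_ldmc", "feve_ldmc"))
    expect_equal(prof_p[[cl]], prof[[cl]], tolerance = 1e-12, info = cl)
})

test_that("profiles reject communities with unknown species", {
  tt <- makeTraitTable(list(ldmc = c(200, 300)))
  ab <- matrix(c(0.5, 0.3, 0.2), 1)
  colnames(ab) <- c("sp1", "sp2", "spX")
  keys <- data.frame(experiment = "e", block = "b", plot = "p", year = 2001)
  cm <- communityMatrix(ab, keys)
  expect_error(fdProfile(cm, tt), "spX")
})
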
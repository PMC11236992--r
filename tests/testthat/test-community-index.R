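test_that("basal area follows pi (D/2)^2", {
  expect_equal(basal_area(2 / sqrt(pi)), 1.0)
  expect_equal(basal_area(10), 78.5398, tolerance = 1e-5)
  expect_equal(basal_area(20), 4 * basal_area(10)) # doubling D quadruples BA
  expect_error(basal_area(0), "positive")
})

test_that("community index is the weighted mean over covered stems", {
  aff <- aff_table(c("spA", "spB"), c(10, 20))
  mono <- data.frame(species = "spA", diameter = c(12, 40), tag = 1:2)
  expect_equal(community_index(mono, aff, "stem")$value, 10)
  expect_equal(community_index(mono, aff, "ba")$value, 10)
  mix <- data.frame(species = c("spA", "spA", "spA", "spB"), diameter = 20)
  expect_equal(community_index(mix, aff, "stem")$value, 12.5)
  # hand-computed BA weights: D 10 vs 30 -> weights 100 vs 900
  ba <- data.frame(species = c("spA", "spB"), diameter = c(10, 30))
  expect_equal(community_index(ba, aff, "ba")$value, 19.0)
  # equal diameters: stem and BA weighting coincide
  eq <- data.frame(species = c("spA", "spB", "spB"), diameter = 25)
  expect_equal(community_index(eq, aff, "stem")$value,
               community_index(eq, aff, "ba")$value)
})

test_that("uncovered stems are dropped with renormalized weights", {
  aff <- aff_table(c("spA", "spB", "spC"), c(10, 20, 30),
                   included = c(TRUE, TRUE, FALSE))
  st <- data.frame(species = c("spA", "spB", "spC", "indet"), diameter = 20)
  ci <- community_index(st, aff, "stem")
  expect_equal(ci$value, 15) # spC excluded, indet unmatched
  expect_equal(ci$coverage, 0.5)
  expect_warning(
    out <- community_index(data.frame(species = "indet", diameter = 20), aff),
    "undefined")
  expect_true(is.na(out$value))
})

test_that("index is invariant to stem order and species splitting", {
  aff <- aff_table(paste0("s", 1:5), c(8, 11, 14, 17, 20))
  set.seed(42)
  st <- data.frame(species = sample(paste0("s", 1:5), 40, replace = TRUE),
                   diameter = runif(40, 10, 80))
  for (w in c("stem", "ba")) {
    v <- community_index(st, aff, w)$value
    expect_equal(community_index(st[sample.int(40), ], aff, w)$value, v)
    expect_gte(v, 8); expect_lte(v, 20) # bounded by attribute range
  }
})

test_that("trajectory rate uses the endpoint censuses only", {
  aff <- aff_table(c("spA", "spB"), c(10, 20))
  sA <- data.frame(tag = c("a", "b"), species = c("spA", "spB"),
                   diameter = 20, alive = TRUE)
  tr <- index_trajectory(toy_series(list(sA, sA), dates = c(2000, 2010)),
                         aff, "stem")
  expect_equal(tr$annual_rate, 0)
  # dCTI = +0.05 over 10 y -> 0.005 / y
  sB <- sA; sB$species <- c("spA", "spB")
  s2 <- rbind(
    data.frame(tag = c("a", "b", "c", "d"),
               species = c("spA", "spA", "spA", "spB"), diameter = 20,
               alive = TRUE))
  tr2_series <- toy_series(list(
    s2,
    transform(s2, species = c("spA", "spA", "spB", "spB"))),
    dates = c(2000, 2010))
  tr2 <- index_trajectory(tr2_series, aff, "stem")
  expect_equal(tr2$annual_rate, (15 - 12.5) / 10)
  # a middle census never moves the endpoint rate
  mid <- transform(s2, species = c("spB", "spB", "spB", "spB"))
  tr3 <- index_trajectory(toy_series(list(
    s2, mid, transform(s2, species = c("spA", "spA", "spB", "spB"))),
    dates = c(2000, 2004, 2010)), aff, "stem")
  expect_equal(tr3$annual_rate, tr2$annual_rate)
  expect_equal(nrow(tr3$interval_changes), 2)
})

test_that("the worked mortality/recruitment partition is reproduced", {
  aff <- aff_table(c("spA", "spB"), c(10, 20))
  pr <- partition_change(worked_partition_series(), aff, "stem")
  expect_equal(pr$total, 2.5)
  expect_equal(pr$mortality, 10 / 6, tolerance = 1e-12)
  expect_equal(pr$recruitment, 2.5 - 10 / 6, tolerance = 1e-12)
  expect_equal(pr$growth, 0)
  # annualized over the 10-year interval
  pa <- partition_change(worked_partition_series(), aff, "stem",
                         annualize = TRUE)
  expect_equal(pa$total, 0.25)
})

test_that("no deaths and no recruits give a null partition", {
  aff <- aff_table(c("spA", "spB"), c(10, 20))
  s <- data.frame(tag = c("a", "b"), species = c("spA", "spB"),
                  diameter = c(20, 30), alive = TRUE)
  s2 <- transform(s, diameter = diameter + 3)
  pr <- partition_change(toy_series(list(s, s2)), aff, "stem")
  expect_equal(pr$mortality, 0)
  expect_equal(pr$recruitment, 0)
  prba <- partition_change(toy_series(list(s, s2)), aff, "ba")
  expect_equal(prba$mortality, 0)
  expect_equal(prba$recruitment, 0)
  expect_equal(prba$total, prba$growth) # all change is growth
})

test_that("partition components always sum exactly to the total", {
  # property: 60 random census pairs, both weightings (the acceptance
  # suite scales this to 500)
  for (i in 1:60) {
    cfg <- small_sim(1000 + i, n_plots = 1, stems_init = 30,
                     census_dates = c(2010, 2018),
                     m0 = 0.04, r0 = 4, b_r = 0.2, b_m = 0.2)
    bundle <- simulate_census_series(cfg)
    aff <- true_affiliations(bundle)
    for (w in c("stem", "ba")) {
      pr <- partition_change(bundle$series[[1]], aff, w)
      expect_lt(abs(pr$mortality + pr$recruitment + pr$growth - pr$total),
                1e-10)
    }
  }
})

test_that("literal two-term partition matches the chain under stem weighting", {
  aff <- aff_table(c("spA", "spB"), c(10, 20))
  ser <- worked_partition_series()
  chain <- partition_change(ser, aff, "stem", method = "chain")
  lit <- partition_change(ser, aff, "stem", method = "literal")
  expect_equal(lit$mortality, chain$mortality)
  expect_equal(lit$recruitment, chain$recruitment)
  expect_true(is.na(lit$growth))
})

test_that("jackknife contributions carry the documented sign convention", {
  # one plot; spB recruits and fully drives the warming trend
  aff <- aff_table(c("spA", "spB", "spC"), c(10, 20, 15))
  s1 <- data.frame(tag = c("a1", "a2"), species = "spA", diameter = 20,
                   alive = TRUE)
  s2 <- data.frame(tag = c("a1", "a2", "b1"),
                   species = c("spA", "spA", "spB"), diameter = 20,
                   alive = TRUE)
  ser <- toy_series(list(s1, s2), dates = c(2000, 2010))
  jk <- jackknife_contributions(list(ser), aff, "stem")
  # without spB the trend is exactly zero -> contribution -1
  expect_equal(jk$contribution[jk$species == "spB"], -1)
  expect_equal(jk$contribution_sqrt[jk$species == "spB"], -1)
  # spC has no stems anywhere -> contribution exactly 0
  expect_equal(jk$contribution[jk$species == "spC"], 0)
  # and removing it leaves the cross-plot rate unchanged
  expect_equal(jk$rate_without[jk$species == "spC"],
               attr(jk, "rate_all"))
})

test_that("jackknife equals an independent per-species pipeline loop", {
  bundle <- simulate_census_series(small_sim(77, n_plots = 3,
                                             stems_init = 40, n_species = 8))
  aff <- true_affiliations(bundle)
  jk <- jackknife_contributions(bundle$series, aff, "stem")
  rate_all <- attr(jk, "rate_all")
  for (s in aff$species[c(2, 5)]) {
    rates <- vapply(bundle$series, function(cs) {
      cs$stems <- cs$stems[cs$stems$species != s, , drop = FALSE]
      index_trajectory(cs, aff, "stem")$annual_rate
    }, 0)
    expect_equal(jk$rate_without[jk$species == s], mean(rates))
    expect_equal(jk$contribution[jk$species == s],
                 (mean(rates) - rate_all) / rate_all)
  }
  # the transform preserves sign and is monotone in |x|
  expect_equal(sign(jk$contribution_sqrt), sign(jk$contribution))
  expect_equal(order(jk$contribution), order(jk$contribution_sqrt))
})

test_that("size classes are half-open with D = 30 in [30, 50)", {
  aff <- aff_table(c("spA", "spB"), c(10, 20))
  st <- data.frame(
    tag = paste0("t", 1:6), species = c("spA", "spB"),
    diameter = c(10, 29.9, 30, 49.9, 69.9, 70), alive = TRUE)
  ser <- toy_series(list(st), dates = 2010)
  sc <- size_class_summary(ser, aff)
  expect_equal(sc$n, c(2, 2, 1, 1))
  expect_equal(sc$size_class, c("10-30", "30-50", "50-70", ">=70"))
  # single species: identical class means
  st$species <- "spA"
  sc2 <- size_class_summary(toy_series(list(st), dates = 2010), aff)
  expect_true(all(sc2$mean[sc2$n > 0] == 10))
})

test_that("size-class means equal a brute-force groupby", {
  bundle <- simulate_census_series(small_sim(5, stems_init = 200))
  aff <- true_affiliations(bundle)
  sc <- size_class_summary(bundle$series, aff)
  stems <- do.call(rbind, lapply(bundle$series, stems_at, census = 1))
  opt <- aff$t_opt[match(stems$species, aff$species)]
  cls <- cut(stems$diameter, c(10, 30, 50, 70, Inf), right = FALSE,
             labels = c("10-30", "30-50", "50-70", ">=70"))
  for (L in levels(cls)) {
    v <- opt[cls == L & !is.na(opt)]
    expect_equal(sc$n[sc$size_class == L], length(v))
    if (length(v)) expect_equal(sc$mean[sc$size_class == L], mean(v))
  }
})
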
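traits_fixture <- function() {
  data.frame(
    taxon = c("Alpha one", "Alpha two", "Beta one", "Gamma", "Famae"),
    level = c("species", "species", "species", "genus", "family"),
    wood_density = c(0.5, 0.7, 0.4, 0.65, 0.55),
    family = c("Famae", "Famae", "Betaceae", "Famae", "Famae"),
    max_height = NA_real_, light_guild = 0L)
}

test_that("wood density matches at the finest taxonomic level", {
  tr <- traits_fixture()
  got <- match_wood_density(
    c("Alpha one", "Alpha three", "Gamma x", "Delta unknown"), tr)
  expect_equal(got$wood_density[1], 0.5)
  expect_equal(got$level[1], "species")
  # congener mean of {0.5, 0.7}
  expect_equal(got$wood_density[2], 0.6)
  expect_equal(got$level[2], "genus")
  # explicit genus entry
  expect_equal(got$wood_density[3], 0.65)
  expect_equal(got$level[3], "genus")
  # nothing matches -> dataset mean
  expect_equal(got$wood_density[4], mean(tr$wood_density))
  expect_equal(got$level[4], "dataset")
  expect_error(match_wood_density("x", tr[0, ]), "wood density")
})

test_that("family fallback uses the family learned from congeners", {
  tr <- traits_fixture()
  # "Alpha ..." rows declare family Famae; a novel genus of that family is
  # only reachable through an explicit family row
  got <- match_wood_density("Famae-less sp", tr)
  expect_equal(got$level, "dataset")
})

test_that("log-log height data are recovered exactly and selected", {
  d <- seq(10, 90, length.out = 40)
  h <- exp(0.5 + 0.6 * log(d))
  hm <- fit_height_model(d, h)
  expect_equal(hm$family, "loglog")
  expect_equal(unname(hm$coef["a"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(hm$coef["b"]), 0.6, tolerance = 1e-6)
  expect_equal(predict(hm, 25), exp(0.5 + 0.6 * log(25)), tolerance = 1e-6)
})

test_that("weibull height data select the weibull family within 5%", {
  set.seed(8)
  d <- runif(60, 10, 100)
  h <- 40 * (1 - exp(-(d / 30)^0.8)) * exp(rnorm(60, 0, 0.01))
  hm <- fit_height_model(d, h)
  expect_equal(hm$family, "weibull")
  expect_equal(unname(hm$coef[["a"]]), 40, tolerance = 0.05)
  expect_equal(unname(hm$coef[["b"]]), 30, tolerance = 0.05)
  expect_equal(unname(hm$coef[["c"]]), 0.8, tolerance = 0.05)
})

test_that("degenerate height data raise an error", {
  expect_error(fit_height_model(c(20, 20), c(15, 15)), "at least")
  expect_error(fit_height_model(rep(c(20, 25), 10), rep(15, 20)),
               "degenerate")
})

test_that("the pantropical allometry evaluates and scales correctly", {
  # 0.0673 * (0.6 * 400 * 15)^0.976 = 0.0673 * 3600^0.976
  expect_equal(tree_agb(20, 15, 0.6), 0.0673 * 3600^0.976)
  expect_equal(tree_agb(20, 15, 0.6), 199.2, tolerance = 1e-3)
  # exponent hook: exactly linear in rho D^2 H
  expect_equal(tree_agb(20, 15, 0.6, exponent = 1), 0.0673 * 3600)
  # strictly increasing in each argument
  expect_gt(tree_agb(21, 15, 0.6), tree_agb(20, 15, 0.6))
  expect_gt(tree_agb(20, 16, 0.6), tree_agb(20, 15, 0.6))
  expect_gt(tree_agb(20, 15, 0.7), tree_agb(20, 15, 0.6))
  expect_error(tree_agb(-1, 15, 0.6), "positive")
})

test_that("carbon is 45.6% of biomass and linear", {
  expect_equal(tree_agc(1000), 456)
  expect_equal(tree_agc(0), 0)
  expect_equal(tree_agc(3 + 7), tree_agc(3) + tree_agc(7))
})

test_that("a single surviving stem yields the hand-computed growth flux", {
  s <- data.frame(tag = "t1", species = "spA", diameter = c(20, 25),
                  alive = TRUE, census = 1:2, height = NA_real_)
  ser <- census_series("P1", c(2000, 2005), s)
  agc <- data.frame(tag = "t1", census = 1:2, alive = TRUE,
                    diameter = c(20, 25), agc_kg = c(100, 150))
  led <- carbon_fluxes(ser, agc, correct = FALSE)
  # 50 kg over 5 y on 1 ha = 10 kg C /y /ha = 0.01 Mg C /y /ha
  expect_equal(led$fluxes$gain_growth, 0.01)
  expect_equal(led$fluxes$gain_recruitment, 0)
  expect_equal(led$fluxes$loss_mortality, 0)
  expect_equal(led$fluxes$net, 0.01)
  expect_equal(led$stocks$agc_mg_ha, c(0.1, 0.15))
})

test_that("identical censuses give zero fluxes", {
  s <- data.frame(tag = c("a", "b"), species = "spA", diameter = 30,
                  alive = TRUE)
  ser <- toy_series(list(s, s), dates = c(2000, 2006))
  agc <- data.frame(tag = rep(c("a", "b"), 2), census = rep(1:2, each = 2),
                    alive = TRUE, diameter = 30, agc_kg = 500)
  led <- carbon_fluxes(ser, agc)
  expect_equal(led$fluxes$gain_growth, 0)
  expect_equal(led$fluxes$gain_recruitment, 0)
  expect_equal(led$fluxes$loss_mortality, 0)
  expect_equal(led$fluxes$net_corr, 0)
})

test_that("interval corrections are additive, non-negative and vanish as T -> 0", {
  mk <- function(T) {
    s <- data.frame(
      tag = c("a", "b", "c", "d"), species = "spA", diameter = 30,
      alive = TRUE)
    s2 <- data.frame(
      tag = c("a", "b", "c", "e"), species = "spA",
      diameter = c(32, 33, 30, 11),
      alive = c(TRUE, TRUE, FALSE, TRUE))
    ser <- toy_series(list(s, s2), dates = c(2000, 2000 + T))
    agc <- rbind(
      data.frame(tag = s$tag, census = 1, alive = TRUE, diameter = 30,
                 agc_kg = 400),
      data.frame(tag = s2$tag, census = 2, alive = s2$alive,
                 diameter = s2$diameter, agc_kg = c(450, 460, 400, 20)))
    carbon_fluxes(ser, agc, correct = TRUE)
  }
  led <- mk(10)
  f <- led$fluxes
  expect_gte(f$gain_growth_corr, f$gain_growth)
  expect_gte(f$gain_recruitment_corr, f$gain_recruitment)
  expect_gte(f$loss_mortality_corr, f$loss_mortality)
  # net is pinned by the observed stock change in both ledgers
  expect_equal(f$net_corr, f$net)
  # the recruit correction is bounded by flux x interval x mortality rate,
  # so it vanishes with T at fixed annual rates
  for (T in c(10, 0.1)) {
    fx <- mk(T)$fluxes
    m_a <- fx$n_deaths / ((fx$n_survivors + fx$n_deaths) * fx$years)
    corr <- fx$gain_recruitment_corr - fx$gain_recruitment
    expect_lte(corr, fx$gain_recruitment * fx$years * m_a)
  }
})

test_that("plot stocks equal an independent per-stem recomputation", {
  bundle <- simulate_census_series(small_sim(12, n_plots = 2,
                                             stems_init = 80))
  ser <- bundle$series[[1]]
  agc <- stem_agc(ser, bundle$traits)
  led <- carbon_fluxes(ser, agc)
  for (cc in seq_along(ser$census_dates)) {
    alive <- agc$census == cc & agc$alive
    expect_equal(led$stocks$agc_mg_ha[cc],
                 sum(agc$agc_kg[alive]) / 1000 / ser$area_ha)
  }
  # ledger identity on every interval
  f <- led$fluxes
  expect_equal(f$net, f$gain_growth + f$gain_recruitment - f$loss_mortality)
})

test_that("adding a recruit never decreases the recruitment gain", {
  s <- data.frame(tag = c("a", "b"), species = "spA", diameter = 30,
                  alive = TRUE)
  s2 <- rbind(s, data.frame(tag = "r1", species = "spA", diameter = 12,
                            alive = TRUE))
  agc_of <- function(last) {
    rbind(data.frame(tag = s$tag, census = 1, alive = TRUE, diameter = 30,
                     agc_kg = 400),
          data.frame(tag = last$tag, census = 2, alive = TRUE,
                     diameter = last$diameter,
                     agc_kg = ifelse(last$diameter < 20, 30, 410)))
  }
  base <- carbon_fluxes(toy_series(list(s, s)), agc_of(s), correct = FALSE)
  plus <- carbon_fluxes(toy_series(list(s, s2)), agc_of(s2), correct = FALSE)
  expect_gte(plus$fluxes$gain_recruitment, base$fluxes$gain_recruitment)
})

test_that("the one-call ledger runs end to end on simulated plots", {
  bundle <- simulate_census_series(small_sim(13, n_plots = 1,
                                             stems_init = 120))
  led <- carbon_ledger(bundle$series[[1]], bundle$traits)
  expect_s3_class(led, "carbon_ledger")
  expect_true(all(led$stocks$agc_mg_ha >= 0))
  o <- led$overall
  expect_equal(o$net_corr, o$gain_growth_corr + o$gain_recruitment_corr -
                 o$loss_mortality_corr, tolerance = 1e-10)
  # corrected identity holds interval by interval
  f <- led$fluxes
  expect_equal(f$net_corr, f$gain_growth_corr + f$gain_recruitment_corr -
                 f$loss_mortality_corr, tolerance = 1e-10)
})
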
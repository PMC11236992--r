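genus_of <- function(species) {
  vapply(strsplit(as.character(species), "\\s+"), `[`, "", 1)
}

#' Wood density at the finest available taxonomic resolution
#'
#' Matches each species against a trait table, falling back through the
#' taxonomy: an exact species entry; else the mean over the genus (explicit
#' genus-level rows plus species-level rows of congeners); else the mean
#' over the family (explicit family-level rows plus rows assigned to the
#' family via their `family` column); else the dataset-wide mean. The
#' resolution level actually used is reported per species so matching
#' quality is auditable.
#'
#' @param species character vector of binomials.
#' @param traits trait table from [read_traits()] (columns `taxon`,
#'   `level`, `wood_density`, optional `family`).
#' @return data.frame `species`, `wood_density` (g cm^-3), `level`
#'   (species/genus/family/dataset).
#' @export
match_wood_density <- function(species, traits) {
  if (!nrow(traits) || all(is.na(traits$wood_density))) {
    stop("trait table has no wood density values", call. = FALSE)
  }
  tr <- traits[!is.na(traits$wood_density), , drop = FALSE]
  tr_genus <- ifelse(tr$level == "species", genus_of(tr$taxon),
                     ifelse(tr$level == "genus", tr$taxon, NA))
  # family of a genus, learned from rows that declare one
  fam_of_genus <- tapply(tr$family, tr_genus, function(f) {
    f <- f[!is.na(f)]
    if (length(f)) f[1] else NA_character_
  })
  overall <- mean(tr$wood_density)
  sp <- unique(as.character(species))
  rows <- lapply(sp, function(s) {
    hit <- tr$level == "species" & tr$taxon == s
    if (any(hit)) {
      return(data.frame(species = s, wood_density = mean(tr$wood_density[hit]),
                        level = "species"))
    }
    g <- genus_of(s)
    hit <- !is.na(tr_genus) & tr_genus == g
    if (any(hit)) {
      return(data.frame(species = s, wood_density = mean(tr$wood_density[hit]),
                        level = "genus"))
    }
    fam <- if (g %in% names(fam_of_genus)) fam_of_genus[[g]] else NA_character_
    if (!is.na(fam)) {
      hit <- (tr$level == "family" & tr$taxon == fam) |
        (!is.na(tr$family) & tr$family == fam)
      if (any(hit)) {
        return(data.frame(species = s, wood_density = mean(tr$wood_density[hit]),
                          level = "family"))
      }
    }
    data.frame(species = s, wood_density = overall, level = "dataset")
  })
  out <- do.call(rbind, rows)
  out[match(as.character(species), out$species), , drop = FALSE]
}

#' Fit a plot-level height-diameter model
#'
#' Fits both candidate families to the measured (diameter, height) pairs of
#' a plot - a three-parameter Weibull curve
#' `H = a (1 - exp(-(D/b)^c))` by nonlinear least squares, and a log-log
#' power law `ln H = a + b ln D` by ordinary least squares - and selects
#' the family with the smaller residual standard error on the height
#' scale. The selected model predicts the heights of unmeasured trees in
#' the same plot. A non-convergent Weibull fit falls back to the log-log
#' family with a warning.
#'
#' @param diameter,height measured pairs (cm, m); typically ~60 stems per
#'   plot spanning the diameter classes.
#' @param min_n minimum number of pairs required (default 10).
#' @return object of class `height_model`: `family` (`"weibull"` or
#'   `"loglog"`), `coef`, `rse`, `n`, and `candidates` (per-family RSE).
#' @export
fit_height_model <- function(diameter, height, min_n = 10) {
  ok <- !is.na(diameter) & !is.na(height) & diameter > 0 & height > 0
  d <- diameter[ok]; h <- height[ok]
  if (length(d) < min_n) {
    stop("need at least ", min_n, " measured height-diameter pairs, got ",
         length(d), call. = FALSE)
  }
  if (length(unique(d)) < 3) {
    stop("degenerate height-diameter data: fewer than 3 distinct diameters",
         call. = FALSE)
  }
  rse <- function(obs, pred, p) sqrt(sum((obs - pred)^2) / (length(obs) - p))

  ll <- stats::lm(log(h) ~ log(d))
  ll_coef <- c(a = unname(stats::coef(ll)[1]), b = unname(stats::coef(ll)[2]))
  ll_rse <- rse(h, exp(stats::fitted(ll)), 2)

  wb <- tryCatch({
    fit <- minpack.lm::nlsLM(
      h ~ a * (1 - exp(-(d / b)^c)),
      start = list(a = max(h) * 1.2, b = stats::median(d), c = 0.9),
      lower = c(a = 1e-3, b = 1e-3, c = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    list(coef = stats::coef(fit), rse = rse(h, stats::fitted(fit), 3))
  }, error = function(e) NULL)

  if (is.null(wb)) {
    warning("Weibull height model did not converge; using log-log",
            call. = FALSE)
    fam <- "loglog"
  } else {
    fam <- if (wb$rse < ll_rse) "weibull" else "loglog"
  }
  cand <- data.frame(
    family = c("loglog", if (!is.null(wb)) "weibull"),
    rse = c(ll_rse, if (!is.null(wb)) wb$rse))
  structure(list(
    family = fam,
    coef = if (fam == "weibull") wb$coef else ll_coef,
    rse = if (fam == "weibull") wb$rse else ll_rse,
    n = length(d), candidates = cand),
    class = "height_model")
}

#' @export
print.height_model <- function(x, ...) {
  cat(sprintf("<height_model> %s, n = %d, RSE = %.3f m\n  coefficients: %s\n",
              x$family, x$n, x$rse,
              paste(names(x$coef), signif(x$coef, 5), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @export
#' @rdname fit_height_model
#' @param object a fitted `height_model`.
#' @param ... unused.
predict.height_model <- function(object, diameter, ...) {
  cf <- object$coef
  if (object$family == "weibull") {
    cf[["a"]] * (1 - exp(-(diameter / cf[["b"]])^cf[["c"]]))
  } else {
    exp(cf[["a"]] + cf[["b"]] * log(diameter))
  }
}

#' Aboveground biomass of a tree
#'
#' Pantropical diameter-height-wood-density allometry
#' `AGB = 0.0673 (rho D^2 H)^0.976` with wood density rho in g cm^-3,
#' diameter D in cm and height H in m, returning kg of dry biomass.
#'
#' @param diameter cm, positive.
#' @param height m, positive.
#' @param wood_density g cm^-3, positive.
#' @param coef,exponent allometry constants; the defaults are the
#'   published pantropical values.
#' @return AGB in kg.
#' @export
tree_agb <- function(diameter, height, wood_density,
                     coef = 0.0673, exponent = 0.976) {
  if (any(is.na(diameter) | diameter <= 0) ||
      any(is.na(height) | height <= 0) ||
      any(is.na(wood_density) | wood_density <= 0)) {
    stop("diameter, height and wood_density must all be positive",
         call. = FALSE)
  }
  coef * (wood_density * diameter^2 * height)^exponent
}

#' Aboveground carbon from biomass
#'
#' Aboveground carbon is taken as 45.6% of aboveground biomass.
#'
#' @param agb biomass (kg or Mg), non-negative.
#' @param fraction carbon fraction of dry biomass (default 0.456).
#' @return carbon in the units of `agb`.
#' @export
tree_agc <- function(agb, fraction = 0.456) {
  if (any(is.na(agb) | agb < 0)) stop("agb must be >= 0", call. = FALSE)
  fraction * agb
}

#' Per-stem aboveground carbon at every census
#'
#' Computes AGC (kg) for every stem record of a plot: wood density matched
#' through [match_wood_density()], height taken from the field measurement
#' when present and otherwise predicted from the plot's height-diameter
#' model, and dead stems valued at their recorded (last live) diameter.
#'
#' @param series a [census_series].
#' @param traits trait table (see [read_traits()]).
#' @param height_model a fitted [fit_height_model()] object; when `NULL`
#'   one is fitted from the measured heights in `series` (any census).
#' @return data.frame `tag`, `census`, `alive`, `diameter`, `agc_kg`;
#'   attribute `height_model` and `wood_density` (per-species match).
#' @export
stem_agc <- function(series, traits, height_model = NULL) {
  st <- series$stems
  if (is.null(height_model)) {
    meas <- st[!is.na(st$height), , drop = FALSE]
    height_model <- fit_height_model(meas$diameter, meas$height)
  }
  wd <- match_wood_density(unique(st$species), traits)
  rho <- wd$wood_density[match(st$species, wd$species)]
  hgt <- ifelse(is.na(st$height), predict(height_model, st$diameter),
                st$height)
  out <- data.frame(tag = st$tag, census = st$census, alive = st$alive,
                    diameter = st$diameter,
                    agc_kg = tree_agc(tree_agb(st$diameter, hgt, rho)))
  attr(out, "height_model") <- height_model
  attr(out, "wood_density") <- wd
  out
}

#' Carbon stocks and census-interval-corrected fluxes for one plot
#'
#' For every census the aboveground carbon stock (Mg C ha^-1) is the sum
#' of live-stem AGC; for every census interval of length T years the
#' uncorrected fluxes (Mg C ha^-1 y^-1) are
#' growth gain = sum over survivors of (AGC_end - AGC_start)/T,
#' recruitment gain = sum over recruits of AGC_end/T, and
#' mortality loss = sum over dying stems of AGC_start/T. The net sink is
#' always gains minus losses.
#'
#' Two additive correction terms account for dynamics unobservable within
#' a census interval, both growing with T and vanishing as T -> 0:
#' (i) trees that died mid-interval grew, on average, for half of it at
#' the survivors' mean annual AGC increment, adding
#' `n_dead x mean_growth / 2` to both the growth gain and the mortality
#' loss; (ii) stems that recruited and died unobserved, expected at rate
#' `R x m x T / 2` per year (R the annual recruit count, m the annual
#' per-capita mortality rate), each valued at a threshold-size AGC, added
#' to both the recruitment gain and the mortality loss. Because each
#' correction enters a gain and the loss equally, the net flux - which is
#' pinned down by the observed stock change - is identical in the
#' corrected and uncorrected ledgers.
#'
#' @param series a [census_series] with >= 2 censuses.
#' @param agc per-stem AGC table from [stem_agc()] (columns `tag`,
#'   `census`, `alive`, `agc_kg`).
#' @param correct compute the interval corrections (default `TRUE`).
#' @param agc_recruit_kg AGC assigned to an unobserved recruit, kg;
#'   default is the median AGC of observed recruits (falling back to the
#'   smallest observed stem AGC when an interval has none).
#' @return object of class `carbon_ledger`: `stocks` (data.frame
#'   `census`, `date`, `agc_mg_ha`), `fluxes` (per interval, uncorrected
#'   and corrected gain_growth / gain_recruitment / loss_mortality / net),
#'   `overall` (time-weighted means over the whole record), `area_ha`.
#' @export
carbon_fluxes <- function(series, agc, correct = TRUE,
                          agc_recruit_kg = NULL) {
  k <- length(series$census_dates)
  if (k < 2) stop("carbon fluxes require at least 2 censuses", call. = FALSE)
  area <- series$area_ha
  kg2mgha <- function(x) x / 1000 / area

  stocks <- data.frame(census = seq_len(k), date = series$census_dates,
                       agc_mg_ha = vapply(seq_len(k), function(cc) {
                         a <- agc[agc$census == cc & agc$alive, , drop = FALSE]
                         kg2mgha(sum(a$agc_kg))
                       }, 0))

  flux <- lapply(seq_len(k - 1), function(cc) {
    T <- series$census_dates[cc + 1] - series$census_dates[cc]
    if (T <= 0) stop("non-positive census interval", call. = FALSE)
    a1 <- agc[agc$census == cc & agc$alive, , drop = FALSE]
    rec2 <- agc[agc$census == cc + 1, , drop = FALSE]
    a2 <- rec2[rec2$alive, , drop = FALSE]
    surv <- intersect(a1$tag, a2$tag)
    dead <- setdiff(a1$tag, surv)           # alive at cc, not alive at cc+1
    recruits <- setdiff(a2$tag, a1$tag)     # alive at cc+1, absent/new at cc

    g1 <- a1$agc_kg[match(surv, a1$tag)]
    g2 <- a2$agc_kg[match(surv, a2$tag)]
    gain_growth <- kg2mgha(sum(g2 - g1)) / T
    rec_agc <- a2$agc_kg[match(recruits, a2$tag)]
    gain_recruitment <- kg2mgha(sum(rec_agc)) / T
    loss_mortality <- kg2mgha(sum(a1$agc_kg[match(dead, a1$tag)])) / T

    corr_growth <- corr_recruit <- 0
    if (correct) {
      # mean survivor increment, clamped at 0 so corrections stay additive
      g_bar <- if (length(surv)) max(0, mean((g2 - g1) / T)) else 0
      corr_growth <- kg2mgha(length(dead) * g_bar / 2)
      m_a <- if (nrow(a1)) length(dead) / (nrow(a1) * T) else 0
      r_a <- length(recruits) / T
      a_min <- if (!is.null(agc_recruit_kg)) agc_recruit_kg
        else if (length(rec_agc)) stats::median(rec_agc)
        else if (nrow(a2)) min(a2$agc_kg) else 0
      corr_recruit <- kg2mgha(r_a * m_a * T / 2 * a_min)
    }
    data.frame(
      from = cc, to = cc + 1, years = T,
      gain_growth = gain_growth, gain_recruitment = gain_recruitment,
      loss_mortality = loss_mortality,
      net = gain_growth + gain_recruitment - loss_mortality,
      gain_growth_corr = gain_growth + corr_growth,
      gain_recruitment_corr = gain_recruitment + corr_recruit,
      loss_mortality_corr = loss_mortality + corr_growth + corr_recruit,
      net_corr = gain_growth + gain_recruitment - loss_mortality,
      n_survivors = length(surv), n_deaths = length(dead),
      n_recruits = length(recruits))
  })
  flux <- do.call(rbind, flux)

  tw <- function(col) sum(flux[[col]] * flux$years) / sum(flux$years)
  overall <- data.frame(
    years = sum(flux$years),
    gain_growth = tw("gain_growth"),
    gain_recruitment = tw("gain_recruitment"),
    loss_mortality = tw("loss_mortality"),
    net = tw("net"),
    gain_growth_corr = tw("gain_growth_corr"),
    gain_recruitment_corr = tw("gain_recruitment_corr"),
    loss_mortality_corr = tw("loss_mortality_corr"),
    net_corr = tw("net_corr"))

  structure(list(plot_id = series$plot_id, stocks = stocks, fluxes = flux,
                 overall = overall, area_ha = area, corrected = correct),
            class = "carbon_ledger")
}

#' @export
print.carbon_ledger <- function(x, ...) {
  cat(sprintf("<carbon_ledger> plot %s (%g ha)\n", x$plot_id, x$area_ha))
  cat("  stocks (Mg C/ha): ",
      paste(sprintf("%.1f", x$stocks$agc_mg_ha), collapse = " -> "), "\n")
  o <- x$overall
  cat(sprintf(
    "  fluxes (Mg C/ha/y): growth %+0.3f, recruitment %+0.3f, mortality -%0.3f, net %+0.3f\n",
    o$gain_growth, o$gain_recruitment, o$loss_mortality, o$net))
  invisible(x)
}

#' One-call carbon ledger for a plot
#'
#' Convenience wrapper: fits the plot height model from measured heights,
#' matches wood density, computes per-stem AGC and returns the
#' [carbon_fluxes()] ledger.
#'
#' @inheritParams stem_agc
#' @inheritParams carbon_fluxes
#' @export
carbon_ledger <- function(series, traits, correct = TRUE) {
  agc <- stem_agc(series, traits)
  carbon_fluxes(series, agc, correct = correct)
}
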
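#' Cross-sectional stem area
#'
#' Basal area of a stem from its diameter at 1.3 m (or above buttress):
#' pi (D/2)^2, in cm^2.
#'
#' @param diameter stem diameter(s), cm; must be positive.
#' @return basal area(s), cm^2.
#' @export
basal_area <- function(diameter) {
  if (any(is.na(diameter)) || any(diameter <= 0)) {
    stop("diameter must be positive", call. = FALSE)
  }
  pi * (diameter / 2)^2
}

# attribute value per stem; NA for species without the attribute
stem_attribute <- function(stems, affiliations, attribute) {
  if (!attribute %in% names(affiliations)) {
    stop("attribute '", attribute, "' not found in the affiliation table",
         call. = FALSE)
  }
  aff <- affiliations
  if ("included" %in% names(aff)) aff[[attribute]][!aff$included] <- NA
  aff[[attribute]][match(stems$species, aff$species)]
}

#' Community-weighted mean of a species attribute
#'
#' The community temperature index (CTI) of a set of stems is the weighted
#' mean of the species' thermal optima, with each stem weighted equally
#' (`weighting = "stem"`, CTI_Stem) or by its basal area
#' (`weighting = "ba"`, CTI_BA). The same machinery yields the community
#' precipitation index (attribute `"p_opt"`) or a community-weighted wood
#' density. Stems whose species lacks the attribute - below-threshold
#' species, stems not identified to species - are dropped and the weights
#' renormalized over the remainder; `coverage` reports the retained weight
#' fraction.
#'
#' @param stems data.frame of live stems (`species`, `diameter`).
#' @param affiliations species attribute table; rows with
#'   `included = FALSE` are treated as attribute-missing.
#' @param weighting `"stem"` or `"ba"`.
#' @param attribute column of `affiliations` to average (default `t_opt`).
#' @return list `value`, `coverage` (weight fraction of stems carrying the
#'   attribute), `n_stems`, `n_covered`, `weighting`, `attribute`. `value`
#'   is `NA` (with a warning) when no stem carries the attribute.
#' @export
community_index <- function(stems, affiliations,
                            weighting = c("stem", "ba"),
                            attribute = "t_opt") {
  weighting <- match.arg(weighting)
  a <- stem_attribute(stems, affiliations, attribute)
  w <- if (weighting == "ba") basal_area(stems$diameter) else
    rep(1, nrow(stems))
  ok <- !is.na(a)
  res <- list(value = NA_real_, coverage = 0, n_stems = nrow(stems),
              n_covered = sum(ok), weighting = weighting,
              attribute = attribute)
  if (!nrow(stems) || !any(ok)) {
    warning("no stem carries attribute '", attribute,
            "'; community index undefined", call. = FALSE)
    return(res)
  }
  res$value <- sum(w[ok] * a[ok]) / sum(w[ok])
  res$coverage <- sum(w[ok]) / sum(w)
  res
}

#' Community index per census and its annual rate of change
#'
#' Computes the index at every census of a plot and the annualized change
#' `(last - first) / (date_last - date_first)` - the thermophilization
#' rate when the attribute is `t_opt`. Per-interval changes between
#' consecutive censuses are also reported; the headline rate uses the
#' endpoints only.
#'
#' @param series a [census_series] with at least 2 censuses (for a rate).
#' @inheritParams community_index
#' @return object of class `index_trajectory`: list with `plot_id`,
#'   `values` (data.frame `census`, `date`, `value`, `coverage`),
#'   `annual_rate`, `interval` (years, first to last census),
#'   `interval_changes` (data.frame of per-interval annual rates),
#'   `weighting`, `attribute`.
#' @export
index_trajectory <- function(series, affiliations,
                             weighting = c("stem", "ba"),
                             attribute = "t_opt") {
  weighting <- match.arg(weighting)
  k <- length(series$census_dates)
  vals <- lapply(seq_len(k), function(cc) {
    ci <- suppressWarnings(
      community_index(stems_at(series, cc), affiliations, weighting, attribute))
    data.frame(census = cc, date = series$census_dates[cc],
               value = ci$value, coverage = ci$coverage)
  })
  vals <- do.call(rbind, vals)
  rate <- NA_real_
  interval <- if (k >= 2) diff(range(series$census_dates)) else NA_real_
  if (k >= 2 && !is.na(vals$value[1]) && !is.na(vals$value[k])) {
    rate <- (vals$value[k] - vals$value[1]) / interval
  }
  ic <- if (k >= 2) {
    data.frame(
      from = seq_len(k - 1), to = 2:k,
      years = diff(series$census_dates),
      annual_change = diff(vals$value) / diff(series$census_dates))
  } else {
    data.frame(from = integer(), to = integer(), years = numeric(),
               annual_change = numeric())
  }
  structure(list(plot_id = series$plot_id, values = vals,
                 annual_rate = rate, interval = interval,
                 interval_changes = ic, weighting = weighting,
                 attribute = attribute),
            class = "index_trajectory")
}

#' @export
print.index_trajectory <- function(x, ...) {
  cat(sprintf("<index_trajectory> plot %s, %s-weighted %s\n",
              x$plot_id, x$weighting, x$attribute))
  print(x$values, row.names = FALSE)
  cat(sprintf("  annual rate: %.6g per year over %.2f years\n",
              x$annual_rate, x$interval))
  invisible(x)
}

# stem sets for the demographic partition; survivor species identity is
# taken from the first census when determinations conflict across censuses
partition_sets <- function(series) {
  k <- length(series$census_dates)
  if (k < 2) stop("partition requires at least 2 censuses", call. = FALSE)
  first <- stems_at(series, 1)
  last <- stems_at(series, k)
  surv_tags <- intersect(first$tag, last$tag)
  surv_f <- first[first$tag %in% surv_tags, , drop = FALSE]
  surv_l <- last[last$tag %in% surv_tags, , drop = FALSE]
  surv_l$species <- surv_f$species[match(surv_l$tag, surv_f$tag)]
  list(alive_f = first, alive_l = last, surv_f = surv_f, surv_l = surv_l,
       interval = diff(range(series$census_dates)))
}

#' Demographic partition of community index change
#'
#' Decomposes the total change in a community index between the first and
#' last census into contributions of mortality, recruitment and (under
#' basal-area weighting) growth, using the four stem sets Alive_F (all
#' alive at the first census), Alive_L (all alive at the last), Survive_F
#' (survivors at first-census sizes) and Survive_L (survivors at
#' last-census sizes).
#'
#' With `method = "chain"` (default) the components are a telescoping
#' chain that sums exactly to the total change:
#' mortality `= I(Survive_F) - I(Alive_F)`, growth
#' `= I(Survive_L) - I(Survive_F)`, recruitment
#' `= I(Alive_L) - I(Survive_L)`. Under stem weighting the two survivor
#' indices coincide, so growth is exactly 0 and the familiar two-term
#' decomposition (mortality `= I(Survive) - I(Alive_F)`, recruitment
#' `= I(Alive_L) - I(Survive)`) is recovered.
#'
#' `method = "literal"` instead reports mortality
#' `= I(Survive_L) - I(Alive_F)` and recruitment
#' `= I(Alive_L) - I(Survive_F)` with no growth term; under basal-area
#' weighting those two terms fold survivor growth into both components and
#' need not sum to the total, so no additivity is asserted for it.
#'
#' @inheritParams index_trajectory
#' @param method `"chain"` (additive, default) or `"literal"`.
#' @param annualize divide all components by the census interval
#'   (default `FALSE`: components are index units over the full period).
#' @return list of class `partition_result`: `plot_id`, `weighting`,
#'   `attribute`, `method`, `total`, `mortality`, `recruitment`, `growth`,
#'   `interval`, `annualized`.
#' @export
partition_change <- function(series, affiliations,
                             weighting = c("stem", "ba"),
                             attribute = "t_opt",
                             method = c("chain", "literal"),
                             annualize = FALSE) {
  weighting <- match.arg(weighting)
  method <- match.arg(method)
  ps <- partition_sets(series)
  idx <- function(st) {
    suppressWarnings(
      community_index(st, affiliations, weighting, attribute)$value)
  }
  i_af <- idx(ps$alive_f); i_al <- idx(ps$alive_l)
  if (!nrow(ps$surv_f)) {
    warning("no survivors between first and last census; survivor indices missing",
            call. = FALSE)
    i_sf <- NA_real_; i_sl <- NA_real_
  } else {
    i_sf <- idx(ps$surv_f); i_sl <- idx(ps$surv_l)
  }
  total <- i_al - i_af
  if (method == "chain") {
    mortality <- i_sf - i_af
    growth <- if (weighting == "ba") i_sl - i_sf else 0
    recruitment <- if (weighting == "ba") i_al - i_sl else i_al - i_sf
  } else {
    mortality <- i_sl - i_af
    recruitment <- i_al - i_sf
    growth <- NA_real_
  }
  f <- if (annualize) 1 / ps$interval else 1
  structure(list(plot_id = series$plot_id, weighting = weighting,
                 attribute = attribute, method = method,
                 total = total * f, mortality = mortality * f,
                 recruitment = recruitment * f, growth = growth * f,
                 interval = ps$interval, annualized = annualize),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  unit <- if (x$annualized) "per year" else "over the period"
  cat(sprintf("<partition_result> plot %s, %s-weighted %s (%s, %s)\n",
              x$plot_id, x$weighting, x$attribute, x$method, unit))
  cat(sprintf("  total %+.6g = mortality %+.6g + recruitment %+.6g + growth %+.6g\n",
              x$total, x$mortality, x$recruitment,
              if (is.na(x$growth)) 0 else x$growth))
  invisible(x)
}

# unweighted mean of per-plot annual rates; plots with no defined rate
# are dropped consistently
mean_annual_rate <- function(series_list, affiliations, weighting, attribute) {
  rates <- vapply(series_list, function(s) {
    index_trajectory(s, affiliations, weighting, attribute)$annual_rate
  }, 0)
  mean(rates, na.rm = TRUE)
}

#' Jackknife species contributions to the community index trend
#'
#' Each species in turn is removed from every plot (its stems dropped
#' entirely) and the cross-plot mean annual index change recomputed. The
#' species' contribution is `(rate_without - rate_all) / rate_all`:
#' negative values mark species that strengthen the trend (the trend is
#' weaker without them), positive values species that damp it. A
#' signed-square-root transform (`sign(x) * sqrt(|x|)`) is returned
#' alongside, the usual variance-stabilizing scale for relating
#' contributions to species traits.
#'
#' @param series_list list of [census_series] (all plots).
#' @inheritParams community_index
#' @return data.frame `species`, `contribution`, `contribution_sqrt`,
#'   `rate_without`; attribute `rate_all`. Errors when the all-species
#'   cross-plot rate is exactly zero (contributions undefined).
#' @export
jackknife_contributions <- function(series_list, affiliations,
                                    weighting = c("stem", "ba"),
                                    attribute = "t_opt") {
  weighting <- match.arg(weighting)
  rate_all <- mean_annual_rate(series_list, affiliations, weighting, attribute)
  if (is.na(rate_all) || rate_all == 0) {
    stop("cross-plot mean annual rate is zero or undefined; ",
         "jackknife contributions are undefined", call. = FALSE)
  }
  present <- unique(unlist(lapply(series_list, function(s) s$stems$species)))
  sp <- sort(unique(affiliations$species))
  rows <- lapply(sp, function(s) {
    if (!s %in% present) {
      return(data.frame(species = s, contribution = 0,
                        contribution_sqrt = 0, rate_without = rate_all))
    }
    dropped <- lapply(series_list, function(cs) {
      cs$stems <- cs$stems[cs$stems$species != s, , drop = FALSE]
      cs
    })
    rw <- mean_annual_rate(dropped, affiliations, weighting, attribute)
    contrib <- (rw - rate_all) / rate_all
    data.frame(species = s, contribution = contrib,
               contribution_sqrt = sign(contrib) * sqrt(abs(contrib)),
               rate_without = rw)
  })
  out <- do.call(rbind, rows)
  attr(out, "rate_all") <- rate_all
  out
}

#' Distribution of stem thermal optima by size class
#'
#' Summarises stem-level attribute values in four diameter classes -
#' [10, 30), [30, 50), [50, 70) and >= 70 cm (half-open lower-inclusive
#' boundaries) - restricted to the first census of each plot so no stem is
#' counted twice. Stems whose species lacks the attribute are excluded.
#'
#' @param series_list a [census_series] or list of them.
#' @inheritParams community_index
#' @return data.frame `size_class`, `n`, `mean`, `sd` (empty classes kept
#'   with `n = 0`).
#' @export
size_class_summary <- function(series_list, affiliations,
                               attribute = "t_opt") {
  if (inherits(series_list, "census_series")) series_list <- list(series_list)
  stems <- do.call(rbind, lapply(series_list, stems_at, census = 1))
  a <- stem_attribute(stems, affiliations, attribute)
  d <- stems$diameter[!is.na(a)]
  a <- a[!is.na(a)]
  breaks <- c(10, 30, 50, 70, Inf)
  labs <- c("10-30", "30-50", "50-70", ">=70")
  cls <- cut(d, breaks, labels = labs, right = FALSE)
  out <- do.call(rbind, lapply(labs, function(L) {
    v <- a[!is.na(cls) & cls == L]
    data.frame(size_class = L, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  out
}
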
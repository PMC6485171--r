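## Covariate extrapolation 2011-2030.
##
## Each municipality-covariate series is projected by an exponential-trend
## model fitted to the previous decade (2000-2010):
##   value(t) = floor + (level_2010 - floor) * exp(-lambda * (t - 2010)),
## with lambda the least-squares slope of log(value - floor) on year. The
## sign of lambda is free, so growing series (urbanisation, GDP) are
## handled with a cap. National-level poverty recalibration rescales
## municipal values multiplicatively to hit survey/World Bank national
## means during the recession years.

#' Fit an exponential trend to a decade of observations
#'
#' Ordinary least squares of `log(value - floor)` on year across all
#' supplied points (not just the endpoints), giving the per-year rate
#' `lambda` and the fitted 2010 level. Series that are non-positive after
#' shifting off the floor cannot support a log-scale fit and return a
#' degenerate flat trend (`lambda = 0`, flagged).
#'
#' @param series Tibble (or data frame) with columns `year`, `value`;
#'   typically the 2000-2010 window.
#' @param floor,cap Bounds of the covariate (floor default 0; cap optional).
#' @param anchor_year Year at which the fitted level is reported
#'   (default 2010).
#' @return A one-row tibble of class `esf_trend`: `lambda`, `level`,
#'   `anchor_year`, `floor`, `cap`, `degenerate`.
#' @export
fit_decay_trend <- function(series, floor = 0, cap = NA_real_,
                            anchor_year = 2010) {
  check_columns(series, c("year", "value"), "series")
  if (!is.na(cap) && cap < floor) abort("cap must be >= floor")
  shifted <- series$value - floor
  ok <- is.finite(shifted) & shifted > 0
  if (sum(ok) < 2) {
    level <- if (any(is.finite(series$value))) {
      series$value[which.max(series$year)]
    } else {
      floor
    }
    out <- tibble(lambda = 0, level = level, anchor_year = anchor_year,
                  floor = floor, cap = cap, degenerate = TRUE)
    class(out) <- c("esf_trend", class(out))
    return(out)
  }
  t_rel <- series$year[ok] - anchor_year
  y <- log(shifted[ok])
  slope <- sum((t_rel - mean(t_rel)) * (y - mean(y))) /
    sum((t_rel - mean(t_rel))^2)
  intercept <- mean(y) - slope * mean(t_rel)
  out <- tibble(lambda = -slope, level = floor + exp(intercept),
                anchor_year = anchor_year, floor = floor, cap = cap,
                degenerate = FALSE)
  class(out) <- c("esf_trend", class(out))
  out
}

#' Extrapolate a fitted trend to future years
#'
#' `value(t) = floor + (level - floor) * exp(-lambda * (t - anchor_year))`,
#' clipped to `[floor, cap]`. Monotone in `t` whenever `lambda != 0`.
#'
#' @param trend An `esf_trend` from [fit_decay_trend()].
#' @param years Integer years to forecast (e.g. 2011:2030).
#' @return Tibble with `year`, `value`.
#' @export
extrapolate <- function(trend, years) {
  stopifnot(inherits(trend, "esf_trend"))
  v <- trend$floor +
    (trend$level - trend$floor) * exp(-trend$lambda * (years - trend$anchor_year))
  hi <- if (is.na(trend$cap)) Inf else trend$cap
  tibble(year = years, value = clip(v, trend$floor, hi))
}

#' Forecast all panel covariates beyond the fitting window
#'
#' Fits the exponential trend per municipality and covariate on the
#' 2000-2010 window and replaces/extends covariate values for
#' `forecast_years`. Fraction covariates are bounded in \[0,1\];
#' non-negative ones floored at 0; log-scale covariates are fitted on the
#' exponentiated (positive) scale and re-logged. Bolsa Familia coverage is
#' observed through 2016, so its forecast is re-anchored at the 2016 level
#' and applied from 2017 only.
#'
#' @param panel Municipal panel covering at least the fitting window.
#' @param targets Covariate metadata as in [default_covariate_targets()]
#'   (`covariate`, `kind` used).
#' @param fit_years Window used to estimate trends (default 2000:2010).
#' @param forecast_years Years to fill (default 2011:2030).
#' @return The panel extended to `forecast_years` (rows created where
#'   absent; population extrapolated at its own fitted trend, coverage and
#'   doctors carried forward from the last observed year).
#' @export
forecast_covariates <- function(panel, targets = default_covariate_targets(),
                                fit_years = 2000:2010,
                                forecast_years = 2011:2030) {
  check_columns(panel, c("muni_id", "year", "population",
                         targets$covariate), "panel")
  panel <- panel %>% arrange(.data$muni_id, .data$year)
  last_obs <- max(panel$year)
  new_years <- setdiff(forecast_years, panel$year)

  carry <- panel %>% filter(.data$year == last_obs)
  if (length(new_years) > 0) {
    ext <- tidyr::expand_grid(muni_id = unique(panel$muni_id),
                              year = new_years) %>%
      left_join(carry %>% select(-"year"), by = "muni_id")
    # carried-forward death counts are not observations
    for (dc in grep("^deaths_", names(ext), value = TRUE)) ext[[dc]] <- NA_integer_
    panel <- bind_rows(panel, ext) %>% arrange(.data$muni_id, .data$year)
  }

  ids <- sort(unique(panel$muni_id))
  years_all <- sort(unique(panel$year))
  ny <- length(years_all)
  if (nrow(panel) != length(ids) * ny) {
    abort("forecast_covariates requires a balanced panel (one row per municipality-year)")
  }

  # masked per-column OLS slope of log(value) on year; columns without
  # >= 2 positive points get a degenerate flat trend (lambda 0)
  masked_trend <- function(W, yrs, anchor) {
    logW <- suppressWarnings(log(W))
    valid <- is.finite(logW)
    logW[!valid] <- 0
    t_rel <- yrs - anchor
    nv <- colSums(valid)
    st <- colSums(valid * t_rel)
    sy <- colSums(logW)
    stt <- colSums(valid * t_rel^2)
    sty <- colSums(logW * t_rel)
    denom <- nv * stt - st^2
    ok <- nv >= 2 & denom > 0
    slope <- ifelse(ok, (nv * sty - st * sy) / pmax(denom, 1e-300), 0)
    inter <- ifelse(ok, (sy - slope * st) / pmax(nv, 1), 0)
    last_val <- W[nrow(W), ]
    list(lambda = -slope,
         level = ifelse(ok, exp(inter), ifelse(is.finite(last_val), last_val, 0)),
         degenerate = !ok)
  }

  fit_idx <- which(years_all %in% fit_years)
  for (j in seq_len(nrow(targets))) {
    nm <- targets$covariate[j]
    kind <- targets$kind[j]
    cap <- if (kind == "fraction") 1 else Inf
    anchor <- if (nm == "bfp_coverage") min(last_obs, 2016) else max(fit_years)
    fill_years <- forecast_years[forecast_years > anchor]
    if (length(fill_years) == 0) next
    M <- matrix(panel[[nm]], nrow = ny)  # years x municipalities
    natural <- if (kind == "log") exp(M) else M
    tr <- masked_trend(natural[fit_idx, , drop = FALSE],
                       years_all[fit_idx], max(fit_years))
    lvl <- if (anchor == max(fit_years)) {
      tr$level
    } else {
      natural[which(years_all == anchor), ]
    }
    for (yr in fill_years) {
      v <- clip(lvl * exp(-tr$lambda * (yr - anchor)), 0, cap)
      M[which(years_all == yr), ] <- if (kind == "log") log(pmax(v, 1e-12)) else v
    }
    panel[[nm]] <- as.vector(M)
  }

  # population keeps growing at its fitted per-municipality trend
  pop_years <- forecast_years[forecast_years > last_obs]
  if (length(pop_years) > 0) {
    P <- matrix(panel$population, nrow = ny)
    obs_idx <- which(years_all <= last_obs)
    tr <- masked_trend(P[obs_idx, , drop = FALSE], years_all[obs_idx], last_obs)
    lvl <- P[which(years_all == last_obs), ]
    for (yr in pop_years) {
      P[which(years_all == yr), ] <- pmax(round(lvl * exp(-tr$lambda * (yr - last_obs))), 1)
    }
    panel$population <- P[cbind(match(panel$year, years_all), match(panel$muni_id, ids))]
  }
  panel
}

#' Default national poverty calibration path
#'
#' Linear interpolation through the published national poverty means for
#' 2015 (13.8%), 2020 (18.4%, recession peak) and 2030 (12.0%), starting
#' from the 2010 panel level. Used as the recession-scenario default for
#' [calibrate_national()].
#' @param start_2011 Poverty level assumed for 2011 (default 0.15).
#' @export
default_poverty_path <- function(start_2011 = 0.15) {
  anchors <- tibble(year = c(2011, 2015, 2020, 2030),
                    target = c(start_2011, 0.138, 0.184, 0.120))
  years <- 2011:2030
  tibble(year = years,
         target = stats::approx(anchors$year, anchors$target, xout = years)$y)
}

#' Rescale a covariate to national calibration targets
#'
#' For each year in the path, every municipality's value is multiplied by
#' `target / current population-weighted national mean`, then clipped to
#' \[0,1\]. Because clipping can pull the mean back off target, the rescale
#' is iterated to a fixed point (at most 8 passes), leaving the national
#' mean within half a percentage point of the target whenever feasible.
#' Idempotent up to clipping.
#'
#' @param panel Municipal panel containing `covariate` and `population`.
#' @param path Tibble with columns `year`, `target` (targets in \[0,1\]).
#' @param covariate Covariate to calibrate (default `"poverty_rate"`).
#' @return The recalibrated panel.
#' @export
calibrate_national <- function(panel, path, covariate = "poverty_rate") {
  check_columns(panel, c("year", "population", covariate), "panel")
  check_columns(path, c("year", "target"), "path")
  if (any(path$target < 0 | path$target > 1)) {
    abort("calibration targets must lie in [0, 1]")
  }
  absent <- setdiff(path$year, unique(panel$year))
  if (length(absent) > 0) {
    abort(sprintf("calibration years absent from panel: %s",
                  paste(absent, collapse = ", ")))
  }
  for (k in seq_len(nrow(path))) {
    yr <- path$year[k]
    tg <- path$target[k]
    idx <- panel$year == yr
    for (pass in seq_len(8)) {
      cur <- wmean(panel[[covariate]][idx], panel$population[idx])
      if (cur <= 0) break
      if (abs(cur - tg) < 1e-10) break
      panel[[covariate]][idx] <- clip(panel[[covariate]][idx] * tg / cur, 0, 1)
    }
  }
  panel
}
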
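## Calibration, internal/external validation, sensitivity harness.
##
## Internal validation refits the generating fixed-effects Poisson
## log-linear regression on simulated death counts and checks that the
## fitted coefficients equal the inputs. The fitter maximises the
## concentrated likelihood: municipality intercepts are profiled out
## analytically (alpha_i(beta) = log(D_i / sum_t mu_it)), leaving a
## Newton iteration in the slope coefficients only, with the slope
## covariance taken from the Schur complement of the full Hessian (so the
## profiling is accounted for). This is the exact dummy-variable MLE
## without materialising thousands of indicator columns.

#' Fixed-effects Poisson regression (concentrated likelihood)
#'
#' Fits `deaths ~ Poisson(exp(alpha_g + X beta + offset))` with one free
#' intercept per group, by Newton iteration on the concentrated
#' log-likelihood. Groups whose deaths are all zero have `alpha = -Inf`
#' and drop out of the likelihood.
#'
#' @param X Numeric design matrix (columns must be named).
#' @param deaths Non-negative counts (one per row of `X`).
#' @param offset Log person-years offset per row.
#' @param group Group (municipality) identifier per row.
#' @param tol Convergence tolerance on the max absolute score.
#' @param max_iter Newton iteration cap.
#' @return An object of class `esf_fe_fit`: coefficients, `vcov`
#'   (Schur-corrected), group intercepts, log-likelihood, convergence
#'   info.
#' @export
fit_fe_poisson <- function(X, deaths, offset, group, tol = 1e-10,
                           max_iter = 50) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) abort("design matrix columns must be named")
  g <- factor(group)
  D <- as.vector(rowsum(deaths, g))
  keep_g <- levels(g)[D > 0]
  keep <- g %in% keep_g
  if (!any(keep)) abort("all groups have zero deaths; nothing to fit")
  Xk <- X[keep, , drop = FALSE]
  dk <- deaths[keep]
  offk <- offset[keep]
  gk <- droplevels(g[keep])
  Dk <- as.vector(rowsum(dk, gk))

  p <- ncol(Xk)
  beta <- rep(0, p)
  gi <- as.integer(gk)

  eval_state <- function(beta) {
    eta0 <- as.vector(Xk %*% beta) + offk
    denom <- as.vector(rowsum(exp(eta0), gk))
    alpha <- log(Dk / denom)
    mu <- exp(alpha[gi] + eta0)
    ll <- sum(dk * (alpha[gi] + eta0) - mu)
    list(alpha = alpha, mu = mu, ll = ll)
  }

  st <- eval_state(beta)
  converged <- FALSE
  iter <- 0
  H <- NULL
  repeat {
    iter <- iter + 1
    score <- as.vector(crossprod(Xk, dk - st$mu))
    A <- rowsum(Xk * st$mu, gk)                       # groups x p
    Dw <- as.vector(rowsum(st$mu, gk))                # sum_t mu per group
    H <- crossprod(Xk * sqrt(st$mu)) - crossprod(A / sqrt(Dw))
    if (max(abs(score)) < tol || iter > max_iter) {
      converged <- max(abs(score)) < tol
      break
    }
    step <- tryCatch(solve(H, score), error = function(e) {
      abort("singular concentrated Hessian: collinear covariates")
    })
    # step halving if the concentrated likelihood does not improve
    sfac <- 1
    repeat {
      cand <- eval_state(beta + sfac * step)
      if (cand$ll >= st$ll - 1e-12 || sfac < 1e-4) break
      sfac <- sfac / 2
    }
    beta <- beta + sfac * step
    st <- cand
  }
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(Xk), colnames(Xk))
  structure(
    list(coefficients = setNames(beta, colnames(Xk)), vcov = vc,
         alpha = setNames(st$alpha, levels(gk)),
         dropped_groups = setdiff(levels(g), levels(gk)),
         loglik = st$ll, niter = iter, converged = converged,
         nobs = sum(keep), n_groups = nlevels(gk)),
    class = "esf_fe_fit"
  )
}

#' @export
tidy.esf_fe_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(se),
         conf.low = unname(x$coefficients - z * se),
         conf.high = unname(x$coefficients + z * se))
}

#' @export
glance.esf_fe_fit <- function(x, ...) {
  tibble(nobs = x$nobs, n_groups = x$n_groups, logLik = x$loglik,
         niter = x$niter, converged = x$converged)
}

#' @export
print.esf_fe_fit <- function(x, ...) {
  cat("<esf_fe_fit> fixed-effects Poisson,", x$n_groups, "groups,",
      x$nobs, "obs\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Calibrate the secular-trend coefficient to an observed rate series
#'
#' Finds the per-year log-rate drift `gamma` that minimises the sum of
#' squared differences between log national mean predicted rates and the
#' log observed series over the calibration window, re-anchoring the
#' municipality fixed effects at each candidate. Observed rates are first
#' adjusted for undernotification (multiplicative factor >= 1).
#'
#' @param panel Panel with observed deaths for the window.
#' @param table [effect_table()].
#' @param observed Tibble `year`, `rate` (national mean ACSC rate).
#' @param stratum Outcome stratum calibrated (default `acsc_total`).
#' @param window Calibration years (default 2010:2015).
#' @param undernotification Multiplicative correction applied to the
#'   observed rates (scalar or one factor per observed year; >= 1).
#' @param interval Search interval for `gamma`.
#' @return List of class `esf_calibration`: `gamma`, the updated effect
#'   `table`, and the achieved `sse`.
#' @export
calibrate_secular_trend <- function(panel, table, observed,
                                    stratum = "acsc_total",
                                    window = 2010:2015,
                                    undernotification = 1,
                                    interval = c(-0.2, 0.2)) {
  check_columns(observed, c("year", "rate"), "observed series")
  obs <- observed %>% filter(.data$year %in% window)
  if (nrow(obs) < 2) abort("need >= 2 observed years in the window")
  if (any(obs$rate <= 0)) abort("observed rates must be positive")
  if (any(undernotification < 1)) abort("undernotification factors must be >= 1")
  adj <- obs$rate * undernotification
  panel <- panel %>% arrange(.data$muni_id, .data$year)
  rows <- panel %>% filter(.data$year %in% obs$year)
  dur_all <- coverage_duration(panel$muni_id, panel$esf_coverage)
  dur <- dur_all[panel$year %in% obs$year]

  objective <- function(gamma) {
    tb <- set_gamma(table, stratum, gamma)
    fe <- estimate_fixed_effects(panel, tb, stratum, window = window)
    r <- expected_rate(rows, tb, stratum, fe, duration = dur)
    pred <- tapply(r, factor(rows$year, levels = obs$year), mean)
    sum((log(pred) - log(adj))^2)
  }
  opt <- optimize(objective, interval = interval, tol = 1e-9)
  structure(list(gamma = opt$minimum,
                 table = set_gamma(table, stratum, opt$minimum),
                 sse = opt$objective),
            class = "esf_calibration")
}

set_gamma <- function(table, stratum, gamma) {
  table$strata$gamma[table$strata$stratum == stratum] <- gamma
  table
}

#' Internal validation: recover the input coefficients from simulated data
#'
#' Refits the fixed-effects Poisson regression (municipality intercepts,
#' the model covariates, the coverage-duration term and the time trend)
#' on a simulated panel and compares every fitted log rate ratio with the
#' value introduced as input.
#'
#' @param panel Simulated panel with `deaths_<stratum>` for the fitted
#'   years (plus coverage history for duration tracking).
#' @param table The generating [effect_table()].
#' @param stratum Outcome stratum.
#' @param years Years fitted (default 2017:2030).
#' @inheritParams coverage_effect
#' @return List of class `esf_internal_validation`: `report` tibble
#'   (`term`, `input`, `estimate`, `std.error`, `conf.low`, `conf.high`,
#'   `covered`), `max_abs_dev`, and the underlying `fit`.
#' @export
internal_validation <- function(panel, table, stratum,
                                years = 2017:2030,
                                parameterization = "continuous") {
  dcol <- paste0("deaths_", stratum)
  check_columns(panel, c("muni_id", "year", "population", "esf_coverage",
                         dcol, table$covariates$covariate), "panel")
  panel <- panel %>% arrange(.data$muni_id, .data$year)
  dur_all <- coverage_duration(panel$muni_id, panel$esf_coverage)
  sel <- panel$year %in% years & !is.na(panel[[dcol]])
  rows <- panel[sel, ]
  dur <- dur_all[sel]
  w <- if (parameterization == "categorical") {
    ifelse(rows$esf_coverage < 0.7, 0,
           ifelse(dur < table$duration_lag, 0.5, 1))
  } else {
    rows$esf_coverage * pmin(dur / table$duration_lag, 1)
  }
  X <- cbind(as.matrix(rows[, table$covariates$covariate]),
             coverage_term = w, time = rows$year - 2010)
  py <- stratum_person_years(rows, stratum)
  fit <- fit_fe_poisson(X, rows[[dcol]], offset = log(py / 1e5),
                        group = rows$muni_id)
  srow <- stratum_row(table, stratum)
  inputs <- c(log(table$covariates$rr), log(srow$rr_full), srow$gamma)
  names(inputs) <- colnames(X)
  td <- tidy(fit)
  report <- td %>%
    mutate(input = unname(inputs[.data$term]),
           covered = .data$input >= .data$conf.low &
             .data$input <= .data$conf.high) %>%
    select("term", "input", "estimate", "std.error",
           "conf.low", "conf.high", "covered")
  structure(list(report = report,
                 max_abs_dev = max(abs(report$estimate - report$input)),
                 fit = fit),
            class = "esf_internal_validation")
}

#' @export
tidy.esf_internal_validation <- function(x, ...) x$report

#' @export
glance.esf_internal_validation <- function(x, ...) {
  tibble(max_abs_dev = x$max_abs_dev,
         frac_covered = mean(x$report$covered),
         converged = x$fit$converged)
}

#' External validation against an observed rate series
#'
#' Ordinary least squares of the observed series on the predicted one
#' over overlapping years: slope, intercept, R-squared, and the fraction
#' of observed points inside the predicted 95% credible band (when the
#' prediction carries `ci_lo`/`ci_hi`).
#'
#' @param predicted Tibble `year`, `rate` and optionally `ci_lo`, `ci_hi`.
#' @param observed Tibble `year`, `rate`.
#' @return One-row tibble of class `esf_external_validation`: `slope`,
#'   `intercept`, `r_squared`, `frac_in_ci`, `n_years`, `flagged`.
#' @export
external_validation <- function(predicted, observed) {
  check_columns(predicted, c("year", "rate"), "predicted")
  check_columns(observed, c("year", "rate"), "observed")
  j <- dplyr::inner_join(
    predicted %>% rename(pred = "rate"),
    observed %>% select("year", obs = "rate"),
    by = "year"
  )
  if (nrow(j) == 0) abort("no overlapping years")
  flagged <- nrow(j) < 3
  if (flagged) {
    warn("fewer than 3 overlapping years: R-squared undefined")
    fitstats <- list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_)
  } else {
    m <- lm(obs ~ pred, data = j)
    fitstats <- list(slope = unname(coef(m)[2]),
                     intercept = unname(coef(m)[1]),
                     r2 = summary(m)$r.squared)
  }
  frac <- if (all(c("ci_lo", "ci_hi") %in% names(j))) {
    mean(j$obs >= j$ci_lo & j$obs <= j$ci_hi)
  } else {
    NA_real_
  }
  out <- tibble(slope = fitstats$slope, intercept = fitstats$intercept,
                r_squared = fitstats$r2, frac_in_ci = frac,
                n_years = nrow(j), flagged = flagged)
  class(out) <- c("esf_external_validation", class(out))
  out
}

#' Sensitivity-analysis harness
#'
#' Reruns the pipeline under each variant of a sensitivity axis with a
#' shared seed and collects the headline outputs (2030 scenario rate
#' ratios versus the status quo and 2017-2030 excess deaths). For the
#' `decline_magnitude` axis the dose-response ordering (larger coverage
#' declines, higher mortality) is checked and a warning raised if it is
#' violated; variants that fail outright are reported with an `error`
#' column, not dropped.
#'
#' @param config Pipeline configuration ([default_config()] /
#'   [load_config()]).
#' @param grid List with elements `axis` (one of `decline_magnitude`,
#'   `duration_effect`, `poverty_stratified_effect`, `recession_path`,
#'   `secular_trend`) and `variants`, a named list of configuration
#'   overrides (>= 2 variants).
#' @return Tibble with one row per variant: headline metrics and an
#'   `error` column; attribute `dose_response_ok` for the decline axis.
#' @export
run_sensitivity <- function(config, grid) {
  axes <- c("decline_magnitude", "duration_effect",
            "poverty_stratified_effect", "recession_path", "secular_trend")
  if (!is.list(grid) || is.null(grid$axis) || is.null(grid$variants)) {
    abort("grid must be a list with elements 'axis' and 'variants'")
  }
  if (!grid$axis %in% axes) {
    abort(sprintf("unknown sensitivity axis '%s'", grid$axis))
  }
  if (length(grid$variants) < 2) abort("a sensitivity axis needs >= 2 variants")
  variants <- grid$variants
  if (is.null(names(variants)) || any(names(variants) == "")) {
    names(variants) <- paste0("variant_", seq_along(variants))
  }
  rows <- lapply(names(variants), function(vn) {
    cfg <- merge_config(config, variants[[vn]])
    res <- tryCatch(run_pipeline(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      return(tibble(variant = vn, ratio_austerity = NA_real_,
                    ratio_austerity_mmp_end = NA_real_,
                    excess_austerity = NA_real_,
                    excess_austerity_mmp_end = NA_real_,
                    error = conditionMessage(res)))
    }
    tibble(
      variant = vn,
      ratio_austerity = res$ratios$estimate[
        res$ratios$comparison == "austerity vs status_quo" &
          res$ratios$year == 2030],
      ratio_austerity_mmp_end = res$ratios$estimate[
        res$ratios$comparison == "austerity_mmp_end vs status_quo" &
          res$ratios$year == 2030],
      excess_austerity = res$excess$estimate[
        res$excess$comparison == "austerity vs status_quo"],
      excess_austerity_mmp_end = res$excess$estimate[
        res$excess$comparison == "austerity_mmp_end vs status_quo"],
      error = NA_character_
    )
  })
  out <- bind_rows(rows)
  if (grid$axis == "decline_magnitude" && !anyNA(out$ratio_austerity)) {
    sev <- vapply(variants, function(v) {
      s <- tryCatch(v$scenarios$decline_severity, error = function(e) NULL)
      if (is.null(s)) NA_real_ else s
    }, numeric(1))
    if (!anyNA(sev)) {
      ok <- all(diff(out$ratio_austerity[order(sev)]) > 0)
      attr(out, "dose_response_ok") <- ok
      if (!ok) warn("dose-response ordering violated on the decline_magnitude axis")
    }
  }
  out
}
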
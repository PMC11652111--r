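#' Fit a quasi-Poisson log-link regression
#'
#' The workhorse of the gradient/determinant analyses: a single-predictor
#' generalized linear model with log link and quasi-Poisson dispersion
#' (estimated by the Pearson statistic), fitted by iteratively reweighted
#' least squares. Reported "explanatory power" is the deviance pseudo-R^2,
#' 1 - residual deviance / null deviance; the squared Pearson correlation
#' of fitted vs observed is also carried along for comparison. The slope
#' p-value is a t-test with dispersion-scaled standard error.
#'
#' @param x Numeric predictor.
#' @param y Non-negative counts (non-integer values tolerated with a
#'   warning).
#' @param response,predictor Names recorded in the output.
#' @return A `trend_fit` object; see [tidy.trend_fit()].
#' @export
fit_quasipoisson <- function(x, y, response = "y", predictor = "x") {
  n <- length(y)
  if (n < 3L) abort("need at least 3 observations")
  if (length(x) != n) abort("x and y lengths differ")
  if (any(!is.finite(y)) || any(y < 0)) abort("y must be non-negative and finite")
  if (all(y == 0)) abort("all responses are zero; quasi-Poisson fit undefined")
  if (!is_count_vector(y)) warn("non-integer responses; fitting quasi-Poisson anyway")
  fit <- glm(y ~ x, family = quasipoisson(link = "log"),
             control = list(maxit = 100))
  if (!fit$converged) abort(paste0("IRLS did not converge in 100 iterations ",
                                   "(deviance ", format(fit$deviance), ")"))
  new_trend_fit(fit, response, predictor, family = "quasipoisson", n = n)
}

#' Fit an ordinary least-squares (gaussian) trend
#'
#' Used where the response is real-valued (e.g. NRI), with R^2 and the
#' slope t-test from the standard linear model.
#'
#' @inheritParams fit_quasipoisson
#' @param y Numeric response.
#' @return A `trend_fit` object.
#' @export
fit_gaussian <- function(x, y, response = "y", predictor = "x") {
  n <- length(y)
  if (n < 3L) abort("need at least 3 observations")
  if (length(x) != n) abort("x and y lengths differ")
  fit <- lm(y ~ x)
  new_trend_fit(fit, response, predictor, family = "gaussian", n = n)
}

new_trend_fit <- function(fit, response, predictor, family, n) {
  cf <- summary(fit)$coefficients
  slope <- if (nrow(cf) >= 2) cf[2, 1] else 0
  p <- if (nrow(cf) >= 2) cf[2, 4] else NA_real_
  if (family == "quasipoisson") {
    null_dev <- fit$null.deviance
    r2 <- if (null_dev > 0) 1 - fit$deviance / null_dev else 0
    disp <- summary(fit)$dispersion
  } else {
    r2 <- summary(fit)$r.squared
    disp <- summary(fit)$sigma^2
  }
  yobs <- fit$model[[1]]
  pr2 <- if (var(fitted(fit)) > 0 && var(yobs) > 0) {
    cor(fitted(fit), yobs)^2
  } else 0
  structure(list(response = response, predictor = predictor, family = family,
                 slope = slope, intercept = coef(fit)[[1]],
                 pseudo_r2 = max(0, min(1, r2)), pearson_r2 = pr2,
                 p_value = p, dispersion = disp, n = n, fit = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(x$family, " trend: ", x$response, " ~ ", x$predictor,
      "  slope = ", format(x$slope, digits = 4),
      ", R2 = ", format(x$pseudo_r2, digits = 3),
      ", p = ", format(x$p_value, digits = 3),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Tidy a trend fit into a one-row tibble
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return Tibble with `response`, `predictor`, `family`, `slope`,
#'   `pseudo_r2`, `pearson_r2`, `p_value`, `n`.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(response = x$response, predictor = x$predictor,
                 family = x$family, slope = x$slope,
                 pseudo_r2 = x$pseudo_r2, pearson_r2 = x$pearson_r2,
                 p_value = x$p_value, n = x$n)
}

#' One-line model summary of a trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return Tibble with fit-level statistics (dispersion, deviances where
#'   applicable).
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  out <- tibble::tibble(family = x$family, pseudo_r2 = x$pseudo_r2,
                        dispersion = x$dispersion, n = x$n)
  if (x$family == "quasipoisson") {
    out$null_deviance <- x$fit$null.deviance
    out$deviance <- x$fit$deviance
  }
  out
}

#' Species richness vs belt area
#'
#' Quasi-Poisson fit of per-belt species richness on belt area (km^2), the
#' test of the area hypothesis for a richness gradient.
#'
#' @param profile A [diversity_profile()] (or [belt_richness()]) tibble with
#'   `sr` and `area_km2` columns.
#' @return A `trend_fit`.
#' @export
richness_area_fit <- function(profile) {
  if (!"area_km2" %in% names(profile)) {
    abort("belt areas not attached; run attach_areas() before the area fit")
  }
  fit_quasipoisson(profile$area_km2, profile$sr,
                   response = "sr", predictor = "area_km2")
}

#' Correlation of native and non-native richness across belts
#'
#' Pearson correlation of belt-level native vs non-native species richness,
#' testing whether the two groups follow the same elevational pattern.
#'
#' @param matrix A `belt_matrix`.
#' @param status Tibble `(taxon, native_status)` or `(accepted_name,
#'   native_status)` labelling every matrix taxon.
#' @return One-row tibble: `mountain_id`, `r`, `p_value`, `n` (belts with
#'   at least one species), `flag` (`"ok"` or `"zero_variance"`, in which
#'   case `r` is `NA`).
#' @export
native_nonnative_correlation <- function(matrix, status) {
  status <- tibble::as_tibble(status)
  if ("accepted_name" %in% names(status) && !"taxon" %in% names(status)) {
    status <- dplyr::rename(status, taxon = "accepted_name")
  }
  lab <- status$native_status[match(matrix$taxa, status$taxon)]
  if (anyNA(lab)) abort("native_status missing for some matrix taxa")
  native_sr <- rowSums(matrix$presence[, lab == "native", drop = FALSE])
  nonnat_sr <- rowSums(matrix$presence[, lab == "non_native", drop = FALSE])
  keep <- (native_sr + nonnat_sr) > 0
  native_sr <- native_sr[keep]; nonnat_sr <- nonnat_sr[keep]
  if (sum(keep) < 3L) abort("need at least 3 non-empty belts")
  if (var(native_sr) == 0 || var(nonnat_sr) == 0) {
    return(tibble::tibble(mountain_id = matrix$mountain_id, r = NA_real_,
                          p_value = NA_real_, n = sum(keep),
                          flag = "zero_variance"))
  }
  ct <- cor.test(native_sr, nonnat_sr, method = "pearson")
  tibble::tibble(mountain_id = matrix$mountain_id,
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n = sum(keep), flag = "ok")
}

#' Trend of phylogenetic structure along the gradient
#'
#' Ordinary least-squares fit of NRI on belt midpoint elevation (NRI is
#' real-valued, so a gaussian fit is used even though count responses
#' elsewhere get quasi-Poisson GLMs). The mountain is classified at
#' alpha = 0.05 as `clustering_increasing` (significant positive slope:
#' more clustered with elevation), `clustering_decreasing`, or `flat`.
#'
#' @param profile An [nri_profile()] tibble.
#' @return A `trend_fit` with an extra `trend` element.
#' @export
nri_trend <- function(profile) {
  ok <- profile$evaluable & is.finite(profile$nri)
  if (sum(ok) < 3L) abort("need at least 3 evaluable belts")
  fit <- fit_gaussian(profile$midpoint[ok], profile$nri[ok],
                      response = "nri", predictor = "midpoint")
  fit$trend <- if (!is.finite(fit$p_value) || fit$p_value >= 0.05) "flat"
               else if (fit$slope > 0) "clustering_increasing"
               else "clustering_decreasing"
  fit
}

#' Phylogenetic structure vs species richness
#'
#' Gaussian fit of per-belt NRI on per-belt species richness (the
#' taxon-scale relationship of community phylogenetic structure).
#'
#' @param nri_profile An [nri_profile()] tibble.
#' @param profile A [diversity_profile()] tibble for the same mountain.
#' @return A `trend_fit`.
#' @export
nri_richness_fit <- function(nri_profile, profile) {
  sr <- profile$sr[match(nri_profile$belt, profile$belt)]
  ok <- nri_profile$evaluable & is.finite(nri_profile$nri) & is.finite(sr)
  if (sum(ok) < 3L) abort("need at least 3 evaluable belts")
  fit_gaussian(sr[ok], nri_profile$nri[ok], response = "nri", predictor = "sr")
}

#' Elevation of the richness peak
#'
#' Midpoint of the belt with maximal species richness; ties resolve to the
#' lowest such belt. Invariant to adding a constant to all richness values.
#'
#' @param profile A tibble with `midpoint` and `sr` (ascending belts).
#' @return Numeric elevation in metres.
#' @export
peak_elevation <- function(profile) {
  if (nrow(profile) == 0L) abort("empty richness profile")
  ord <- order(profile$midpoint)
  sr <- profile$sr[ord]
  profile$midpoint[ord][which.max(sr)]
}

#' Determinants of the diversity peak across mountains
#'
#' One single-predictor fit of peak elevation per mountain attribute
#' (relative elevation, longitude, annual mean temperature, annual
#' precipitation). The default family follows the count-regression
#' convention of the source analyses (quasi-Poisson, log link); a gaussian
#' fit is available since peak elevations are not counts. No
#' multiple-testing correction is applied across the four predictors (none
#' was in the original analysis); `p_adjusted = "none"` is recorded.
#'
#' @param peaks Tibble `(mountain_id, peak_m)` with at least 4 mountains.
#' @param attributes Tibble with `mountain_id`, `relative_elevation_m`,
#'   `longitude_deg`, `amt_c`, `ap_mm`.
#' @param family `"quasipoisson"` (default) or `"gaussian"`.
#' @return Tibble of tidied fits, one row per predictor, plus a
#'   `p_adjusted` column.
#' @export
peak_determinants <- function(peaks, attributes,
                              family = c("quasipoisson", "gaussian")) {
  family <- match.arg(family)
  dat <- dplyr::inner_join(tibble::as_tibble(peaks),
                           tibble::as_tibble(attributes), by = "mountain_id")
  if (nrow(dat) < 4L) abort("need at least 4 mountains")
  predictors <- c("relative_elevation_m", "longitude_deg", "amt_c", "ap_mm")
  predictors <- intersect(predictors, names(dat))
  fits <- purrr::map_dfr(predictors, function(p) {
    f <- if (family == "quasipoisson") {
      suppressWarnings(fit_quasipoisson(dat[[p]], dat$peak_m,
                                        response = "peak_m", predictor = p))
    } else {
      fit_gaussian(dat[[p]], dat$peak_m, response = "peak_m", predictor = p)
    }
    tidy(f)
  })
  fits$p_adjusted <- "none"
  fits
}
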
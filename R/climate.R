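#' Bioclim variables handled by the climate module
#'
#' Temperature variables (Bio1 annual mean, Bio5 max of warmest month,
#' Bio6 min of coldest month) are modelled as linear lapse functions of
#' elevation and always accepted; precipitation variables (Bio12, Bio13,
#' Bio14, Bio18, Bio19) may need curvature, so polynomial degrees 1-3 are
#' compared and the fit is only accepted when it clears an adjusted-R2
#' threshold.
#' @export
BIO_VARIABLES <- c("bio1", "bio5", "bio6", "bio12", "bio13", "bio14",
                   "bio18", "bio19")

#' @rdname BIO_VARIABLES
#' @export
BIO_TEMPERATURE <- c("bio1", "bio5", "bio6")

.norm_bio <- function(variable) {
  v <- tolower(variable)
  if (!v %in% BIO_VARIABLES)
    stop("unknown Bioclim variable '", variable, "'")
  v
}

#' Fit a per-gradient elevation-to-climate calibration model
#'
#' Least-squares polynomial regression of a Bioclim value on elevation.
#' Temperature variables are fitted as straight-line lapse models and are
#' always accepted. For precipitation, degrees 1-3 are fitted (subject to
#' enough points) and the degree with the highest adjusted R2 is selected
#' (or, with `select = "aicc"`, the lowest AICc); the model is accepted
#' only when its adjusted R2 exceeds `threshold`, so noisy calibrations
#' are excluded from downstream use.
#'
#' @param points Data frame with columns `elevation_m` and `value`.
#' @param variable Bioclim variable name (e.g. `"bio1"`, `"bio12"`).
#' @param threshold Adjusted-R2 acceptance cutoff for precipitation
#'   variables. Default 0.5.
#' @param gradient_id Optional gradient identifier carried in the model.
#' @param select Degree-selection rule for precipitation: maximize
#'   `"adj_r2"` (default) or minimize `"aicc"`.
#' @return A `climate_model` list: `gradient_id`, `variable`, `degree`,
#'   `coefficients` (intercept first), `adj_r2`, `r2`, `accepted`, `n`.
#' @export
fit_lapse_model <- function(points, variable, threshold = 0.5,
                            gradient_id = NA_character_,
                            select = c("adj_r2", "aicc")) {
  variable <- .norm_bio(variable)
  select <- match.arg(select)
  elev <- points$elevation_m; value <- points$value
  if (length(unique(elev)) < 2L)
    stop("all elevations identical: singular design")
  is_temp <- variable %in% BIO_TEMPERATURE
  degrees <- if (is_temp) 1L else 1:3
  # need degree + 2 points (one residual df for adjusted R2)
  degrees <- degrees[length(elev) >= degrees + 2L]
  if (length(degrees) == 0L)
    stop("insufficient points (", length(elev), ") for calibration")

  fits <- lapply(degrees, function(d)
    stats::lm(value ~ stats::poly(elev, d, raw = TRUE)))
  # noiseless calibrations fit perfectly; the summary warning is benign
  adj <- vapply(fits, function(f)
    suppressWarnings(summary(f)$adj.r.squared), 0)
  r2 <- vapply(fits, function(f)
    suppressWarnings(summary(f)$r.squared), 0)
  pick <- if (is_temp || length(fits) == 1L) 1L
          else if (select == "adj_r2") which.max(adj)
          else which.min(vapply(seq_along(fits), function(i)
            aicc(as.numeric(stats::logLik(fits[[i]])),
                 degrees[i] + 2L, length(elev)), 0))
  model <- list(
    gradient_id = gradient_id,
    variable = variable,
    degree = degrees[pick],
    coefficients = unname(stats::coef(fits[[pick]])),
    adj_r2 = adj[pick],
    r2 = r2[pick],
    accepted = is_temp || (is.finite(adj[pick]) && adj[pick] > threshold),
    n = length(elev)
  )
  class(model) <- "climate_model"
  model
}

#' Predict a climate value from a calibration model
#'
#' Polynomial evaluation in the variable's units. Refuses unaccepted
#' models, enforcing the exclusion of poorly calibrated precipitation
#' fits.
#'
#' @param model A `climate_model` from [fit_lapse_model()].
#' @param elevation Elevation(s), m.
#' @return Predicted value(s).
#' @export
predict_climate <- function(model, elevation) {
  stopifnot(inherits(model, "climate_model"))
  if (!isTRUE(model$accepted))
    stop("climate model for ", model$variable, " (gradient ",
         model$gradient_id, ") was rejected (adj R2 = ",
         signif(model$adj_r2, 3), "); refusing to predict")
  b <- model$coefficients
  powers <- outer(elevation, 0:model$degree, `^`)
  as.numeric(powers %*% b)
}

#' Read climate calibration points
#'
#' @param path CSV with columns `gradient_id,variable,elevation_m,value`
#'   (optional `source`; rows with `source == "direct"` are exact-location
#'   values that bypass modelling).
#' @return Data frame of calibration points.
#' @export
read_climate_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gradient_id", "variable", "elevation_m", "value")
  if (!all(need %in% names(df)))
    stop("climate points need columns ", paste(need, collapse = ", "))
  df$variable <- vapply(df$variable, .norm_bio, "")
  df
}

#' Fit all per-gradient calibration models
#'
#' @param points Calibration point data frame (see [read_climate_points()]);
#'   rows flagged `source == "direct"` are excluded from fitting.
#' @param threshold Adjusted-R2 acceptance cutoff for precipitation.
#' @param select Degree-selection rule, see [fit_lapse_model()].
#' @return List of `climate_model` objects.
#' @export
fit_climate_models <- function(points, threshold = 0.5,
                               select = "adj_r2") {
  if ("source" %in% names(points))
    points <- points[is.na(points$source) | points$source != "direct", ,
                     drop = FALSE]
  combos <- unique(points[, c("gradient_id", "variable")])
  lapply(seq_len(nrow(combos)), function(i) {
    sub <- points[points$gradient_id == combos$gradient_id[i] &
                  points$variable == combos$variable[i], , drop = FALSE]
    fit_lapse_model(sub, combos$variable[i], threshold = threshold,
                    gradient_id = combos$gradient_id[i], select = select)
  })
}

#' Attach climate values to band statistics
#'
#' Fills one column per Bioclim variable into the band table. Direct
#' (exact-location) values take precedence over model predictions; bands
#' covered by neither -- including bands on gradients whose precipitation
#' model was rejected -- stay `NA`.
#'
#' @param stats_df Band statistics from [band_stats()].
#' @param models List of `climate_model` objects (accepted or not).
#' @param direct Optional data frame of exact-location values with columns
#'   `gradient_id,variable,elevation_m,value`.
#' @return `stats_df` with `bio1 ... bio19` columns appended.
#' @export
attach_climate <- function(stats_df, models, direct = NULL) {
  for (v in BIO_VARIABLES) stats_df[[v]] <- NA_real_
  for (m in models) {
    if (!isTRUE(m$accepted)) next
    rows <- which(stats_df$gradient_id == m$gradient_id)
    if (length(rows))
      stats_df[rows, m$variable] <- predict_climate(m, stats_df$elevation_m[rows])
  }
  if (!is.null(direct) && nrow(direct)) {
    direct$variable <- vapply(direct$variable, .norm_bio, "")
    for (i in seq_len(nrow(direct))) {
      rows <- which(stats_df$gradient_id == direct$gradient_id[i] &
                    stats_df$elevation_m == direct$elevation_m[i])
      if (length(rows))
        stats_df[rows, direct$variable[i]] <- direct$value[i]
    }
  }
  stats_df
}

#' @export
print.climate_model <- function(x, ...) {
  cat(sprintf("climate_model: %s ~ poly(elev, %d) on gradient %s | adj R2 %.3f | %s\n",
              x$variable, x$degree, x$gradient_id, x$adj_r2,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}
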
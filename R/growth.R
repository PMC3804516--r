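#' Fit the net specific growth rate from an OD time series
#'
#' The net growth rate mu_net is the least-squares slope of ln(OD) versus
#' time from the end of the lag phase until the time of maximum cell
#' density.  The lag end is detected as the first time point at which OD
#' exceeds \code{(1 + epsilon) * OD(0)} and stays above that level for
#' the rest of the series (the sustained-rise condition guards against
#' single noisy readings near the detection margin; on noise-free
#' monotone curves it reduces to the first crossing).  The time of
#' maximum density is taken as the first reading entering the plateau
#' band — within \code{plateauTolerance} of the maximum; with
#' measurement noise the literal argmax can land anywhere along a flat
#' stationary plateau — and the fit runs strictly before it, since
#' growth has ended by the plateau and including plateau readings
#' biases the slope.  On noise-free capped-exponential data the fit
#' therefore recovers the true rate exactly.  Blank-referenced OD
#' readings at or below zero are excluded from the log fit.
#'
#' @param curve data.frame with strictly increasing \code{time} (hours)
#'   and \code{od} columns (one curve from
#'   \code{\link{readGrowthCurves}} or
#'   \code{\link{simulateGrowthCurves}}).
#' @param epsilon relative OD increase over the initial reading that
#'   marks the end of the lag phase (default 0.2).
#' @param plateauTolerance relative band below the maximum OD treated as
#'   stationary plateau (default 0.05).
#' @return list with \code{lag_end} and \code{t_max_od} (hours),
#'   \code{mu_net} (1/h), \code{r_squared} and \code{n_points}.
#' @export
fitGrowthRate <- function(curve, epsilon = 0.2, plateauTolerance = 0.05) {
  t <- curve$time
  od <- curve$od
  if (all(od <= 0)) stop("no positive OD readings; cannot fit ln(OD)")
  risen <- od > (1 + epsilon) * od[1]
  sustained <- rev(cumprod(rev(risen))) == 1
  lag_idx <- which(sustained)[1]
  if (is.na(lag_idx)) stop("OD never exceeds the lag-end criterion")
  lag_end <- t[lag_idx]
  t_max <- t[which(od >= (1 - plateauTolerance) * max(od))[1]]
  win <- which(t >= lag_end & t < t_max & od > 0)
  if (length(win) < 3)
    stop("fewer than 3 positive OD points between lag end and maximum OD")
  fit <- stats::lm(log(od[win]) ~ t[win])
  list(lag_end = lag_end, t_max_od = t_max,
       mu_net = unname(stats::coef(fit)[2]),
       r_squared = stats::cor(t[win], log(od[win]))^2,
       n_points = length(win))
}

#' Fit a product yield as a slope against substrate utilised
#'
#' End-product yields are the least-squares slope of product
#' concentration against the amount of substrate utilised over the
#' exponential-phase samples.
#'
#' @param product numeric vector of product concentrations (g/L).
#' @param substrateUsed numeric vector of cumulative substrate utilised
#'   (g/L), aligned with \code{product}.
#' @param window optional index vector restricting the fit to the
#'   exponential-phase samples (default: all points).
#' @return list with \code{slope} (g product per g substrate),
#'   \code{intercept}, \code{r_squared} and \code{n_points}.
#' @export
fitYield <- function(product, substrateUsed, window = NULL) {
  if (!is.null(window)) {
    product <- product[window]
    substrateUsed <- substrateUsed[window]
  }
  if (length(product) < 3 || length(product) != length(substrateUsed))
    stop("yield fit needs at least 3 aligned points")
  fit <- stats::lm(product ~ substrateUsed)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = stats::cor(substrateUsed, product)^2,
       n_points = length(product))
}

#' Pairwise ANCOVA comparison of two regression series
#'
#' Pools two (x, y) series into one regression with a treatment indicator
#' z (0 for series A, 1 for series B) and reports the significance of the
#' treatment term: \code{y ~ x + z} (\code{main_effect}, the default) or
#' \code{y ~ x + z + x:z} (\code{interaction}, where the reported term is
#' the slope difference x:z).  The main-effect form tests a treatment
#' offset at common slope even though the compared quantities are
#' slopes; the interaction form is offered for a direct slope
#' comparison, and the form used is recorded in the result.
#'
#' @param seriesA,seriesB data.frames (or lists) with numeric \code{x}
#'   and \code{y} of at least 3 points each.
#' @param modelForm \code{"main_effect"} or \code{"interaction"}.
#' @param alpha significance level (default 0.05).
#' @return list with \code{comparison}, \code{model_form},
#'   \code{coefficient} (of the treatment term), \code{p_value} and
#'   \code{significant}.
#' @export
ancovaCompare <- function(seriesA, seriesB, modelForm = c("main_effect",
                                                          "interaction"),
                          alpha = 0.05) {
  modelForm <- match.arg(modelForm)
  if (length(seriesA$x) < 3 || length(seriesB$x) < 3)
    stop("each series needs at least 3 points")
  dat <- data.frame(x = c(seriesA$x, seriesB$x),
                    y = c(seriesA$y, seriesB$y),
                    z = rep(c(0, 1), c(length(seriesA$x),
                                       length(seriesB$x))))
  fit <- if (modelForm == "main_effect") stats::lm(y ~ x + z, data = dat)
         else stats::lm(y ~ x * z, data = dat)
  term <- if (modelForm == "main_effect") "z" else "x:z"
  coefs <- summary(fit)$coefficients
  if (!term %in% rownames(coefs))
    stop("collinear inputs: treatment term could not be estimated")
  list(comparison = "A vs B", model_form = modelForm,
       coefficient = unname(coefs[term, "Estimate"]),
       p_value = unname(coefs[term, "Pr(>|t|)"]),
       significant = unname(coefs[term, "Pr(>|t|)"]) < alpha)
}

#' Growth-fit and ANCOVA summary across a set of curves
#'
#' @param curves named list of growth-curve data.frames.
#' @param epsilon lag-detection parameter for
#'   \code{\link{fitGrowthRate}}.
#' @return data.frame of per-curve fits (strain/condition parsed from the
#'   curve data), suitable for \code{\link{writeReport}}.
#' @export
fitGrowthRates <- function(curves, epsilon = 0.2) {
  rows <- lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    fit <- fitGrowthRate(cv, epsilon = epsilon)
    data.frame(curve = nm,
               strain = if ("strain" %in% names(cv)) cv$strain[1] else NA,
               condition = if ("condition" %in% names(cv))
                 cv$condition[1] else NA,
               lag_end = fit$lag_end, t_max_od = fit$t_max_od,
               mu_net = fit$mu_net, r_squared = fit$r_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
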
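#' Express replicate measurements as percent of a control
#'
#' `100 * mean(values) / mean(control)`, plus each replicate as a percent of
#' the control mean.
#'
#' @param values Numeric replicate measurements.
#' @param control Numeric control replicates; control mean must be > 0.
#' @return List with `percent` (scalar) and `per_replicate` (vector).
#' @export
#' @examples
#' percent_of_control(c(45, 55), c(100, 100))
percent_of_control <- function(values, control) {
  if (mean(control) <= 0) abort("control mean must be positive")
  list(percent = 100 * mean(values) / mean(control),
       per_replicate = 100 * values / mean(control))
}

#' Four-parameter logistic response curve
#'
#' `r(d) = lower + (upper - lower) / (1 + (d / ic50)^hill)`. At zero dose
#' the response is `upper`; it decays to `lower` as the dose grows (for
#' `hill > 0`), crossing the midpoint at `d = ic50`.
#'
#' @param dose Dose values (same unit as `ic50`).
#' @param lower,upper Lower/upper asymptotes.
#' @param ic50 Half-maximal inhibitory concentration, > 0.
#' @param hill Hill slope.
#' @return Response values.
#' @export
four_pl <- function(dose, lower, upper, ic50, hill) {
  lower + (upper - lower) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of [four_pl()] by Levenberg-Marquardt. Initialization
#' is fixed for reproducibility: `upper` = max response, `lower` = min
#' response, `ic50` = dose nearest the mid-response, `hill` = 1. Parameter
#' standard errors come from the curvature at the optimum. A fit that fails
#' or does not converge is returned flagged (`converged = FALSE`), never as
#' a silent number.
#'
#' @param data Data frame of the plate.
#' @param dose,response Column names (tidy-eval) holding dose (e.g. pM) and
#'   response; defaults `dose`, `response`.
#' @return A `four_pl_fit` object; see [tidy.four_pl_fit()] and
#'   [glance.four_pl_fit()].
#' @export
#' @examples
#' plate <- tibble::tibble(dose = 10^(0:5),
#'                         response = four_pl(10^(0:5), 0, 100, 3300, 1))
#' glance(fit_4pl(plate))
fit_4pl <- function(data, dose = "dose", response = "response") {
  d <- data[[dose]]
  r <- data[[response]]
  if (length(unique(d)) < 4L) abort("need >= 4 distinct doses to fit")
  if (any(d < 0)) abort("doses must be non-negative")
  if (any(!is.finite(r))) abort("responses must be finite")
  ## zero doses carry no information about the slope on the log scale but
  ## are legitimate controls; keep them (the model is defined at d = 0)
  mid <- (max(r) + min(r)) / 2
  pos <- d[d > 0]
  if (length(unique(pos)) < 4L) abort("need >= 4 distinct positive doses")
  start <- list(
    lower = min(r), upper = max(r),
    ic50 = pos[which.min(abs(r[d > 0] - mid))], hill = 1
  )
  df <- tibble(d = d, r = r)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ lower + (upper - lower) / (1 + (d / ic50)^hill),
      data = df, start = start,
      lower = c(lower = -Inf, upper = -Inf, ic50 = 1e-12, hill = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(fit = NULL, estimates = setNames(rep(NA_real_, 4),
                                            c("lower", "upper", "ic50", "hill")),
           std_errors = setNames(rep(NA_real_, 4),
                                 c("lower", "upper", "ic50", "hill")),
           converged = FALSE, message = conditionMessage(fit),
           data = df, n = nrow(df)),
      class = "four_pl_fit"
    ))
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(est)))
  converged <- isTRUE(fit$convInfo$isConv) &&
    is.finite(est[["ic50"]]) && est[["ic50"]] > 0 &&
    est[["upper"]] > est[["lower"]]
  structure(
    list(fit = fit, estimates = est, std_errors = se,
         converged = converged, message = NULL, data = df, n = nrow(df)),
    class = "four_pl_fit"
  )
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat("<four_pl_fit>",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a 4PL fit into a parameter table
#'
#' @param x A `four_pl_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.four_pl_fit <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = unname(x$estimates),
         std.error = unname(x$std_errors[names(x$estimates)]))
}

#' One-row summary of a 4PL fit
#'
#' @param x A `four_pl_fit`.
#' @param ... Unused.
#' @return Tibble with `ic50`, `ic50_se`, `hill`, `lower`, `upper`,
#'   `sigma`, `converged`, `nobs`.
#' @export
glance.four_pl_fit <- function(x, ...) {
  sigma <- if (!is.null(x$fit)) summary(x$fit)$sigma else NA_real_
  tibble(
    ic50 = unname(x$estimates["ic50"]),
    ic50_se = unname(x$std_errors["ic50"]),
    hill = unname(x$estimates["hill"]),
    lower = unname(x$estimates["lower"]),
    upper = unname(x$estimates["upper"]),
    sigma = sigma, converged = x$converged, nobs = x$n
  )
}

#' @export
predict.four_pl_fit <- function(object, dose, ...) {
  e <- object$estimates
  four_pl(dose, e["lower"], e["upper"], e["ic50"], e["hill"])
}

#' Survival-normalized enzymatic activity
#'
#' Divides a raw activity readout by the survival fraction, expressing
#' activity per unit of surviving cells: `normalized = raw /
#' (survival_percent / 100)`. At 100% survival the value is unchanged; at
#' 50% survival it doubles.
#'
#' @param raw Raw activity in arbitrary fluorescence units (vectorized).
#' @param survival_percent Percent cell survival in (0, 100].
#' @return Tibble with `raw_activity`, `survival_percent`, `normalized`.
#' @export
#' @examples
#' normalize_activity(150, 50)
normalize_activity <- function(raw, survival_percent) {
  if (any(survival_percent <= 0)) {
    abort("survival percent must be positive: normalization is undefined")
  }
  if (any(survival_percent > 100)) {
    abort("survival percent cannot exceed 100")
  }
  tibble(raw_activity = raw, survival_percent = survival_percent,
         normalized = raw / (survival_percent / 100))
}

#' Summarise normalized activity against surface charge
#'
#' Bins points by zeta potential, reporting per-bin mean, sample SD and
#' count, and fits an ordinary least-squares line of activity on zeta
#' potential (slope, intercept, r-squared). When all activities are equal
#' the r-squared is reported as 0.
#'
#' @param points Data frame of observations.
#' @param bins Numeric bin edges covering every zeta value (left-closed,
#'   right edge included in the last bin).
#' @param pz,activity Column names holding the zeta potential (mV) and the
#'   normalized activity; defaults `pz_mV`, `normalized_activity`.
#' @return A `charge_activity_summary`: list with `by_bin` and `ols`
#'   tibbles; `tidy()` returns the bins, `glance()` the regression.
#' @export
charge_activity_summary <- function(points, bins, pz = "pz_mV",
                                    activity = "normalized_activity") {
  x <- points[[pz]]
  y <- points[[activity]]
  if (length(x) < 2L) abort("need at least 2 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("zeta and activity values must be finite")
  }
  bins <- sort(bins)
  if (min(x) < bins[1] || max(x) > bins[length(bins)]) {
    abort("bins must cover all zeta values")
  }
  grp <- cut(x, breaks = bins, include.lowest = TRUE)
  by_bin <- dplyr::summarise(
    dplyr::group_by(tibble(grp = grp, y = y), .data$grp),
    n = dplyr::n(),
    mean_activity = mean(.data$y),
    sd_activity = stats::sd(.data$y),
    .groups = "drop"
  )
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else summary(fit)$r.squared
  ols <- tibble(slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                r_squared = r2, n = length(x))
  structure(list(by_bin = by_bin, ols = ols,
                 data = tibble(pz_mV = x, normalized_activity = y)),
            class = "charge_activity_summary")
}

#' @export
print.charge_activity_summary <- function(x, ...) {
  cat("<charge_activity_summary>\n")
  print(x$by_bin)
  cat(sprintf("OLS: Y = %.4f X + %.4f; r^2 = %.4f (n = %d)\n",
              x$ols$slope, x$ols$intercept, x$ols$r_squared, x$ols$n))
  invisible(x)
}

#' @export
tidy.charge_activity_summary <- function(x, ...) x$by_bin

#' @export
glance.charge_activity_summary <- function(x, ...) x$ols
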
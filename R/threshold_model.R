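#' Threshold-model parameters
#'
#' Parameters of the threshold model of GAL induction timing. The model says
#' a cell initiates GAL expression a fixed delay `tau` after extracellular
#' glucose drops below its repression threshold `g_star`. For a linear
#' depletion from `g_s` to zero over a depletion time `Td`, the initiation
#' time (measured from the start of depletion) is
#' \deqn{T_i = \frac{g_s - g^*}{g_s} T_d + \tau,}
#' and, with independent cell-to-cell variation in the threshold and delay,
#' its variance is
#' \deqn{\sigma^2(T_i) = \frac{\sigma^2(g^*)}{g_s^2} T_d^2 + \sigma^2(\tau).}
#'
#' Defaults are representative population estimates for GAL1 induction in
#' budding yeast depleted from 2% glucose in a constant 2% galactose
#' background.
#'
#' @param g_star Glucose repression threshold (% w/v). Must lie in
#'   `[0, g_s]`.
#' @param tau Activation delay after threshold crossing (minutes).
#' @param sigma_g_star Cell-to-cell SD of `g_star` (% w/v), `>= 0`.
#' @param sigma_tau Cell-to-cell SD of `tau` (minutes), `>= 0`.
#' @param g_s Initial glucose concentration (% w/v), `> 0`.
#' @return An object of class `"threshold_params"`.
#' @examples
#' p <- threshold_params(g_star = 1.4, tau = 17, sigma_g_star = 0.2,
#'                       sigma_tau = 18, g_s = 2)
#' predict_initiation_mean(p, Td = c(0, 4, 8))
#' @export
threshold_params <- function(g_star = 1.4, tau = 17, sigma_g_star = 0.2,
                             sigma_tau = 18, g_s = 2) {
  if (!is.numeric(g_s) || length(g_s) != 1L || g_s <= 0)
    stop("g_s must be a single positive number (% w/v)")
  if (!is.numeric(g_star) || length(g_star) != 1L ||
      g_star < 0 || g_star > g_s)
    stop("g_star must lie in [0, g_s]")
  if (sigma_g_star < 0 || sigma_tau < 0)
    stop("sigma_g_star and sigma_tau must be >= 0")
  structure(list(g_star = g_star, tau = tau,
                 sigma_g_star = sigma_g_star, sigma_tau = sigma_tau,
                 g_s = g_s),
            class = "threshold_params")
}

#' @export
print.threshold_params <- function(x, ...) {
  cat("Threshold model parameters\n")
  cat(sprintf("  g* = %.3g %%  (SD %.3g %%),  g_s = %.3g %%\n",
              x$g_star, x$sigma_g_star, x$g_s))
  cat(sprintf("  tau = %.3g min  (SD %.3g min)\n", x$tau, x$sigma_tau))
  invisible(x)
}

#' Mean initiation time under the threshold model
#'
#' @param params A [threshold_params()] object.
#' @param Td Depletion time(s) in hours, `>= 0`.
#' @return Mean initiation time(s) in hours from the start of depletion.
#' @export
predict_initiation_mean <- function(params, Td) {
  stopifnot(inherits(params, "threshold_params"))
  if (any(!is.finite(Td)) || any(Td < 0))
    stop("Td must be finite and >= 0 (hours)")
  (params$g_s - params$g_star) / params$g_s * Td + params$tau / 60
}

#' Standard deviation of the initiation time under the threshold model
#'
#' @inheritParams predict_initiation_mean
#' @return SD of the initiation time in hours.
#' @export
predict_initiation_sd <- function(params, Td) {
  stopifnot(inherits(params, "threshold_params"))
  if (any(!is.finite(Td)) || any(Td < 0))
    stop("Td must be finite and >= 0 (hours)")
  sqrt(params$sigma_g_star^2 * Td^2 / params$g_s^2 + (params$sigma_tau / 60)^2)
}

#' Validate an initiation dataset
#'
#' An initiation dataset is a long-format data frame with one row per cell:
#' columns `depletion_time_hr`, `cell_id`, `initiation_time_hr`, and
#' optionally `run_id`. Each depletion-time condition must contain at least
#' one cell and all initiation times must be finite.
#'
#' @param data A data frame.
#' @return The validated data frame (invisibly classed).
#' @export
as_initiation_dataset <- function(data) {
  need <- c("depletion_time_hr", "initiation_time_hr")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"cell_id" %in% names(data))
    data$cell_id <- seq_len(nrow(data))
  if (any(!is.finite(data$depletion_time_hr)) ||
      any(data$depletion_time_hr < 0))
    stop("depletion_time_hr must be finite and >= 0")
  if (any(!is.finite(data$initiation_time_hr)))
    stop("initiation_time_hr must be finite")
  if (nrow(data) == 0L) stop("empty dataset")
  data
}

#' Fit the mean-initiation-time model by ordinary least squares
#'
#' Regresses initiation time on depletion time and maps the slope and
#' intercept to the threshold `g_star = g_s * (1 - slope)` and the delay
#' `tau = 60 * intercept` (minutes). By default the regression uses
#' per-condition means (one point per depletion time); `pooled = TRUE`
#' fits all per-cell points instead. Confidence intervals come from
#' standard OLS theory on slope and intercept, transformed linearly.
#'
#' A slope outside `[0, 1]` implies a threshold outside `[0, g_s]`; the
#' estimate is *not* clamped — the fit is flagged (`$slope_out_of_range`)
#' and a warning is raised.
#'
#' @param data An initiation dataset (see [as_initiation_dataset()]).
#' @param g_s Initial glucose concentration (% w/v).
#' @param pooled Fit pooled per-cell points instead of condition means.
#' @return An object of class `"initiation_fit"` with elements `g_star`,
#'   `tau` (minutes), `r_squared`, `ci` (2-row matrix of 95% intervals),
#'   `n_conditions`, `slope_out_of_range`, `params`
#'   (a [threshold_params()] carrying the point estimates), and the
#'   underlying `lm` fit.
#' @export
fit_initiation_mean <- function(data, g_s = 2, pooled = FALSE) {
  data <- as_initiation_dataset(data)
  conds <- sort(unique(data$depletion_time_hr))
  if (length(conds) < 2L)
    stop("at least 2 distinct depletion-time conditions are required")
  if (pooled) {
    df <- data.frame(Td = data$depletion_time_hr,
                     Ti = data$initiation_time_hr)
  } else {
    Ti <- tapply(data$initiation_time_hr, data$depletion_time_hr, mean)
    df <- data.frame(Td = as.numeric(names(Ti)), Ti = as.numeric(Ti))
  }
  fit <- lm(Ti ~ Td, data = df)
  slope <- unname(coef(fit)["Td"])
  intercept <- unname(coef(fit)["(Intercept)"])
  g_star <- g_s * (1 - slope)
  tau <- 60 * intercept
  ci_raw <- suppressWarnings(confint(fit, level = 0.95))
  ci <- rbind(g_star = sort(g_s * (1 - ci_raw["Td", ])),
              tau = sort(60 * ci_raw["(Intercept)", ]))
  colnames(ci) <- c("lower", "upper")
  out_of_range <- slope < 0 || slope > 1
  if (out_of_range)
    warning(sprintf(
      "fitted slope %.3f implies a threshold outside [0, g_s]; not clamped",
      slope))
  structure(list(
    g_star = g_star, tau = tau, g_s = g_s,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    ci = ci, n_conditions = length(conds),
    slope = slope, intercept = intercept,
    slope_out_of_range = out_of_range,
    pooled = pooled,
    params = threshold_params(
      g_star = min(max(g_star, 0), g_s), tau = tau,
      sigma_g_star = 0, sigma_tau = 0, g_s = g_s),
    fit = fit), class = "initiation_fit")
}

#' @export
print.initiation_fit <- function(x, ...) {
  cat("Initiation-time fit (OLS",
      if (x$pooled) "on pooled cells" else "on condition means", ")\n")
  cat(sprintf("  g* = %.3f %% w/v  [%.3f, %.3f]\n",
              x$g_star, x$ci["g_star", 1], x$ci["g_star", 2]))
  cat(sprintf("  tau = %.2f min    [%.2f, %.2f]\n",
              x$tau, x$ci["tau", 1], x$ci["tau", 2]))
  cat(sprintf("  R^2 = %.4f over %d conditions\n",
              x$r_squared, x$n_conditions))
  if (x$slope_out_of_range)
    cat("  WARNING: slope outside [0, 1]; threshold estimate out of range\n")
  invisible(x)
}

#' Fit the initiation-time variance model
#'
#' Regresses the per-condition sample variance of the initiation time on the
#' squared depletion time — the coordinate in which the variance model is
#' exactly linear — and maps the slope and intercept to
#' `sigma_g_star = g_s * sqrt(slope)` and `sigma_tau = 60 * sqrt(intercept)`
#' (minutes). A negative slope or intercept means the variance model does
#' not describe the data; an error of class `"galswitch_misfit"` carrying
#' the raw regression coefficients is thrown rather than clamping silently.
#'
#' @param data An initiation dataset; every condition needs `>= 2` cells.
#' @param g_s Initial glucose concentration (% w/v).
#' @return An object of class `"variance_fit"`: `sigma_g_star` (% w/v),
#'   `sigma_tau` (minutes), `slope`, `intercept`, `ci`, `r_squared` and the
#'   underlying `lm` fit.
#' @export
fit_initiation_variance <- function(data, g_s = 2) {
  data <- as_initiation_dataset(data)
  n_per <- tapply(data$initiation_time_hr, data$depletion_time_hr, length)
  if (any(n_per < 2L))
    stop("every depletion-time condition needs >= 2 cells")
  v <- tapply(data$initiation_time_hr, data$depletion_time_hr, var)
  fit_initiation_variance_points(as.numeric(names(v)), as.numeric(v), g_s)
}

#' Fit the variance model from precomputed per-condition variances
#'
#' Lower-level interface to [fit_initiation_variance()] taking the
#' per-condition variances directly (useful for noiseless self-consistency
#' checks and for data summarised elsewhere).
#'
#' @param Td_hr Depletion times (hours), at least two distinct values.
#' @param var_hr2 Sample variances of the initiation time (hours squared).
#' @param g_s Initial glucose concentration (% w/v).
#' @return See [fit_initiation_variance()].
#' @export
fit_initiation_variance_points <- function(Td_hr, var_hr2, g_s = 2) {
  if (length(unique(Td_hr)) < 2L)
    stop("at least 2 distinct depletion-time conditions are required")
  df <- data.frame(Td2 = Td_hr^2, v = var_hr2)
  fit <- lm(v ~ Td2, data = df)
  slope <- unname(coef(fit)["Td2"])
  intercept <- unname(coef(fit)["(Intercept)"])
  if (slope < 0 || intercept < 0)
    stop(errorCondition(
      sprintf(paste0("variance model misfit: slope = %.4g, intercept = %.4g",
                     " (both must be >= 0)"), slope, intercept),
      class = "galswitch_misfit",
      slope = slope, intercept = intercept))
  ci_raw <- suppressWarnings(confint(fit, level = 0.95))
  ci <- rbind(
    sigma_g_star = g_s * sqrt(pmax(sort(ci_raw["Td2", ]), 0)),
    sigma_tau = 60 * sqrt(pmax(sort(ci_raw["(Intercept)", ]), 0)))
  colnames(ci) <- c("lower", "upper")
  structure(list(
    sigma_g_star = g_s * sqrt(slope),
    sigma_tau = 60 * sqrt(intercept),
    slope = slope, intercept = intercept,
    ci = ci, g_s = g_s,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_conditions = length(unique(Td_hr)),
    fit = fit), class = "variance_fit")
}

#' @export
print.variance_fit <- function(x, ...) {
  cat("Initiation-time variance fit (OLS on Td^2)\n")
  cat(sprintf("  sigma(g*) = %.3f %% w/v\n", x$sigma_g_star))
  cat(sprintf("  sigma(tau) = %.2f min\n", x$sigma_tau))
  cat(sprintf("  R^2 = %.4f over %d conditions\n",
              x$r_squared, x$n_conditions))
  invisible(x)
}

#' Bootstrap SD of a per-condition summary statistic
#'
#' Resamples cells with replacement within each depletion-time condition,
#' recomputes a summary statistic `B` times, and returns the SD over
#' replicates — the bootstrap standard error of that statistic. With a fixed
#' `seed` the result is bit-reproducible; the caller's RNG state is restored
#' on exit.
#'
#' @param data An initiation dataset.
#' @param statistic Function mapping a numeric vector to a scalar
#'   (default `mean`).
#' @param B Number of bootstrap replicates, `>= 2`.
#' @param seed Optional integer seed.
#' @return Data frame with `depletion_time_hr`, `n_cells`, `statistic`
#'   (the point value) and `boot_sd`.
#' @export
bootstrap_sd <- function(data, statistic = mean, B = 1000, seed = NULL) {
  data <- as_initiation_dataset(data)
  if (!is.function(statistic)) stop("statistic must be a function")
  if (B < 2) stop("B must be >= 2: the SD over a single replicate is undefined")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  conds <- sort(unique(data$depletion_time_hr))
  out <- lapply(conds, function(td) {
    x <- data$initiation_time_hr[data$depletion_time_hr == td]
    if (length(x) == 0L) stop("empty condition at Td = ", td)
    reps <- vapply(seq_len(B), function(b)
      statistic(x[sample.int(length(x), replace = TRUE)]), numeric(1))
    data.frame(depletion_time_hr = td, n_cells = length(x),
               statistic = statistic(x), boot_sd = sd(reps))
  })
  do.call(rbind, out)
}

#' Read / write an initiation dataset as CSV
#'
#' Long format, one row per cell: `run_id`, `depletion_time_hr`, `cell_id`,
#' `initiation_time_hr`.
#'
#' @param path File path.
#' @return `read_initiation_csv` returns the validated data frame.
#' @export
read_initiation_csv <- function(path) {
  as_initiation_dataset(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_initiation_csv
#' @param data An initiation dataset.
#' @export
write_initiation_csv <- function(data, path) {
  data <- as_initiation_dataset(data)
  if (!"run_id" %in% names(data))
    data$run_id <- sprintf("Td%0.3f", data$depletion_time_hr)
  write.csv(data[c("run_id", "depletion_time_hr", "cell_id",
                   "initiation_time_hr")],
            path, row.names = FALSE)
  invisible(path)
}
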
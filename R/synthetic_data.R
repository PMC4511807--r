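#' Synthetic-population generator configuration
#'
#' Bundles everything needed to emulate a glucose-depletion run: the
#' generating threshold-model parameters, the cycle-length distributions of
#' the three growth regimes, the fluorescence shape parameters and the
#' sampling scheme. Defaults reproduce the measured anchors of the
#' reference assays: 5-min imaging over 15 h, a 4-h hold at 2% glucose,
#' glucose cycles of 1.38 +/- 0.25 h, galactose cycles of 1.65 +/- 0.38 h,
#' right-skewed diauxic cycles of 3.19 +/- 1.95 h (lognormal), and a
#' galactose-grown FI plateau of 8200 +/- 2000 AU.
#'
#' The pre-initiation FI decline (dilution of pre-existing reporter) decays
#' exponentially at the glucose-growth dilution rate; the post-initiation
#' rise is sigmoidal toward the plateau. Measurement noise is i.i.d.
#' Gaussian per sample.
#'
#' @param params Generating [threshold_params()].
#' @param glu_cycle_mean,glu_cycle_sd Glucose-regime cycle length (hours).
#' @param dia_cycle_mean,dia_cycle_sd Diauxie-regime cycle length (hours);
#'   drawn lognormal (right-skewed).
#' @param gal_cycle_mean,gal_cycle_sd Galactose-regime cycle length (hours).
#' @param fi_plateau_mean,fi_plateau_sd Per-cell FI plateau (AU).
#' @param fi_initial Initial FI above the rescaled-zero frame (AU).
#' @param noise_sd Measurement noise SD per sample (AU).
#' @param decline_rate Pre-initiation FI decay rate (1/min); default is the
#'   glucose-growth dilution rate `log(2)/82.8`.
#' @param rise_rate Post-initiation rise rate (1/min).
#' @param cadence Sampling cadence (minutes).
#' @param record_min Record length (minutes).
#' @param hold_min Hold duration before depletion (minutes).
#' @param n_cells Cells per condition.
#' @param min_cycle_hr Lower truncation for all cycle draws (hours).
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(params = threshold_params(),
                             glu_cycle_mean = 1.38, glu_cycle_sd = 0.25,
                             dia_cycle_mean = 3.19, dia_cycle_sd = 1.95,
                             gal_cycle_mean = 1.65, gal_cycle_sd = 0.38,
                             fi_plateau_mean = 8200, fi_plateau_sd = 2000,
                             fi_initial = 1500, noise_sd = 20,
                             decline_rate = log(2) / 82.8,
                             rise_rate = 0.004,
                             cadence = 5, record_min = 900, hold_min = 240,
                             n_cells = 150, min_cycle_hr = 0.2) {
  stopifnot(inherits(params, "threshold_params"))
  sds <- c(glu_cycle_sd, dia_cycle_sd, gal_cycle_sd, fi_plateau_sd, noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (cadence <= 0) stop("cadence must be > 0")
  structure(as.list(environment()), class = "generator_config")
}

truncated_normal <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lower | x > upper))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# lognormal parameterised by its own mean/sd (not the log scale)
rlnorm_msd <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Draw per-cell threshold-model initiation times
#'
#' The generative reading of the threshold model: each cell draws its own
#' repression threshold `g*` (normal, truncated to `(0, g_s]`) and delay
#' `tau` (normal, untruncated by default — truncating at zero would bias
#' population-level recovery because the delay SD is of the order of its
#' mean; a truncated variant is available for realistic trajectory
#' synthesis and is biased upward), and its initiation time follows the
#' mean model evaluated at its own parameters.
#'
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param params Generating [threshold_params()].
#' @param Td_hr Depletion time (hours), scalar.
#' @param n Number of cells.
#' @param truncate_tau Truncate the delay draws at zero.
#' @return Data frame with per-cell `g_star`, `tau_min` and `Ti_hr`.
#' @export
generate_initiation_times <- function(params, Td_hr, n,
                                      truncate_tau = FALSE) {
  stopifnot(inherits(params, "threshold_params"), Td_hr >= 0)
  g_star <- truncated_normal(n, params$g_star, params$sigma_g_star,
                             lower = 0, upper = params$g_s)
  tau <- if (truncate_tau)
    truncated_normal(n, params$tau, params$sigma_tau, lower = 0)
  else rnorm(n, params$tau, params$sigma_tau)
  Ti <- (params$g_s - g_star) / params$g_s * Td_hr + tau / 60
  data.frame(g_star = g_star, tau_min = tau, Ti_hr = Ti)
}

#' Generate a multi-condition initiation dataset
#'
#' Draws [generate_initiation_times()] populations over a grid of depletion
#' times and stacks them into the long-format initiation dataset consumed
#' by [fit_initiation_mean()] and [fit_initiation_variance()].
#'
#' @param params Generating [threshold_params()].
#' @param Td_hr Vector of depletion times (hours).
#' @param n_cells Cells per condition.
#' @param seed Optional integer seed.
#' @param truncate_tau Passed to [generate_initiation_times()].
#' @return Initiation dataset with the generating latents (`g_star`,
#'   `tau_min`) attached as extra columns.
#' @export
generate_initiation_dataset <- function(params, Td_hr = depletion_grid(),
                                        n_cells = 150, seed = NULL,
                                        truncate_tau = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(Td_hr, function(td) {
    d <- generate_initiation_times(params, td, n_cells,
                                   truncate_tau = truncate_tau)
    data.frame(run_id = sprintf("Td%0.3f", td), depletion_time_hr = td,
               cell_id = seq_len(n_cells), initiation_time_hr = d$Ti_hr,
               g_star = d$g_star, tau_min = d$tau_min)
  })
  as_initiation_dataset(do.call(rbind, out))
}

noiseless_fi <- function(t, t_init, fi_initial, plateau,
                         decline_rate, rise_rate) {
  fi <- numeric(length(t))
  if (t_init > t[1]) {
    pre <- t < t_init
    # exponential dilution decay pinned to fi_initial at t[1] and 0 at t_init
    e <- exp(-decline_rate * (t[pre] - t[1]))
    e_end <- exp(-decline_rate * (t_init - t[1]))
    fi[pre] <- fi_initial * (e - e_end) / (1 - e_end)
  }
  post <- t >= t_init
  fi[post] <- plateau * (1 - exp(-rise_rate * (t[post] - t_init)))^2
  fi
}

#' Generate a synthetic single-condition population
#'
#' Emulates one depletion run: each cell draws its threshold-model latents,
#' its true initiation time follows the mean model at its own draws, and
#' its FI trajectory declines from the initial level to zero (rescaled
#' frame) until initiation, then rises sigmoidally toward a per-cell
#' plateau, with additive Gaussian measurement noise. Budding events
#' concatenate glucose-regime cycles while extracellular glucose is at or
#' above the cell's own threshold, one diauxic cycle, then galactose-regime
#' cycles to the end of the record; the regime of every cycle is stored as
#' ground truth.
#'
#' A cell whose drawn initiation time precedes the depletion start (possible
#' with an untruncated delay at short depletion times) emits a trajectory
#' whose minimum lies before the depletion start; the detector's boundary
#' convention then reports initiation at the depletion start.
#'
#' @param config A [generator_config()].
#' @param Td_hr Depletion time of the run (hours).
#' @param seed Optional integer seed.
#' @param truncate_tau Passed to [generate_initiation_times()].
#' @return List of class `"synthetic_population"`: `trajectories` (list of
#'   [cell_trajectory()], each carrying its noiseless `fi_true`), `latents`
#'   (per-cell data frame incl. `Ti_hr`, `t_init_min`, `plateau`),
#'   `truth_cycles` (per-cycle regime labels), and the `schedule`.
#' @export
generate_threshold_population <- function(config, Td_hr, seed = NULL,
                                          truncate_tau = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  if (config$record_min < config$hold_min + Td_hr * 60)
    stop("record length must cover hold + depletion")
  sched <- make_schedule(Td = Td_hr * 60, hold = config$hold_min,
                         g_s = config$params$g_s,
                         total = config$record_min)
  tms <- seq(0, config$record_min, by = config$cadence)
  n <- config$n_cells
  lat <- generate_initiation_times(config$params, Td_hr, n,
                                   truncate_tau = truncate_tau)
  lat$plateau <- truncated_normal(n, config$fi_plateau_mean,
                                  config$fi_plateau_sd, lower = 0)
  lat$t_init_min <- config$hold_min + lat$Ti_hr * 60
  lat$cell_id <- seq_len(n)

  trajectories <- vector("list", n)
  truth <- list()
  for (i in seq_len(n)) {
    fi_true <- noiseless_fi(tms, lat$t_init_min[i], config$fi_initial,
                            lat$plateau[i], config$decline_rate,
                            config$rise_rate)
    fi <- fi_true + rnorm(length(tms), 0, config$noise_sd)

    buds <- runif(1, 0, config$glu_cycle_mean * 60)
    labels <- character(0)
    stage <- "Glucose"
    while (buds[length(buds)] <= config$record_min) {
      b <- buds[length(buds)]
      if (stage == "Glucose" && glucose_at(sched, b) < lat$g_star[i])
        stage <- "Diauxie"
      len_hr <- switch(stage,
        Glucose = truncated_normal(1, config$glu_cycle_mean,
                                   config$glu_cycle_sd,
                                   lower = config$min_cycle_hr),
        Diauxie = max(rlnorm_msd(1, config$dia_cycle_mean,
                                 config$dia_cycle_sd),
                      config$min_cycle_hr),
        Galactose = truncated_normal(1, config$gal_cycle_mean,
                                     config$gal_cycle_sd,
                                     lower = config$min_cycle_hr))
      buds <- c(buds, b + len_hr * 60)
      labels <- c(labels, stage)
      if (stage == "Diauxie") stage <- "Galactose"
    }
    # drop the unfinished final cycle
    buds <- buds[buds <= config$record_min]
    labels <- labels[seq_len(max(length(buds) - 1L, 0L))]
    trajectories[[i]] <- cell_trajectory(
      cell_id = i, time_min = tms, fi = fi, budding_min = buds,
      depletion_start_min = config$hold_min, Td_hr = Td_hr,
      fi_true = fi_true)
    if (length(labels))
      truth[[length(truth) + 1L]] <- data.frame(
        cell_id = i, cycle_index = seq_along(labels), true_label = labels)
  }
  structure(list(trajectories = trajectories, latents = lat,
                 truth_cycles = if (length(truth)) do.call(rbind, truth)
                                else NULL,
                 schedule = sched, Td_hr = Td_hr, config = config),
            class = "synthetic_population")
}

#' Map a simulated lineage to a fluorescence trajectory
#'
#' Links the stochastic simulator to the observable the analysis consumes:
#' the inducible transporter count stands in for the fluorescent reporter
#' (both are Gal4p-activated GAL products; the simulator does not carry the
#' reporter itself as a species), scaled to AU, offset by a background, with
#' optional Gaussian measurement noise. Division times become budding
#' events.
#'
#' @param lineage A `"lineage_record"` from [simulate_cell()].
#' @param scale AU per molecule.
#' @param background Additive background (AU).
#' @param noise_sd Measurement noise SD (AU); 0 for none.
#' @param cell_id Identifier for the resulting trajectory.
#' @return A [cell_trajectory()].
#' @export
simulator_to_fi <- function(lineage, scale = 13.7, background = 0,
                            noise_sd = 0, cell_id = 1) {
  stopifnot(inherits(lineage, "lineage_record"))
  fi_true <- scale * lineage$g2 + background
  fi <- fi_true + if (noise_sd > 0)
    rnorm(length(fi_true), 0, noise_sd) else 0
  cell_trajectory(cell_id = cell_id, time_min = lineage$time, fi = fi,
                  budding_min = lineage$division_times,
                  depletion_start_min = lineage$schedule$hold,
                  Td_hr = lineage$schedule$Td / 60,
                  fi_true = fi_true)
}

#' Write a synthetic population as the CSV trio consumed by the analysis
#'
#' Fluorescence (`cell_id`, `time_min`, `fi_au`), budding (`cell_id`,
#' `bud_time_min`) and run (`run_id`, `depletion_time_hr`,
#' `depletion_start_min`) tables, plus the ground-truth latents in a
#' separate file so analysis code cannot accidentally read them.
#'
#' @param pop A `"synthetic_population"`.
#' @param dir Output directory.
#' @param run_id Run identifier.
#' @return Invisibly, the paths written.
#' @export
write_population_csvs <- function(pop, dir, run_id = "run1") {
  stopifnot(inherits(pop, "synthetic_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fl <- do.call(rbind, lapply(pop$trajectories, function(tr)
    data.frame(cell_id = tr$cell_id, time_min = tr$time_min,
               fi_au = tr$fi)))
  bud <- do.call(rbind, lapply(pop$trajectories, function(tr)
    if (length(tr$budding_min))
      data.frame(cell_id = tr$cell_id, bud_time_min = tr$budding_min)
    else NULL))
  run <- data.frame(run_id = run_id, depletion_time_hr = pop$Td_hr,
                    depletion_start_min = pop$config$hold_min)
  paths <- file.path(dir, paste0(run_id, "_",
                                 c("fluorescence", "budding", "run",
                                   "latents"), ".csv"))
  write.csv(fl, paths[1], row.names = FALSE)
  write.csv(bud, paths[2], row.names = FALSE)
  write.csv(run, paths[3], row.names = FALSE)
  write.csv(pop$latents, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read the fluorescence/budding/run CSV trio back into trajectories
#'
#' @param dir Directory written by [write_population_csvs()].
#' @param run_id Run identifier.
#' @return List of [cell_trajectory()] objects.
#' @export
read_population_csvs <- function(dir, run_id = "run1") {
  fl <- read.csv(file.path(dir, paste0(run_id, "_fluorescence.csv")))
  bud <- read.csv(file.path(dir, paste0(run_id, "_budding.csv")))
  run <- read.csv(file.path(dir, paste0(run_id, "_run.csv")))
  lapply(split(fl, fl$cell_id), function(d) {
    d <- d[order(d$time_min), ]
    b <- sort(bud$bud_time_min[bud$cell_id == d$cell_id[1]])
    cell_trajectory(cell_id = d$cell_id[1], time_min = d$time_min,
                    fi = d$fi_au, budding_min = b,
                    depletion_start_min = run$depletion_start_min[1],
                    Td_hr = run$depletion_time_hr[1])
  })
}
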
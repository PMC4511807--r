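#' Parameters of the minimal Gal4p/Gal2p energy model
#'
#' The model has two species produced by zeroth-order delayed reactions,
#' Gal4p (`g4`) and Gal2p (`g2`), with propensities
#' \deqn{\beta_4 = \frac{\alpha_4}{1 + (glu/c_4)^{n_4}}, \qquad
#'       \beta_2 = \alpha_2 \frac{(g_4/c_2)^{n_2}}{1 + (g_4/c_2)^{n_2}},}
#' both scaled by a dimensionless energy term
#' \deqn{E = \max\{E_{glu}(glu),\; E_{gal}(g_2),\; \epsilon\},}
#' where \eqn{E_{glu}} and \eqn{E_{gal}} are piecewise-linear, increasing
#' from zero and saturating at `E_glu_max` (at glucose `th_glu`) and
#' `E_gal_max` (at `th_gal` Gal2p molecules). `E` also scales the growth
#' rate: volume grows as `dV/dt = E * gamma * V`, and the cell divides when
#' `V` reaches 2, partitioning every mature and immature (pending) protein
#' binomially with p = 0.5.
#'
#' Cell-to-cell heterogeneity enters through the glucose half-repression
#' point `c4` (normal, truncated positive) and the basal energy `eps`
#' (scaled Beta on `(0, eps_max)`), drawn once per cell by
#' [sample_cell_params()].
#'
#' Energy maxima and the growth rate are anchored to measured cell-cycle
#' lengths: `E_glu_max` is normalised to 1 with `gamma = log(2)/82.8` per
#' minute, so a saturated-glucose cell doubles every 1.38 h; `E_gal_max =
#' 1.38/1.65` gives the 1.65 h galactose doubling time. The Hill constants
#' are calibrated so the network is OFF in 2% glucose (Gal4p well below
#' `c2`) and switches ON after repression is released; see the package
#' vignette for the calibration rationale.
#'
#' @param alpha4,alpha2 Maximal production rates (molecules/min); 0
#'   switches a channel off entirely (useful for diagnostics).
#' @param n4,n2 Hill coefficients (dimensionless).
#' @param c4_mean,c4_sd Mean and cell-to-cell SD of the glucose
#'   half-repression point (% w/v).
#' @param c2 Gal4p half-activation point (molecules).
#' @param E_glu_max,E_gal_max Saturating energy levels on glucose and on
#'   galactose (dimensionless); `E_gal_max <= E_glu_max`.
#' @param th_glu Glucose level at which `E_glu` saturates (% w/v).
#' @param th_gal Gal2p count at which `E_gal` saturates (molecules).
#' @param eps_max,eps_shape_a,eps_shape_b Range and Beta shape parameters of
#'   the basal-energy distribution; `eps_max < E_gal_max`.
#' @param gamma Basal growth rate (1/min). May be 0 for non-growing
#'   diagnostic configurations (no division ever triggers).
#' @param delay Fixed protein maturation delay (minutes).
#' @param max_step Maximum dSSA time increment (minutes); propensities are
#'   frozen within a step, so this bounds the error from time-varying rates.
#' @param eps_fixed If non-`NULL`, every cell gets exactly this basal energy
#'   instead of a Beta draw (used by [constant_energy_params()]).
#' @return An object of class `"energy_params"`.
#' @export
energy_params <- function(alpha4 = 2, alpha2 = 5, n4 = 6, n2 = 4,
                          c4_mean = 1.4, c4_sd = 0.2, c2 = 150,
                          E_glu_max = 1, E_gal_max = 1.38 / 1.65,
                          th_glu = 0.5, th_gal = 200,
                          eps_max = 0.8, eps_shape_a = 2, eps_shape_b = 4,
                          gamma = log(2) / 82.8, delay = 5, max_step = 1,
                          eps_fixed = NULL) {
  pos <- c(n4 = n4, n2 = n2,
           c4_mean = c4_mean, c2 = c2, E_glu_max = E_glu_max,
           E_gal_max = E_gal_max, th_glu = th_glu, th_gal = th_gal,
           eps_max = eps_max, eps_shape_a = eps_shape_a,
           eps_shape_b = eps_shape_b, max_step = max_step)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    stop("parameters must be > 0: ", paste(bad, collapse = ", "))
  if (alpha4 < 0 || alpha2 < 0)
    stop("production rates must be >= 0 (0 switches a channel off)")
  if (c4_sd < 0) stop("c4_sd must be >= 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (delay < 0) stop("delay must be >= 0")
  if (E_gal_max > E_glu_max) stop("E_gal_max must be <= E_glu_max")
  if (eps_max >= E_gal_max) stop("eps_max must be < E_gal_max")
  if (!is.null(eps_fixed) && (eps_fixed <= 0 || !is.finite(eps_fixed)))
    stop("eps_fixed must be a positive number or NULL")
  structure(list(alpha4 = alpha4, alpha2 = alpha2, n4 = n4, n2 = n2,
                 c4_mean = c4_mean, c4_sd = c4_sd, c2 = c2,
                 E_glu_max = E_glu_max, E_gal_max = E_gal_max,
                 th_glu = th_glu, th_gal = th_gal,
                 eps_max = eps_max, eps_shape_a = eps_shape_a,
                 eps_shape_b = eps_shape_b,
                 gamma = gamma, delay = delay, max_step = max_step,
                 eps_fixed = eps_fixed),
            class = "energy_params")
}

#' Constant-energy control parameters
#'
#' Returns a copy of `params` in which the energy term is pinned to the
#' constant `E`: both saturating levels equal `E` and every cell's basal
#' energy is fixed at `E`, so `max(E_glu, E_gal, eps) = E` at all times.
#' The control runs through exactly the same simulation engine as the full
#' model — the only difference is the energy function's output.
#'
#' @param params An [energy_params()] object.
#' @param E The constant energy level.
#' @return An `"energy_params"` object.
#' @export
constant_energy_params <- function(params, E = 1) {
  stopifnot(inherits(params, "energy_params"))
  p <- unclass(params)
  p$E_glu_max <- E
  p$E_gal_max <- E
  p$eps_max <- E * 0.999   # unused when eps_fixed is set; keeps invariants
  p$eps_fixed <- E
  do.call(energy_params, p)
}

#' Gal4p production propensity (before energy scaling)
#'
#' Repressive Hill function of glucose: `alpha4 / (1 + (glu/c4)^n4)`.
#'
#' @param glu Glucose concentration(s) (% w/v), `>= 0`.
#' @param params An [energy_params()] object.
#' @param c4 Half-repression point; defaults to the population mean.
#' @return Rate in molecules/min.
#' @export
propensity_gal4 <- function(glu, params, c4 = params$c4_mean) {
  stopifnot(inherits(params, "energy_params"))
  if (any(glu < 0)) stop("glu must be >= 0")
  params$alpha4 / (1 + (glu / c4)^params$n4)
}

#' Gal2p production propensity (before energy scaling)
#'
#' Activating Hill function of Gal4p:
#' `alpha2 * (g4/c2)^n2 / (1 + (g4/c2)^n2)`.
#'
#' @param g4 Gal4p count(s), `>= 0`.
#' @param params An [energy_params()] object.
#' @return Rate in molecules/min.
#' @export
propensity_gal2 <- function(g4, params) {
  stopifnot(inherits(params, "energy_params"))
  if (any(g4 < 0)) stop("g4 must be >= 0")
  h <- (g4 / params$c2)^params$n2
  params$alpha2 * h / (1 + h)
}

#' Energy scaling term
#'
#' `E = max(E_glu_max * min(glu/th_glu, 1), E_gal_max * min(g2/th_gal, 1),
#' eps)`: energy is supplied either by glucose metabolism, by galactose
#' metabolism (proxied by the Gal2p transporter count), or — during the
#' carbon-source transition — by a basal floor `eps`.
#'
#' @param glu Glucose concentration (% w/v), `>= 0`.
#' @param g2 Gal2p count, `>= 0`.
#' @param eps Basal energy of this cell.
#' @param params An [energy_params()] object.
#' @return Dimensionless energy level.
#' @export
energy <- function(glu, g2, eps, params) {
  stopifnot(inherits(params, "energy_params"))
  if (any(glu < 0) || any(g2 < 0) || any(eps < 0))
    stop("glu, g2 and eps must be >= 0")
  pmax(params$E_glu_max * pmin(glu / params$th_glu, 1),
       params$E_gal_max * pmin(g2 / params$th_gal, 1),
       eps)
}

#' Draw per-cell heterogeneity parameters
#'
#' `c4` is drawn from a normal distribution truncated to positive values
#' (rejection sampling); `eps` is `eps_max` times a Beta(`a`, `b`) draw, or
#' exactly `eps_fixed` when that is set. Uses the current RNG state.
#'
#' @param params An [energy_params()] object.
#' @param n Number of cells.
#' @return Data frame with columns `c4` and `eps`.
#' @export
sample_cell_params <- function(params, n = 1) {
  stopifnot(inherits(params, "energy_params"))
  if (params$c4_sd == 0) {
    c4 <- rep(params$c4_mean, n)
  } else {
    c4 <- rnorm(n, params$c4_mean, params$c4_sd)
    while (any(bad <- c4 <= 0))
      c4[bad] <- rnorm(sum(bad), params$c4_mean, params$c4_sd)
  }
  eps <- if (!is.null(params$eps_fixed)) rep(params$eps_fixed, n)
         else params$eps_max * rbeta(n, params$eps_shape_a, params$eps_shape_b)
  data.frame(c4 = c4, eps = eps)
}

#' Create a cell state
#'
#' @param c4,eps This cell's sampled heterogeneity parameters (see
#'   [sample_cell_params()]).
#' @param t Current time (minutes).
#' @param g4,g2 Initial mature protein counts.
#' @param volume Initial volume (dimensionless; cells divide at 2).
#' @return An object of class `"cell_state"`.
#' @export
new_cell_state <- function(c4, eps, t = 0, g4 = 0L, g2 = 0L, volume = 1) {
  if (g4 < 0 || g2 < 0) stop("counts must be non-negative")
  if (volume < 1 || volume >= 2)
    stop("volume must lie in [1, 2) between divisions")
  structure(list(t = t, g4 = as.integer(g4), g2 = as.integer(g2),
                 volume = volume,
                 pending_time = numeric(0), pending_species = integer(0),
                 division_times = numeric(0),
                 c4 = c4, eps = eps),
            class = "cell_state")
}

#' Advance a cell by one dSSA step
#'
#' One step of the delayed stochastic simulation: the energy term and both
#' propensities are evaluated at the current time (glucose frozen within the
#' step) and an exponential waiting time is drawn from the total scaled
#' rate. The cell advances to the earliest of the waiting time, the
#' `max_step` cap, the next pending maturation, or the volume-doubling
#' (division) time — firing a reaction only in the first case, in which one
#' channel is chosen proportionally to its scaled propensity and its product
#' is queued to appear `delay` minutes later. Zero total propensity is
#' handled by pure capped advancement. Volume is integrated over the elapsed
#' interval with the frozen energy; division (at volume 2) partitions all
#' mature and pending proteins binomially and resets the volume to 1.
#'
#' @param state A [new_cell_state()] object.
#' @param schedule A [make_schedule()] object.
#' @param params An [energy_params()] object.
#' @return The advanced `"cell_state"`.
#' @export
step_dssa <- function(state, schedule, params) {
  stopifnot(inherits(state, "cell_state"),
            inherits(schedule, "glucose_schedule"),
            inherits(params, "energy_params"))
  res <- dssa_advance_cpp(
    t = state$t, g4 = state$g4, g2 = state$g2, volume = state$volume,
    pending_time = state$pending_time,
    pending_species = state$pending_species,
    division_times = state$division_times,
    c4 = state$c4, eps = state$eps,
    alpha4 = params$alpha4, alpha2 = params$alpha2,
    n4 = params$n4, n2 = params$n2, c2 = params$c2,
    E_glu_max = params$E_glu_max, E_gal_max = params$E_gal_max,
    th_glu = params$th_glu, th_gal = params$th_gal,
    gamma = params$gamma, delay = params$delay, max_step = params$max_step,
    hold = schedule$hold, td = schedule$Td, gs = schedule$g_s,
    t_end = state$t + 10 * params$max_step + 1e6, single_step = TRUE,
    cadence = -1, record = FALSE)
  out <- state
  out$t <- res$t
  out$g4 <- res$g4
  out$g2 <- res$g2
  out$volume <- res$volume
  out$pending_time <- res$pending_time
  out$pending_species <- res$pending_species
  out$division_times <- res$division_times
  out
}

#' Divide a cell
#'
#' Requires volume `>= 2`. Every mature molecule and every pending
#' (immature) production is independently assigned to the daughter with
#' probability 1/2; the mother keeps the rest. Both volumes reset to 1 and
#' the division time is appended to the mother's record.
#'
#' @param state A [new_cell_state()] object with `volume >= 2`.
#' @return List with elements `mother` and `daughter` (both `"cell_state"`).
#' @export
divide <- function(state) {
  stopifnot(inherits(state, "cell_state"))
  if (state$volume < 2)
    stop("divide() called with volume < 2")
  d4 <- if (state$g4 > 0) rbinom(1, state$g4, 0.5) else 0L
  d2 <- if (state$g2 > 0) rbinom(1, state$g2, 0.5) else 0L
  to_daughter <- if (length(state$pending_time))
    runif(length(state$pending_time)) < 0.5 else logical(0)

  mother <- state
  mother$g4 <- state$g4 - as.integer(d4)
  mother$g2 <- state$g2 - as.integer(d2)
  mother$pending_time <- state$pending_time[!to_daughter]
  mother$pending_species <- state$pending_species[!to_daughter]
  mother$volume <- 1
  mother$division_times <- c(state$division_times, state$t)

  daughter <- new_cell_state(c4 = state$c4, eps = state$eps, t = state$t,
                             g4 = d4, g2 = d2, volume = 1)
  daughter$pending_time <- state$pending_time[to_daughter]
  daughter$pending_species <- state$pending_species[to_daughter]
  list(mother = mother, daughter = daughter)
}

#' Simulate one cell lineage
#'
#' Follows the mother cell from `t = 0` to `t_end` under a glucose
#' schedule, recording counts, volume and energy at a fixed output cadence
#' plus all division times. Daughters are partitioned off at each division
#' and discarded (the experiments track mother cells). Reproducible under a
#' fixed RNG seed set by the caller.
#'
#' @param params An [energy_params()] object.
#' @param schedule A [make_schedule()] object.
#' @param t_end End time (minutes); defaults to the schedule's total.
#' @param cadence Output cadence (minutes).
#' @param cell One row of [sample_cell_params()] output; drawn if `NULL`.
#' @param state0 Optional initial `"cell_state"` (overrides `cell`).
#' @return An object of class `"lineage_record"`: vectors `time`, `g4`,
#'   `g2`, `volume`, `energy`, plus `division_times`, `c4`, `eps` and the
#'   schedule.
#' @export
simulate_cell <- function(params, schedule, t_end = schedule$total,
                          cadence = 5, cell = NULL, state0 = NULL) {
  stopifnot(inherits(params, "energy_params"),
            inherits(schedule, "glucose_schedule"))
  if (t_end <= 0) stop("t_end must be > 0")
  if (is.null(state0)) {
    if (is.null(cell)) cell <- sample_cell_params(params, 1)
    state0 <- new_cell_state(c4 = cell$c4[1], eps = cell$eps[1])
  }
  res <- dssa_advance_cpp(
    t = state0$t, g4 = state0$g4, g2 = state0$g2, volume = state0$volume,
    pending_time = state0$pending_time,
    pending_species = state0$pending_species,
    division_times = state0$division_times,
    c4 = state0$c4, eps = state0$eps,
    alpha4 = params$alpha4, alpha2 = params$alpha2,
    n4 = params$n4, n2 = params$n2, c2 = params$c2,
    E_glu_max = params$E_glu_max, E_gal_max = params$E_gal_max,
    th_glu = params$th_glu, th_gal = params$th_gal,
    gamma = params$gamma, delay = params$delay, max_step = params$max_step,
    hold = schedule$hold, td = schedule$Td, gs = schedule$g_s,
    t_end = t_end, single_step = FALSE,
    cadence = cadence, record = TRUE)
  structure(list(time = res$trace$time, g4 = res$trace$g4,
                 g2 = res$trace$g2, volume = res$trace$volume,
                 energy = res$trace$energy,
                 division_times = res$division_times,
                 c4 = state0$c4, eps = state0$eps,
                 schedule = schedule),
            class = "lineage_record")
}

#' Simulate a population of independent lineages
#'
#' @inheritParams simulate_cell
#' @param n_cells Number of cells.
#' @param seed Optional integer seed (set once before all draws).
#' @return List of `"lineage_record"` objects.
#' @export
simulate_population <- function(n_cells, params, schedule,
                                t_end = schedule$total, cadence = 5,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- sample_cell_params(params, n_cells)
  lapply(seq_len(n_cells), function(i)
    simulate_cell(params, schedule, t_end = t_end, cadence = cadence,
                  cell = cells[i, , drop = FALSE]))
}

#' Moment-match the basal-energy distribution to diauxic cycle lengths
#'
#' Each diauxic cell-cycle length `L` (hours) implies a basal energy
#' `eps = log(2) / (gamma * 60 * L)` (the energy at which the doubling time
#' equals `L`). The implied values, rescaled to `(0, 1)` by `eps_max`, are
#' fitted with a Beta distribution by the method of moments.
#'
#' @param diauxic_hr Observed diauxic cell-cycle lengths (hours).
#' @param params An [energy_params()] object supplying `gamma` and
#'   `eps_max`.
#' @return List with `eps_shape_a`, `eps_shape_b`, `eps_max` and the implied
#'   `eps` values.
#' @export
fit_epsilon_moments <- function(diauxic_hr, params) {
  stopifnot(inherits(params, "energy_params"))
  if (length(diauxic_hr) < 2 || any(diauxic_hr <= 0))
    stop("need >= 2 positive diauxic cycle lengths")
  eps <- log(2) / (params$gamma * 60 * diauxic_hr)
  eps <- pmin(eps, params$eps_max * 0.999)
  x <- eps / params$eps_max
  m <- mean(x); v <- var(x)
  if (v <= 0 || v >= m * (1 - m))
    stop("implied basal energies are incompatible with a Beta distribution ",
         "on (0, eps_max); consider a larger eps_max")
  a <- m * (m * (1 - m) / v - 1)
  b <- (1 - m) * (m * (1 - m) / v - 1)
  list(eps_shape_a = a, eps_shape_b = b, eps_max = params$eps_max,
       eps_implied = eps)
}

#' Write a simulated population as CSV files
#'
#' Long-format trajectories (`cell_id`, `time_min`, `g4`, `g2`, `volume`,
#' `energy`), a divisions table (`cell_id`, `division_time_min`) and the
#' sampled schedule.
#'
#' @param population List of `"lineage_record"` objects.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_lineage_csvs <- function(population, dir, prefix = "simulated") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- do.call(rbind, lapply(seq_along(population), function(i) {
    l <- population[[i]]
    data.frame(cell_id = i, time_min = l$time, g4 = l$g4, g2 = l$g2,
               volume = l$volume, energy = l$energy)
  }))
  divs <- do.call(rbind, lapply(seq_along(population), function(i) {
    l <- population[[i]]
    if (!length(l$division_times)) return(NULL)
    data.frame(cell_id = i, division_time_min = l$division_times)
  }))
  p1 <- file.path(dir, paste0(prefix, "_trajectories.csv"))
  p2 <- file.path(dir, paste0(prefix, "_divisions.csv"))
  p3 <- file.path(dir, paste0(prefix, "_schedule.csv"))
  write.csv(traj, p1, row.names = FALSE)
  write.csv(if (is.null(divs))
    data.frame(cell_id = integer(0), division_time_min = numeric(0))
    else divs, p2, row.names = FALSE)
  write_schedule_csv(population[[1]]$schedule, p3)
  invisible(c(p1, p2, p3))
}
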
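#' Single-cell trajectory container
#'
#' One cell's fluorescence-intensity (FI) time series, sampled on a uniform
#' cadence, together with its budding-event times and run metadata.
#'
#' @param cell_id Identifier.
#' @param time_min Sampling times (minutes), strictly increasing.
#' @param fi Fluorescence intensities (AU), finite.
#' @param budding_min Budding-event times (minutes), strictly increasing.
#' @param depletion_start_min Time at which glucose depletion begins.
#' @param Td_hr Depletion time of this cell's run (hours).
#' @param fi_true Optional noiseless FI (kept by the synthetic generator so
#'   latents can be checked against emitted signals).
#' @return An object of class `"cell_trajectory"`.
#' @export
cell_trajectory <- function(cell_id, time_min, fi, budding_min = numeric(0),
                            depletion_start_min = NA_real_, Td_hr = NA_real_,
                            fi_true = NULL) {
  if (length(time_min) != length(fi))
    stop("time_min and fi must have equal length")
  if (any(diff(time_min) <= 0))
    stop("time_min must be strictly increasing")
  if (any(!is.finite(fi))) stop("fi must be finite")
  if (length(budding_min) > 1 && any(diff(budding_min) <= 0))
    stop("budding_min must be strictly increasing")
  structure(list(cell_id = cell_id, time_min = time_min, fi = fi,
                 budding_min = budding_min,
                 depletion_start_min = depletion_start_min,
                 Td_hr = Td_hr, fi_true = fi_true),
            class = "cell_trajectory")
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
}

#' Detect the initiation point of a fluorescence trajectory
#'
#' The initiation point is where the FI trajectory turns from falling to
#' rising as the cell switches on GAL expression. The trajectory is smoothed
#' with a centered moving average, discrete slopes are computed, and the
#' initiation sample is the first time at or after the start of glucose
#' depletion where the slope becomes positive and stays positive for
#' `persistence` consecutive intervals. If the slope is already positive at
#' the depletion start (a cell that never dipped), the initiation time is
#' the depletion start itself, so an initiation time is defined even for
#' instantaneous depletion. A trajectory that never turns up is flagged
#' non-inducing.
#'
#' The FI is rescaled by subtracting its (raw) value at the initiation
#' sample, so the rescaled trajectory is exactly zero there.
#'
#' @param traj A [cell_trajectory()] object.
#' @param depletion_start Start of glucose depletion (minutes); defaults to
#'   the trajectory's metadata.
#' @param window Smoothing window in samples (centered moving average).
#' @param persistence Number of consecutive positive-slope intervals
#'   required.
#' @return List of class `"initiation_detection"`: `initiation_hr` (from
#'   depletion start; `NA` if non-inducing), `t_init_min` (absolute),
#'   `index` (initiation sample), `non_inducing`, and `fi_rescaled`.
#' @export
detect_initiation <- function(traj,
                              depletion_start = traj$depletion_start_min,
                              window = 5, persistence = 3) {
  stopifnot(inherits(traj, "cell_trajectory"))
  if (!is.finite(depletion_start))
    stop("depletion_start must be supplied (in minutes)")
  tm <- traj$time_min
  if (depletion_start < tm[1] || depletion_start > tm[length(tm)])
    stop("trajectory does not span depletion_start")
  sm <- moving_average(traj$fi, window)
  slope <- diff(sm)
  pos <- slope > 0
  pos[is.na(pos)] <- FALSE
  # start indices of runs of >= `persistence` positive slopes
  runlen <- as.numeric(stats::filter(as.numeric(pos), rep(1, persistence),
                                     sides = 1))
  starts <- which(runlen == persistence) - persistence + 1L
  i0 <- which(tm >= depletion_start)[1]
  starts <- starts[starts >= i0]
  if (!length(starts)) {
    return(structure(list(initiation_hr = NA_real_, t_init_min = NA_real_,
                          index = NA_integer_, non_inducing = TRUE,
                          fi_rescaled = NULL, traj = traj),
                     class = "initiation_detection"))
  }
  idx <- starts[1]
  # boundary convention: already rising at the depletion start
  t_init <- if (idx == i0) depletion_start else tm[idx]
  structure(list(initiation_hr = (t_init - depletion_start) / 60,
                 t_init_min = t_init, index = idx, non_inducing = FALSE,
                 fi_rescaled = traj$fi - traj$fi[idx], traj = traj),
            class = "initiation_detection")
}

#' Accumulation time of a rescaled trajectory
#'
#' Time for the rescaled FI (zero at the initiation point) to first reach a
#' fixed threshold, with linear interpolation between the bracketing samples
#' to remove sampling-cadence quantisation. The reference point defaults to
#' the initiation point; `reference = "depletion_start"` measures from the
#' start of glucose depletion instead (both definitions are in use for this
#' quantity, so reports should state which was chosen). A trajectory that
#' never reaches the threshold within the record is flagged censored.
#'
#' @param detection An `"initiation_detection"` from [detect_initiation()].
#' @param threshold_au Threshold on the rescaled FI (AU).
#' @param reference `"initiation"` or `"depletion_start"`.
#' @return List: `accumulation_hr` (`NA` if censored or non-inducing),
#'   `censored`, `t_cross_min`, `reference`.
#' @export
accumulation_time <- function(detection, threshold_au = 200,
                              reference = c("initiation",
                                            "depletion_start")) {
  stopifnot(inherits(detection, "initiation_detection"))
  reference <- match.arg(reference)
  if (detection$non_inducing)
    return(list(accumulation_hr = NA_real_, censored = NA,
                t_cross_min = NA_real_, reference = reference))
  tm <- detection$traj$time_min
  fi <- detection$fi_rescaled
  idx <- detection$index
  after <- seq(idx, length(fi))
  hit <- after[which(fi[after] >= threshold_au)[1]]
  if (is.na(hit))
    return(list(accumulation_hr = NA_real_, censored = TRUE,
                t_cross_min = NA_real_, reference = reference))
  if (hit == idx) {
    t_cross <- tm[hit]                       # already above at initiation
  } else {
    f0 <- fi[hit - 1]; f1 <- fi[hit]
    t_cross <- tm[hit - 1] +
      (threshold_au - f0) / (f1 - f0) * (tm[hit] - tm[hit - 1])
  }
  ref_t <- switch(reference,
                  initiation = detection$t_init_min,
                  depletion_start = detection$traj$depletion_start_min)
  list(accumulation_hr = (t_cross - ref_t) / 60, censored = FALSE,
       t_cross_min = t_cross, reference = reference)
}

#' Cell-cycle lengths from budding events
#'
#' The cell-cycle length is the time between two successive budding events.
#'
#' @param budding_min Budding-event times (minutes), strictly increasing.
#' @return Cycle lengths in hours; a zero-length vector with attribute
#'   `too_few = TRUE` if fewer than two events were recorded.
#' @export
cell_cycle_lengths <- function(budding_min) {
  if (length(budding_min) < 2)
    return(structure(numeric(0), too_few = TRUE))
  if (any(diff(budding_min) <= 0))
    stop("budding_min must be strictly increasing")
  diff(budding_min) / 60
}

#' Filter cells by division-completion criteria
#'
#' Retains only cells with at least `min_divisions` recorded budding events;
#' among those, a cell whose last observed cell cycle is the unique longest
#' one is considered not to have exited the diauxic lag phase and is
#' dropped. Machine-readable discard reasons are attached.
#'
#' @param budding List of numeric vectors of budding times (minutes), one
#'   per cell, optionally named, or a data frame with columns `cell_id` and
#'   `bud_time_min`.
#' @param min_divisions Minimum number of budding events.
#' @return Data frame with `cell_id`, `n_buds`, `retained`, `reason`
#'   (`NA`, `"too_few_divisions"` or `"incomplete_diauxic_exit"`).
#' @export
filter_cells <- function(budding, min_divisions = 6) {
  if (is.data.frame(budding)) {
    stopifnot(all(c("cell_id", "bud_time_min") %in% names(budding)))
    budding <- split(budding$bud_time_min, budding$cell_id)
    budding <- lapply(budding, sort)
  }
  ids <- if (!is.null(names(budding))) names(budding)
         else as.character(seq_along(budding))
  rows <- lapply(seq_along(budding), function(i) {
    b <- budding[[i]]
    n <- length(b)
    if (n < min_divisions)
      return(data.frame(cell_id = ids[i], n_buds = n, retained = FALSE,
                        reason = "too_few_divisions"))
    cyc <- diff(b)
    last_is_unique_max <- cyc[length(cyc)] == max(cyc) &&
      sum(cyc == max(cyc)) == 1L
    if (last_is_unique_max)
      return(data.frame(cell_id = ids[i], n_buds = n, retained = FALSE,
                        reason = "incomplete_diauxic_exit"))
    data.frame(cell_id = ids[i], n_buds = n, retained = TRUE,
               reason = NA_character_)
  })
  do.call(rbind, rows)
}

#' Classify cell cycles into glucose / diauxie / galactose regimes
#'
#' Progressive three-group clustering of an ordered cycle-length sequence.
#' Group centers are initialised from the sequence itself: the glucose mean
#' is the first cycle, the galactose mean the last cycle, and the diauxie
#' mean the longest cycle. The first cycle is labeled Glucose; each
#' subsequent cycle is compared only against its current group and the next
#' one in stage order (Glucose vs Diauxie after a Glucose cycle, Diauxie vs
#' Galactose after a Diauxie cycle) and assigned to the nearer center; after
#' the first Galactose label all remaining cycles stay Galactose. Ties go to
#' the earlier-stage group, so labels are always monotone in the order
#' Glucose -> Diauxie -> Galactose.
#'
#' @param cycle_lengths_hr Ordered cycle lengths (hours), length `>= 3`.
#' @param running_mean Update the active group center with the running mean
#'   of its assigned members (sensitivity variant); the default keeps the
#'   centers fixed at initialisation.
#' @return An object of class `"cell_cycle_record"`: `lengths_hr`, `labels`
#'   (character, one of Glucose/Diauxie/Galactose), and `mu` (the three
#'   initial centers).
#' @export
classify_cycles <- function(cycle_lengths_hr, running_mean = FALSE) {
  L <- cycle_lengths_hr
  n <- length(L)
  if (n < 3) stop("need at least 3 cycles to classify")
  if (any(!is.finite(L)) || any(L <= 0))
    stop("cycle lengths must be positive and finite")
  mu <- c(Glucose = L[1], Diauxie = max(L), Galactose = L[n])
  cur <- mu
  members <- list(Glucose = L[1], Diauxie = numeric(0),
                  Galactose = numeric(0))
  labels <- character(n)
  labels[1] <- "Glucose"
  for (i in 2:n) {
    prev <- labels[i - 1]
    if (prev == "Glucose") {
      lab <- if (abs(L[i] - cur["Glucose"]) <= abs(L[i] - cur["Diauxie"]))
        "Glucose" else "Diauxie"
    } else if (prev == "Diauxie") {
      lab <- if (abs(L[i] - cur["Diauxie"]) <= abs(L[i] - cur["Galactose"]))
        "Diauxie" else "Galactose"
    } else {
      lab <- "Galactose"
    }
    labels[i] <- lab
    if (running_mean) {
      members[[lab]] <- c(members[[lab]], L[i])
      cur[lab] <- mean(members[[lab]])
    }
  }
  structure(list(lengths_hr = L, labels = labels, mu = mu,
                 running_mean = running_mean),
            class = "cell_cycle_record")
}

#' Diauxic cell-cycle length of a classified record
#'
#' The longest observed cycle, used as the estimate of the diauxic cell
#' cycle length (it is also the diauxie group's initial center).
#'
#' @param record A `"cell_cycle_record"` from [classify_cycles()].
#' @return Length in hours.
#' @export
diauxic_length <- function(record) {
  stopifnot(inherits(record, "cell_cycle_record"))
  max(record$lengths_hr)
}

#' Filter and classify a population's budding records
#'
#' Applies [filter_cells()] then [classify_cycles()] per retained cell.
#'
#' @inheritParams filter_cells
#' @param running_mean Passed to [classify_cycles()].
#' @return List with `cells` (the filter table, plus `diauxic_hr` for
#'   retained cells) and `cycles` (data frame `cell_id`, `cycle_index`,
#'   `length_hr`, `label`).
#' @export
classify_population <- function(budding, min_divisions = 6,
                                running_mean = FALSE) {
  if (is.data.frame(budding)) {
    stopifnot(all(c("cell_id", "bud_time_min") %in% names(budding)))
    budding <- lapply(split(budding$bud_time_min, budding$cell_id), sort)
  }
  cells <- filter_cells(budding, min_divisions = min_divisions)
  cells$diauxic_hr <- NA_real_
  ids <- if (!is.null(names(budding))) names(budding)
         else as.character(seq_along(budding))
  cyc_rows <- list()
  for (i in seq_along(budding)) {
    if (!cells$retained[cells$cell_id == ids[i]]) next
    lens <- cell_cycle_lengths(budding[[i]])
    rec <- classify_cycles(lens, running_mean = running_mean)
    cells$diauxic_hr[cells$cell_id == ids[i]] <- diauxic_length(rec)
    cyc_rows[[length(cyc_rows) + 1L]] <- data.frame(
      cell_id = ids[i], cycle_index = seq_along(lens),
      length_hr = lens, label = rec$labels)
  }
  cycles <- if (length(cyc_rows)) do.call(rbind, cyc_rows)
            else data.frame(cell_id = character(0), cycle_index = integer(0),
                            length_hr = numeric(0), label = character(0))
  list(cells = cells, cycles = cycles)
}

#' Extract initiation and accumulation features from trajectories
#'
#' Runs [detect_initiation()] and [accumulation_time()] over a list of
#' trajectories and returns one row per cell with quality-control flags.
#'
#' @param trajectories List of [cell_trajectory()] objects.
#' @param threshold_au Accumulation threshold (AU).
#' @param reference Accumulation reference point (see
#'   [accumulation_time()]).
#' @param window,persistence Passed to [detect_initiation()].
#' @return Data frame: `cell_id`, `Td_hr`, `initiation_hr`,
#'   `accumulation_hr`, `non_inducing`, `censored`.
#' @export
extract_features <- function(trajectories, threshold_au = 200,
                             reference = "initiation",
                             window = 5, persistence = 3) {
  rows <- lapply(trajectories, function(traj) {
    det <- detect_initiation(traj, window = window,
                             persistence = persistence)
    acc <- accumulation_time(det, threshold_au = threshold_au,
                             reference = reference)
    data.frame(cell_id = traj$cell_id, Td_hr = traj$Td_hr,
               initiation_hr = det$initiation_hr,
               accumulation_hr = acc$accumulation_hr,
               non_inducing = det$non_inducing,
               censored = isTRUE(acc$censored))
  })
  do.call(rbind, rows)
}
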
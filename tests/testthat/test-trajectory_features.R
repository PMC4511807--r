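test_that("the initiation point of a clean V is its exact minimum", {
  tr <- v_trajectory(t_min = 300, t_total = 600)
  d <- detect_initiation(tr)
  expect_false(d$non_inducing)
  expect_equal(d$t_init_min, 300)
  expect_equal(d$initiation_hr, 5)
  # rescaled FI is exactly zero at the initiation sample
  expect_equal(d$fi_rescaled[d$index], 0)
})

test_that("a trajectory already rising at depletion start initiates there", {
  tm <- seq(0, 600, 5)
  tr <- cell_trajectory(1, tm, fi = 10 + 0.5 * tm,
                        depletion_start_min = 240)
  d <- detect_initiation(tr)
  expect_equal(d$t_init_min, 240)
  expect_equal(d$initiation_hr, 0)
})

test_that("a monotone-decreasing trajectory is flagged non-inducing", {
  tm <- seq(0, 600, 5)
  tr <- cell_trajectory(1, tm, fi = 1000 - tm, depletion_start_min = 0)
  d <- detect_initiation(tr)
  expect_true(d$non_inducing)
  expect_true(is.na(d$initiation_hr))
})

test_that("noisy V minima are located within two samples 95% of the time", {
  set.seed(7)
  err <- replicate(200, {
    tr <- v_trajectory(t_min = 150, t_total = 600, noise_sd = 0.05 * 150)
    abs(detect_initiation(tr)$t_init_min - 150) / 5
  })
  expect_gte(mean(err <= 2), 0.95)
})

test_that("detection and accumulation are invariant to constant FI offsets", {
  set.seed(8)
  tm <- seq(0, 600, 5)
  base <- abs(tm - 200) * 3 + rnorm(length(tm), 0, 10)
  d1 <- detect_initiation(cell_trajectory(1, tm, base,
                                          depletion_start_min = 0))
  d2 <- detect_initiation(cell_trajectory(1, tm, base + 5000,
                                          depletion_start_min = 0))
  expect_equal(d1$t_init_min, d2$t_init_min)
  expect_equal(d1$fi_rescaled, d2$fi_rescaled)
  a1 <- accumulation_time(d1, threshold_au = 200)
  a2 <- accumulation_time(d2, threshold_au = 200)
  expect_equal(a1$accumulation_hr, a2$accumulation_hr)
})

test_that("accumulation time interpolates the threshold crossing", {
  # rescaled FI rises at 2 AU/min after initiation at t = 100
  tm <- seq(0, 400, 5)
  fi <- ifelse(tm < 100, 100 - tm, 2 * (tm - 100))
  d <- detect_initiation(cell_trajectory(1, tm, fi,
                                         depletion_start_min = 0),
                         window = 1, persistence = 1)
  a <- accumulation_time(d, threshold_au = 200)
  expect_false(a$censored)
  expect_equal(a$accumulation_hr, 100 / 60, tolerance = 1e-10)

  # crossing between samples: hand-computed interpolation
  fi2 <- ifelse(tm < 100, 100 - tm, 0)
  fi2[tm == 195] <- 180
  fi2[tm >= 200] <- 230
  d2 <- detect_initiation(cell_trajectory(1, tm, fi2,
                                          depletion_start_min = 0),
                          window = 1, persistence = 1)
  a2 <- accumulation_time(d2, threshold_au = 200)
  # linear bracket (195, 180) -> (200, 230) crosses 200 at t = 197
  expect_equal(a2$t_cross_min, 195 + (200 - 180) / (230 - 180) * 5)

  # measured from the depletion start instead of the initiation point
  a3 <- accumulation_time(d, threshold_au = 200,
                          reference = "depletion_start")
  expect_equal(a3$accumulation_hr,
               a$accumulation_hr + d$initiation_hr)
})

test_that("a plateau below the threshold is censored", {
  tm <- seq(0, 400, 5)
  fi <- ifelse(tm < 100, 100 - tm, pmin(1.5 * (tm - 100), 150))
  d <- detect_initiation(cell_trajectory(1, tm, fi,
                                         depletion_start_min = 0))
  a <- accumulation_time(d, threshold_au = 200)
  expect_true(a$censored)
  expect_true(is.na(a$accumulation_hr))
})

test_that("cell-cycle lengths are successive budding differences in hours", {
  expect_equal(cell_cycle_lengths(c(0, 84, 168)), c(1.4, 1.4))
  expect_equal(cell_cycle_lengths(c(0, 83, 250, 349)),
               c(83, 167, 99) / 60)
  short <- cell_cycle_lengths(c(100))
  expect_length(short, 0)
  expect_true(attr(short, "too_few"))
})

test_that("cells are filtered on division count and diauxic exit", {
  buds <- list(
    few = cumsum(c(0, rep(84, 4))),                          # 5 events
    stuck = cumsum(c(0, 1.4, 1.4, 3.0, 1.7, 1.6, 4.9) * 60), # last is max
    ok = cumsum(c(0, 1.4, 1.3, 4.5, 1.7, 1.6, 1.65) * 60))
  f <- filter_cells(buds)
  expect_equal(f$retained, c(FALSE, FALSE, TRUE))
  expect_equal(f$reason[1], "too_few_divisions")
  expect_equal(f$reason[2], "incomplete_diauxic_exit")
  expect_true(is.na(f$reason[3]))
})

test_that("progressive clustering reproduces hand-traced label sequences", {
  r1 <- classify_cycles(c(1.4, 1.3, 4.5, 1.7, 1.6, 1.65))
  expect_equal(r1$labels, c("Glucose", "Glucose", "Diauxie",
                            "Galactose", "Galactose", "Galactose"))
  expect_equal(diauxic_length(r1), 4.5)

  r2 <- classify_cycles(c(1.0, 5.0, 1.2, 1.2, 1.2, 1.2))
  expect_equal(r2$labels, c("Glucose", "Diauxie", rep("Galactose", 4)))

  # degenerate all-equal sequence: ties resolve to the earlier stage
  r3 <- classify_cycles(rep(1.5, 6))
  expect_equal(diff(match(r3$labels,
                          c("Glucose", "Diauxie", "Galactose"))) >= 0,
               rep(TRUE, 5))

  expect_error(classify_cycles(c(1, 2)), "at least 3")
})

test_that("labels are monotone in stage order and scale-invariant", {
  set.seed(14)
  stages <- c("Glucose", "Diauxie", "Galactose")
  for (i in 1:200) {
    L <- abs(rnorm(sample(3:12, 1), 2, 1)) + 0.1
    r <- classify_cycles(L)
    expect_true(all(diff(match(r$labels, stages)) >= 0))
    # uniform time-unit rescaling leaves the classification unchanged
    expect_equal(classify_cycles(L * 60)$labels, r$labels)
  }
})

test_that("population classification books every cell as retained or discarded", {
  pop <- generate_threshold_population(generator_config(n_cells = 40),
                                       Td_hr = 2, seed = 15)
  buds <- lapply(pop$trajectories, function(tr) tr$budding_min)
  cls <- classify_population(buds)
  expect_equal(nrow(cls$cells), 40)
  expect_equal(sum(cls$cells$retained) + sum(!cls$cells$retained), 40)
  expect_true(all(cls$cycles$cell_id %in%
                    cls$cells$cell_id[cls$cells$retained]))
  expect_true(all(is.finite(cls$cells$diauxic_hr[cls$cells$retained])))
})
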
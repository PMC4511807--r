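test_that("Hill propensities hit their anchor points", {
  p <- energy_params(alpha4 = 10, n4 = 2, c4_mean = 1)
  expect_equal(propensity_gal4(0, p), 10)          # no repression
  expect_equal(propensity_gal4(1, p), 5)           # half-maximal at c4
  expect_equal(propensity_gal4(2, p, c4 = 1), 2)   # 10 / (1 + 4)

  p2 <- energy_params(alpha2 = 6, n2 = 2, c2 = 50)
  expect_equal(propensity_gal2(0, p2), 0)          # no activator
  expect_equal(propensity_gal2(50, p2), 3)         # half-maximal at c2
  expect_equal(propensity_gal2(100 * 50, p2), 6, tolerance = 0.01)
})

test_that("energy is the max of its saturating arms and the basal floor", {
  p <- energy_params(E_glu_max = 1, E_gal_max = 0.84, th_glu = 0.5,
                     th_gal = 200)
  expect_equal(energy(glu = 2, g2 = 0, eps = 0.1, p), 1)      # saturated
  expect_equal(energy(glu = 0, g2 = 0, eps = 0.1, p), 0.1)    # basal floor
  expect_equal(energy(glu = 0.25, g2 = 100, eps = 0.1, p),
               max(0.5, 0.42, 0.1))
})

test_that("parameter invariants are enforced", {
  expect_error(energy_params(E_gal_max = 1.5, E_glu_max = 1), "E_gal_max")
  expect_error(energy_params(eps_max = 0.9, E_gal_max = 0.85), "eps_max")
  expect_error(energy_params(alpha4 = -1), "production rates")
  expect_error(energy_params(th_glu = 0), "> 0")
})

test_that("per-cell heterogeneity draws follow their distributions", {
  p <- energy_params(c4_sd = 0)
  cells <- sample_cell_params(p, 5)
  expect_equal(cells$c4, rep(p$c4_mean, 5))   # degenerate draw

  set.seed(12)
  p2 <- energy_params()
  cells <- sample_cell_params(p2, 1e4)
  expect_true(all(cells$eps > 0 & cells$eps < p2$eps_max))
  expect_true(all(cells$c4 > 0))
  # scaled-Beta mean within 3 SE
  a <- p2$eps_shape_a; b <- p2$eps_shape_b
  mu <- p2$eps_max * a / (a + b)
  se <- p2$eps_max * sqrt(a * b / ((a + b)^2 * (a + b + 1))) / sqrt(1e4)
  expect_lt(abs(mean(cells$eps) - mu), 3 * se)

  # pinned basal energy for the constant-E control
  pc <- constant_energy_params(p2, E = 0.7)
  expect_equal(sample_cell_params(pc, 3)$eps, rep(0.7, 3))
})

test_that("an empty reaction system advances in exact capped steps", {
  p <- energy_params(alpha4 = 0, alpha2 = 0, gamma = 0)
  s <- flat_schedule()
  st <- new_cell_state(c4 = 1.4, eps = 0.3)
  for (k in 1:5) st <- step_dssa(st, s, p)
  expect_equal(st$t, 5 * p$max_step)
  expect_equal(st$g4, 0L)
  expect_equal(st$g2, 0L)
  expect_equal(st$volume, 1)
})

test_that("division partitions everything binomially and conserves counts", {
  st <- new_cell_state(c4 = 1.4, eps = 0.3, g4 = 40, g2 = 60)
  st$volume <- 2
  st$pending_time <- c(1.5, 2.5, 3.5)
  st$pending_species <- c(4L, 2L, 4L)

  expect_error(divide(new_cell_state(c4 = 1, eps = 0.1)), "volume < 2")

  set.seed(4)
  out <- divide(st)
  expect_equal(out$mother$g4 + out$daughter$g4, 40)
  expect_equal(out$mother$g2 + out$daughter$g2, 60)
  expect_equal(length(out$mother$pending_time) +
                 length(out$daughter$pending_time), 3)
  expect_setequal(c(out$mother$pending_time, out$daughter$pending_time),
                  st$pending_time)
  expect_equal(out$mother$volume, 1)
  expect_equal(out$daughter$volume, 1)
  expect_equal(out$mother$division_times, st$t)

  # nothing to split
  empty <- new_cell_state(c4 = 1, eps = 0.1)
  empty$volume <- 2
  out0 <- divide(empty)
  expect_equal(out0$daughter$g4, 0L)
  expect_equal(out0$daughter$g2, 0L)
  expect_length(out0$daughter$pending_time, 0)

  # binomial mean: daughters get half on average
  set.seed(9)
  d4 <- replicate(5000, {
    s1 <- new_cell_state(c4 = 1, eps = 0.1, g4 = 100)
    s1$volume <- 2
    divide(s1)$daughter$g4
  })
  se <- sqrt(100 * 0.25 / 5000)
  expect_lt(abs(mean(d4) - 50), 3 * se)
})

test_that("severed activation keeps the transporter absent", {
  set.seed(21)
  p <- energy_params(alpha2 = 0)
  l <- simulate_cell(p, make_schedule(Td = 0, total = 900))
  expect_true(all(l$g2 == 0))
  expect_gt(max(l$g4), 0)
})

test_that("repressed cells in constant glucose divide on the glucose clock", {
  set.seed(22)
  p <- energy_params()
  l <- simulate_cell(p, make_schedule(Td = 0, hold = 900, total = 900))
  expect_lt(max(l$g4), p$c2 / 2)      # network OFF in 2% glucose
  expect_lt(max(l$g2), 10)            # only basal Hill leakage
  # E = E_glu_max throughout, so divisions are deterministic
  expect_equal(diff(l$division_times),
               rep(log(2) / (p$E_glu_max * p$gamma),
                   length(l$division_times) - 1),
               tolerance = 1e-8)
})

test_that("instantaneous depletion stalls the division clock", {
  set.seed(23)
  p <- energy_params()
  s <- make_schedule(Td = 0, hold = 240, total = 1200)
  pre <- c(); post <- c()
  for (i in 1:20) {
    l <- simulate_cell(p, s, t_end = 1200)
    iv <- diff(l$division_times)
    mid <- l$division_times[-length(l$division_times)]
    pre <- c(pre, iv[mid < 240 & l$division_times[-1] <= 240])
    first_after <- which(mid >= 240)[1]
    if (!is.na(first_after)) post <- c(post, iv[first_after])
  }
  expect_gt(mean(post), mean(pre))
})

test_that("simulation is bit-reproducible under a fixed seed and stays in bounds", {
  p <- energy_params()
  s <- make_schedule(Td = 240, total = 900)
  pop1 <- simulate_population(4, p, s, seed = 77)
  pop2 <- simulate_population(4, p, s, seed = 77)
  expect_identical(pop1, pop2)
  for (l in pop1) {
    expect_true(all(diff(l$time) > 0))
    expect_true(all(l$g4 >= 0 & l$g2 >= 0))
    expect_true(all(l$g4 == round(l$g4) & l$g2 == round(l$g2)))
    expect_true(all(l$volume >= 1 - 1e-12 & l$volume < 2 + 1e-12))
    expect_true(all(l$energy >= l$eps - 1e-12 &
                      l$energy <= p$E_glu_max + 1e-12))
    if (length(l$division_times) > 1)
      expect_true(all(diff(l$division_times) > 0))
  }
})

test_that("energy declines monotonically through the ramp in the repressed sub-case", {
  set.seed(25)
  p <- energy_params(alpha2 = 0)   # g2 = 0: the galactose arm never engages
  s <- make_schedule(Td = 360, hold = 240, total = 900)
  l <- simulate_cell(p, s)
  ramp <- l$time >= 240 & l$time <= 600
  expect_true(all(diff(l$energy[ramp]) <= 1e-12))
})

test_that("basal-energy moment matching inverts the growth-rate map", {
  p <- energy_params()
  set.seed(26)
  eps_true <- p$eps_max * rbeta(2000, 2, 4)
  # implied diauxic cycle lengths at these basal energies
  dia_hr <- log(2) / (p$gamma * eps_true) / 60
  fit <- fit_epsilon_moments(dia_hr, p)
  expect_equal(fit$eps_shape_a, 2, tolerance = 0.15)
  expect_equal(fit$eps_shape_b, 4, tolerance = 0.15)
  expect_error(fit_epsilon_moments(c(-1, 2), p), "positive")
})

test_that("lineage CSV export writes the trajectory, division and schedule tables", {
  p <- energy_params()
  s <- make_schedule(Td = 0, total = 600)
  pop <- simulate_population(2, p, s, t_end = 600, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_lineage_csvs(pop, dir)
  expect_true(all(file.exists(paths)))
  traj <- read.csv(paths[1])
  expect_named(traj, c("cell_id", "time_min", "g4", "g2", "volume",
                       "energy"))
  expect_equal(sort(unique(traj$cell_id)), 1:2)
})
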
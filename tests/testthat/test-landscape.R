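test_that("free-energy differences follow -ln P exactly", {
  # two occupied bins with probabilities 0.8 / 0.2: dF = ln 4
  q <- c(rep(0.1, 800), rep(0.9, 200))
  prof <- free_energy_profile(q, bins = 2, require_two_state = FALSE)
  expect_equal(diff(prof$f_values), log(4))

  # equally populated bins: dF = 0
  q2 <- c(rep(0.1, 500), rep(0.9, 500))
  prof2 <- free_energy_profile(q2, bins = 2, require_two_state = FALSE)
  expect_equal(diff(prof2$f_values), 0)

  expect_error(free_energy_profile(c(0.5, 1.2)), "outside")
})

test_that("three-bin closed-form barrier is reproduced exactly", {
  # probabilities {0.45, 0.10, 0.45} -> barrier ln(0.45/0.10)
  q <- c(rep(1 / 6, 4500), rep(3 / 6, 1000), rep(5 / 6, 4500))
  prof <- free_energy_profile(q, bins = 3)
  expect_equal(prof$basin_unfolded, 1L)
  expect_equal(prof$barrier_bin, 2L)
  expect_equal(prof$basin_folded, 3L)
  expect_equal(barrier_height(prof), log(0.45 / 0.10))
})

test_that("flat and single-basin profiles are rejected as non-two-state", {
  flat <- rep((1:20 - 0.5) / 20, each = 250) # exactly uniform histogram
  expect_error(free_energy_profile(flat, bins = 20), "two-state")
  set.seed(1)
  single <- pmin(pmax(rnorm(5000, 0.5, 0.05), 0), 1)
  expect_error(free_energy_profile(single, bins = 20), "two-state")
})

test_that("exponentiating -F recovers the binned distribution", {
  traj <- two_state_q_series(n_frames = 2e4, seed = 3)
  prof <- free_energy_profile(traj, bins = 50)
  occ <- !is.na(prof$f_values)
  p_back <- exp(-prof$f_values[occ])
  p_back <- p_back / sum(p_back)
  expect_equal(p_back, prof$counts[occ] / sum(prof$counts), tolerance = 1e-12)
})

test_that("synthetic two-state series recovers its generating profile", {
  traj <- two_state_q_series(n_frames = 2e5, seed = 11)
  prof <- free_energy_profile(traj, bins = 50)
  # compare recovered F against the exact generating F where both defined
  f_gen <- -log(traj$true_bin_mass)
  occ <- !is.na(prof$f_values) & is.finite(f_gen)
  delta <- (prof$f_values - f_gen)[occ]
  delta <- delta - stats::median(delta) # profiles defined up to a constant
  # well-populated bins agree within sampling error
  good <- traj$true_bin_mass[occ] > 1e-3
  expect_lt(max(abs(delta[good])), 0.15)
  expect_equal(barrier_height(prof), traj$true_barrier, tolerance = 0.1)
})

test_that("equal basin weights give equal basins before reweighting", {
  traj <- two_state_q_series(basin_weights = c(0.5, 0.5), n_frames = 2e5,
                             seed = 5)
  prof <- free_energy_profile(traj, bins = 50)
  expect_equal(prof$f_values[prof$basin_unfolded],
               prof$f_values[prof$basin_folded], tolerance = 0.1)
})

test_that("reweighting equalizes basins and is a fixed point when equal", {
  # already-equal basins: beta' = beta, profile unchanged up to a constant
  traj_eq <- two_state_q_series(basin_weights = c(0.5, 0.5),
                                n_frames = 2e5, seed = 8)
  prof_eq <- reweight_equal_basins(traj_eq, bins = 50)
  expect_equal(prof_eq$beta_prime_ratio, 1, tolerance = 0.02)

  # skewed basins become equal (and are set to zero)
  traj <- two_state_q_series(basin_weights = c(0.7, 0.3), n_frames = 2e5,
                             seed = 9)
  prof <- reweight_equal_basins(traj, bins = 50)
  expect_equal(prof$f_values[prof$basin_unfolded], 0, tolerance = 0.05)
  expect_equal(prof$f_values[prof$basin_folded], 0, tolerance = 0.05)
  expect_gt(prof$beta_prime_ratio, 1) # cooling favors the low-E folded side
})

test_that("reweighting is invariant to uniform energy offsets", {
  traj <- two_state_q_series(basin_weights = c(0.65, 0.35), n_frames = 1e5,
                             seed = 13)
  prof1 <- reweight_equal_basins(traj, bins = 50)
  traj2 <- traj
  traj2$e_series <- traj2$e_series + 1234.5
  prof2 <- reweight_equal_basins(traj2, bins = 50)
  expect_equal(prof2$beta_prime_ratio, prof1$beta_prime_ratio,
               tolerance = 1e-6)
  expect_equal(prof2$f_values, prof1$f_values, tolerance = 1e-8)
})

test_that("root-found reweighting matches a dense grid search", {
  traj <- two_state_q_series(basin_weights = c(0.7, 0.3), n_frames = 1e5,
                             seed = 21)
  prof <- reweight_equal_basins(traj, bins = 50)
  base <- free_energy_profile(traj$q_series, bins = 50)
  split_q <- base$bin_centers[base$barrier_bin]
  beta <- 1 / traj$temperature
  e0 <- traj$e_series - mean(traj$e_series)
  gap <- vapply(seq(0.8, 1.2, by = 5e-4), function(r) {
    w <- exp(-(r - 1) * beta * e0)
    p <- free_energy_profile(traj$q_series, bins = 50, weights = w,
                             require_two_state = FALSE)
    lo <- p$bin_centers < split_q
    abs(min(p$f_values[!lo], na.rm = TRUE) -
          min(p$f_values[lo], na.rm = TRUE))
  }, numeric(1))
  grid_best <- seq(0.8, 1.2, by = 5e-4)[which.min(gap)]
  expect_equal(prof$beta_prime_ratio, grid_best, tolerance = 1e-3)
})

test_that("barrier is stable to bin-count changes and energy offsets", {
  traj <- two_state_q_series(basin_weights = c(0.6, 0.4), n_frames = 2e5,
                             seed = 17)
  b50 <- barrier_height(reweight_equal_basins(traj, bins = 50))
  b40 <- barrier_height(reweight_equal_basins(traj, bins = 40))
  b60 <- barrier_height(reweight_equal_basins(traj, bins = 60))
  expect_lt(abs(b40 - b50), 0.2)
  expect_lt(abs(b60 - b50), 0.2)
})

test_that("average contact maps pool snapshots near the target Q", {
  flags <- rbind(c(TRUE, TRUE), c(TRUE, FALSE), c(TRUE, FALSE),
                 c(FALSE, FALSE), c(TRUE, TRUE))
  traj <- structure(
    list(q_series = c(0.4, 0.41, 0.39, 0.40, 0.9),
         e_series = rep(0, 5), contact_formed = flags,
         temperature = 1, seed = 1L, save_every = 1L, timestep = 1,
         n_contacts = 2L),
    class = "sbm_trajectory")
  acm <- average_contact_map(traj, q_target = 0.4, tol = 0.02)
  expect_equal(acm$n_snapshots, 4L)
  expect_equal(unname(acm$probability), c(3 / 4, 1 / 4))
  expect_error(average_contact_map(traj, q_target = 0.7, tol = 0.01),
               "no snapshots")
  traj$contact_formed <- NULL
  expect_error(average_contact_map(traj, 0.4), "flags")
})

test_that("profile difference aligns bins across two profiles", {
  t1 <- two_state_q_series(n_frames = 5e4, seed = 2)
  t2 <- two_state_q_series(n_frames = 5e4, seed = 4, barrier_height = 4)
  p1 <- free_energy_profile(t1, bins = 50)
  p2 <- free_energy_profile(t2, bins = 50)
  d <- profile_difference(p1, p2)
  expect_true(all(d$delta == d$f_b - d$f_a))
  expect_true(all(d$q %in% p1$bin_centers))
})
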
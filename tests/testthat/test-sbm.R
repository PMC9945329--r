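# Reference fixture protocol for desk-scale folding runs: 20-bead toy
# fold with a 7.0 Angstrom CA-CA cutoff map (single-bead residues lack
# side-chain atoms, so the bead-level cutoff is wider than the 6 Angstrom
# heavy-atom criterion used for topology metrics).
toy_sbm <- function(seed = 3, cutoff = 7.0) {
  s <- toy_fold(20, seed = seed)
  m <- cutoff_residue_map(atom_contacts(s, cutoff, min_sep = 4), s$length)
  build_sbm(s, m)
}

test_that("topology construction counts bonded terms and filters pairs", {
  # 4-bead chain: 3 bonds, 2 angles, 1 dihedral
  s4 <- toy_fold(8, seed = 1)
  s4$atoms <- s4$atoms[1:4, ]
  s4$residues <- s4$residues[1:4, ]
  s4$length <- 4L
  m4 <- new_contact_map(matrix(c(0L, 3L), ncol = 2), 4L)
  t4 <- build_sbm(s4, m4, min_sep = 3L)
  expect_equal(nrow(t4$bonds), 3L)
  expect_equal(nrow(t4$angles), 2L)
  expect_equal(nrow(t4$dihedrals), 1L)
  expect_equal(nrow(t4$contacts), 1L)

  # pairs below the separation floor are rejected from the contact set
  m_close <- new_contact_map(rbind(c(0L, 2L), c(0L, 3L)), 4L)
  t_f <- build_sbm(s4, m_close, min_sep = 3L)
  expect_equal(nrow(t_f$contacts), 1L) # only (0,3) survives

  # missing CA is an error
  s_bad <- toy_fold(10, seed = 1)
  s_bad$atoms$name[3] <- "CB"
  expect_error(build_sbm(s_bad, new_contact_map(rbind(c(0L, 5L)), 10L)),
               "CA")
})

test_that("native geometry sits at the potential minimum", {
  topo <- toy_sbm()
  eb <- potential_energy(topo, breakdown = TRUE)
  # bonded terms vanish identically at the native geometry
  expect_equal(unname(eb["bond"]), 0, tolerance = 1e-20)
  expect_equal(unname(eb["angle"]), 0, tolerance = 1e-20)
  expect_equal(unname(eb["dihedral"]), 0, tolerance = 1e-20)
  # each contact contributes exactly -epsilon
  expect_equal(unname(eb["contact"]), -nrow(topo$contacts))
  # residual repulsion from just-outside-cutoff pairs is small
  expect_lt(unname(eb["repulsion"]), 0.05 * nrow(topo$contacts))

  # near-stationary point: net force is tiny compared to thermal forces
  f <- net_forces(topo)
  expect_lt(max(abs(f)), 0.5)

  # any perturbation raises the energy
  e0 <- potential_energy(topo)
  set.seed(1)
  for (i in 1:5) {
    pert <- topo$native_xyz + matrix(rnorm(60, sd = 0.2), ncol = 3)
    expect_gt(potential_energy(topo, pert), e0)
  }
})

test_that("analytic forces match finite differences of the energy", {
  topo <- toy_sbm(seed = 5)
  set.seed(7)
  xyz <- topo$native_xyz + matrix(rnorm(60, sd = 0.3), ncol = 3)
  f <- net_forces(topo, xyz)
  h <- 1e-6
  for (probe in list(c(1, 1), c(7, 2), c(13, 3), c(20, 1))) {
    i <- probe[1]; c <- probe[2]
    xp <- xyz; xp[i, c] <- xp[i, c] + h
    xm <- xyz; xm[i, c] <- xm[i, c] - h
    num <- -(potential_energy(topo, xp) - potential_energy(topo, xm)) / (2 * h)
    expect_equal(f[i, c], num, tolerance = 1e-4)
  }
})

test_that("potential energy is invariant under rigid rotation", {
  topo <- toy_sbm()
  rot <- rotation_z(1.1)
  e0 <- potential_energy(topo)
  xyz_rot <- topo$native_xyz %*% t(rot)
  xyz_rot <- sweep(xyz_rot, 2, c(5, -2, 7), `+`)
  expect_equal(potential_energy(topo, xyz_rot), e0, tolerance = 1e-9)
})

test_that("far-apart extended chains have near-zero nonbonded energy", {
  topo <- toy_sbm()
  n <- topo$n_beads
  line <- cbind(seq(0, by = 50, length.out = n), 0, 0)
  eb <- potential_energy(topo, line, breakdown = TRUE)
  expect_equal(unname(eb["contact"]), 0, tolerance = 1e-6)
  expect_equal(unname(eb["repulsion"]), 0, tolerance = 1e-12)
})

test_that("Q follows the 1.2x native-distance criterion", {
  topo <- toy_sbm()
  expect_equal(fraction_native(topo$native_xyz, topo), 1.0)

  # uniform expansion by 1.3: every contact broken
  centred <- scale(topo$native_xyz, scale = FALSE)
  expect_equal(fraction_native(centred * 1.3, topo), 0.0)

  # Q never increases under progressive expansion about the centroid
  qs <- vapply(seq(1, 1.4, by = 0.05),
               function(f) fraction_native(centred * f, topo), numeric(1))
  expect_true(all(diff(qs) <= 0))

  # constructed half-native geometry: scale native so that half the
  # contact distances stay inside 1.2x and half go beyond
  flags <- fraction_native(topo$native_xyz, topo, flags = TRUE)
  expect_length(flags$formed, nrow(topo$contacts))
})

test_that("dynamics are bitwise reproducible and blow-up free", {
  topo <- toy_sbm()
  p <- sbm_params(temperature = 1.0, n_steps = 5e4, save_every = 100,
                  seed = 99)
  tr1 <- run_dynamics(topo, p)
  tr2 <- run_dynamics(topo, p)
  expect_identical(tr1$q_series, tr2$q_series)
  expect_identical(tr1$e_series, tr2$e_series)
  p2 <- sbm_params(temperature = 1.0, n_steps = 5e4, save_every = 100,
                   seed = 100)
  expect_false(identical(run_dynamics(topo, p2)$q_series, tr1$q_series))
})

test_that("a free bead diffuses with linearly growing displacement", {
  # two force-free beads (zeroed coupling constants): pure Langevin
  # diffusion; the distant contact keeps Q defined but exerts no force
  free2 <- structure(list(
    n_beads = 2L, native_xyz = rbind(c(0, 0, 0), c(100, 0, 0)),
    bonds = matrix(integer(), ncol = 2), bond_r0 = numeric(0),
    angles = matrix(integer(), ncol = 3), angle_t0 = numeric(0),
    dihedrals = matrix(integer(), ncol = 4), dihedral_p0 = numeric(0),
    contacts = matrix(c(0L, 1L), ncol = 2), contact_r0 = 100,
    rep_pairs = matrix(integer(), ncol = 2),
    k_bond = 0, k_angle = 0, k_dihedral = 0, energy_scale = 0,
    excluded_radius = 1, min_sep = 4L), class = "sbm_topology")
  p <- sbm_params(temperature = 1.0, n_steps = 2e5, save_every = 50,
                  seed = 17, friction = 1.0)
  msds <- numeric(0)
  for (seed in 17:26) {
    p$seed <- seed
    tr <- run_dynamics(free2, p)
    msds <- c(msds, sum((tr$final_xyz[1, ] - free2$native_xyz[1, ])^2))
  }
  # expected MSD for overdamped-with-inertia Langevin: ~ 6 D t with
  # D = T / gamma; t = n_steps * dt = 100; allow broad sampling band
  expect_gt(mean(msds), 0.3 * 6 * 100)
  expect_lt(mean(msds), 3.0 * 6 * 100)
})

test_that("the native basin is stable well below the folding temperature", {
  topo <- toy_sbm()
  p <- sbm_params(temperature = 0.6, n_steps = 5e5, save_every = 500,
                  seed = 23)
  tr <- run_dynamics(topo, p)
  expect_gt(mean(tr$q_series), 0.9)
})

test_that("kinetic energy equipartitions at the thermostat temperature", {
  topo <- toy_sbm()
  p <- sbm_params(temperature = 1.1, n_steps = 4e5, save_every = 200,
                  seed = 31)
  tr <- run_dynamics(topo, p)
  dof <- 3 * topo$n_beads
  t_eff <- mean(tr$ke_series[-(1:100)]) * 2 / dof
  expect_equal(t_eff, 1.1, tolerance = 0.05)
})

test_that("high-temperature runs generate unfolded configurations", {
  topo <- toy_sbm()
  unf <- generate_unfolded(topo, high_temperature = 2.8, seed = 41)
  expect_lt(fraction_native(unf, topo), 0.2)
  # deterministic given the seed
  unf2 <- generate_unfolded(topo, high_temperature = 2.8, seed = 41)
  expect_identical(unf, unf2)
  # an already-unfolded start returns promptly
  expect_identical(generate_unfolded(
    structure(modifyList(unclass(topo), list(native_xyz = unf)),
              class = "sbm_topology"), 2.8, seed = 1), unf)
})

test_that("topologies round-trip through JSON and export pair lists", {
  topo <- toy_sbm(seed = 6)
  pj <- withr::local_tempfile(fileext = ".json")
  write_sbm_json(topo, pj)
  back <- read_sbm_json(pj)
  expect_equal(back$contacts, topo$contacts)
  expect_equal(back$contact_r0, topo$contact_r0)
  expect_equal(back$dihedral_p0, topo$dihedral_p0)
  expect_equal(back$rep_pairs, topo$rep_pairs)
  expect_equal(potential_energy(back), potential_energy(topo))

  pp <- withr::local_tempfile(fileext = ".txt")
  write_sbm_pairs(topo, pp)
  tab <- utils::read.table(pp)
  expect_equal(nrow(tab), nrow(topo$contacts))
  expect_equal(tab[[1]], topo$contacts[, 1] + 1L)
})

test_that("trajectories round-trip through TSV with contact bitmasks", {
  topo <- toy_sbm()
  p <- sbm_params(temperature = 1.2, n_steps = 2e4, save_every = 200,
                  seed = 3, record_flags = TRUE)
  tr <- run_dynamics(topo, p)
  pt <- withr::local_tempfile(fileext = ".tsv")
  pf <- withr::local_tempfile(fileext = ".bits")
  write_trajectory_tsv(tr, pt, flags_path = pf)
  back <- read_trajectory_tsv(pt, flags_path = pf)
  expect_equal(back$q_series, tr$q_series, tolerance = 1e-9)
  expect_equal(back$e_series, tr$e_series, tolerance = 1e-8)
  expect_equal(back$temperature, tr$temperature)
  expect_identical(back$contact_formed[5, ],
                   unname(tr$contact_formed[5, ]))
})
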
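#' Build a C-alpha structure-based (Go-type) model topology
#'
#' One bead per residue at the native CA position. Bonded terms (bonds,
#' angles, dihedrals) take their native values; each residue pair in the
#' contact map becomes an attractive 10-12 Lennard-Jones native contact of
#' depth `energy_scale` at its native CA distance; every other bead pair
#' with sequence separation >= `min_sep` feels an r^-12 excluded-volume
#' repulsion of radius `excluded_radius`. Separations 1-3 are governed by
#' the bonded terms only. Reduced units: energies in epsilon, kB = 1.
#'
#' Dihedrals whose native geometry is degenerate (three collinear beads)
#' have no defined native angle and are dropped with a warning.
#'
#' @param s A `protein_structure` with one CA per residue.
#' @param m A `residue_contact_map` built on the same structure.
#' @param min_sep Minimum sequence separation for nonbonded pairs
#'   (contacts and repulsion). Default 4.
#' @param energy_scale Contact well depth epsilon (reduced). Default 1.
#' @param excluded_radius Excluded-volume radius, Angstrom. Default 4.
#' @param k_bond,k_angle,k_dihedral Bonded force constants in epsilon units
#'   (per Angstrom^2 / radian^2). Defaults 100, 20, 1.
#' @return Object of class `sbm_topology`.
#' @export
build_sbm <- function(s, m, min_sep = 4L, energy_scale = 1.0,
                      excluded_radius = 4.0, k_bond = 100, k_angle = 20,
                      k_dihedral = 1) {
  stopifnot(inherits(s, "protein_structure"),
            inherits(m, "residue_contact_map"))
  if (m$L != s$length) stop("map and structure chain lengths differ")
  xyz <- ca_coords(s)
  n <- nrow(xyz)

  bonds <- cbind(0:(n - 2L), 1:(n - 1L))
  bond_r0 <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                             xyz[-n, , drop = FALSE])^2))
  if (any(bond_r0 <= 0)) stop("coincident consecutive CA positions")

  angle_of <- function(i, j, k) {
    u <- xyz[i, ] - xyz[j, ]
    v <- xyz[k, ] - xyz[j, ]
    ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(pmin(1, pmax(-1, ct)))
  }
  if (n >= 3L) {
    angles <- cbind(0:(n - 3L), 1:(n - 2L), 2:(n - 1L))
    angle_t0 <- vapply(seq_len(n - 2L),
                       function(i) angle_of(i, i + 1L, i + 2L), numeric(1))
  } else {
    angles <- matrix(integer(), ncol = 3L)
    angle_t0 <- numeric(0)
  }

  dihedral_of <- function(i) {
    b1 <- xyz[i + 1L, ] - xyz[i, ]
    b2 <- xyz[i + 2L, ] - xyz[i + 1L, ]
    b3 <- xyz[i + 3L, ] - xyz[i + 2L, ]
    n1 <- crossprod3(b1, b2)
    n2 <- crossprod3(b2, b3)
    if (sum(n1^2) < 1e-10 || sum(n2^2) < 1e-10) return(NA_real_)
    atan2(sum(crossprod3(n1, n2) * b2), sum(n1 * n2) * sqrt(sum(b2^2)))
  }
  if (n >= 4L) {
    dihedrals <- cbind(0:(n - 4L), 1:(n - 3L), 2:(n - 2L), 3:(n - 1L))
    dihedral_p0 <- vapply(seq_len(n - 3L), dihedral_of, numeric(1))
    bad <- is.na(dihedral_p0)
    if (any(bad)) {
      warning(sum(bad), " dihedral(s) with collinear native geometry dropped")
      dihedrals <- dihedrals[!bad, , drop = FALSE]
      dihedral_p0 <- dihedral_p0[!bad]
    }
  } else {
    dihedrals <- matrix(integer(), ncol = 4L)
    dihedral_p0 <- numeric(0)
  }

  cp <- m$pairs
  keep <- (cp$j - cp$i) >= min_sep
  cp <- cp[keep, , drop = FALSE]
  contact_r0 <- sqrt(rowSums((xyz[cp$j + 1L, , drop = FALSE] -
                                xyz[cp$i + 1L, , drop = FALSE])^2))
  stopifnot(all(contact_r0 > 0))

  # nonbonded repulsion: all sep >= min_sep pairs not in the contact set
  pair_i <- rep(0:(n - 2L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(0:(n - 2L), function(i) (i + 1L):(n - 1L)))
  sel <- (pair_j - pair_i) >= min_sep
  pair_i <- pair_i[sel]; pair_j <- pair_j[sel]
  ckey <- cp$i * n + cp$j
  rep_sel <- !((pair_i * n + pair_j) %in% ckey)

  structure(
    list(
      n_beads = n,
      native_xyz = xyz,
      bonds = bonds, bond_r0 = bond_r0,
      angles = angles, angle_t0 = angle_t0,
      dihedrals = dihedrals, dihedral_p0 = dihedral_p0,
      contacts = unname(as.matrix(cp)), contact_r0 = contact_r0,
      rep_pairs = cbind(pair_i[rep_sel], pair_j[rep_sel]),
      k_bond = k_bond, k_angle = k_angle, k_dihedral = k_dihedral,
      energy_scale = energy_scale, excluded_radius = excluded_radius,
      min_sep = as.integer(min_sep)
    ),
    class = "sbm_topology"
  )
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.sbm_topology <- function(x, ...) {
  cat(sprintf(
    "sbm_topology: %d beads, %d bonds, %d angles, %d dihedrals, %d contacts\n",
    x$n_beads, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
    nrow(x$contacts)))
  invisible(x)
}

#' Potential energy of a configuration
#'
#' @param t An `sbm_topology`.
#' @param xyz n_beads x 3 coordinate matrix (Angstrom). Default: native.
#' @param breakdown If TRUE return the named component vector (bond, angle,
#'   dihedral, contact, repulsion, total) instead of the total.
#' @return Energy in epsilon units.
#' @export
potential_energy <- function(t, xyz = t$native_xyz, breakdown = FALSE) {
  stopifnot(inherits(t, "sbm_topology"))
  e <- sbm_energy_cpp(as.matrix(xyz), unclass(t))
  if (breakdown) e else unname(e["total"])
}

#' Net forces on each bead
#'
#' @inheritParams potential_energy
#' @return n_beads x 3 matrix of forces (epsilon / Angstrom).
#' @export
net_forces <- function(t, xyz = t$native_xyz) {
  stopifnot(inherits(t, "sbm_topology"))
  sbm_forces_cpp(as.matrix(xyz), unclass(t))
}

#' Fraction of native contacts Q
#'
#' A native contact counts as formed when the inter-bead distance is less
#' than 1.2 times its native distance.
#'
#' @param xyz Coordinate matrix.
#' @param t An `sbm_topology` with at least one contact.
#' @param flags If TRUE also return the per-contact formation vector.
#' @return Q in [0, 1], or a list `(q, formed)` when `flags = TRUE`.
#' @export
fraction_native <- function(xyz, t, flags = FALSE) {
  stopifnot(inherits(t, "sbm_topology"))
  out <- sbm_q_cpp(as.matrix(xyz), unclass(t))
  if (flags) out else out$q
}

#' Simulation parameters
#'
#' @param temperature Reduced temperature (kB = 1, epsilon = 1). Simulation
#'   temperatures are model-internal and do not map to Kelvin.
#' @param n_steps Number of integration steps. The default preset is
#'   fixture-scale (1e7); `preset = "production"` selects the cluster-scale
#'   2e10-step protocol used for full-size proteins.
#' @param timestep Integration timestep, reduced time. Default 0.0005.
#' @param friction Langevin friction coefficient, reduced. Default 1.
#' @param save_every Save a frame every this many steps. Default 1000.
#' @param seed Integer seed governing initial velocities and thermostat
#'   noise.
#' @param record_flags Record per-contact formation flags each frame.
#' @param preset `"fixture"` (default) or `"production"`.
#' @return Object of class `sim_params`.
#' @export
sbm_params <- function(temperature, n_steps = NULL, timestep = 5e-4,
                       friction = 1.0, save_every = 1000L, seed = 1L,
                       record_flags = FALSE,
                       preset = c("fixture", "production")) {
  preset <- match.arg(preset)
  if (is.null(n_steps)) {
    n_steps <- if (preset == "production") 2e10 else 1e7
  }
  stopifnot(timestep > 0, n_steps >= 1, save_every >= 1)
  structure(
    list(temperature = temperature, n_steps = n_steps, timestep = timestep,
         friction = friction, save_every = as.integer(save_every),
         seed = as.integer(seed), record_flags = isTRUE(record_flags)),
    class = "sim_params"
  )
}

#' Run Langevin dynamics on an SBM topology
#'
#' BAOAB-split Langevin integration in the NVT ensemble. One seed governs
#' both the Maxwell-distributed initial velocities and the thermostat noise
#' stream, so identical parameters reproduce the trajectory bitwise.
#'
#' @param t An `sbm_topology`.
#' @param p A `sim_params`.
#' @param start_xyz Starting coordinates; default native.
#' @return Object of class `sbm_trajectory`: list with `q_series`,
#'   `e_series` (potential, epsilon), `ke_series`, optional
#'   `contact_formed` (frames x contacts logical matrix), `temperature`,
#'   `seed`, `save_every`, `timestep`, `final_xyz`, `n_contacts`.
#' @export
run_dynamics <- function(t, p, start_xyz = t$native_xyz) {
  stopifnot(inherits(t, "sbm_topology"), inherits(p, "sim_params"))
  raw <- run_dynamics_cpp(unclass(t), as.matrix(start_xyz),
                          p$n_steps, p$timestep, p$friction, p$temperature,
                          p$save_every, p$seed, p$record_flags)
  structure(
    list(q_series = raw$q_series, e_series = raw$e_series,
         ke_series = raw$ke_series,
         contact_formed = raw$contact_formed,
         temperature = p$temperature, seed = p$seed,
         save_every = p$save_every, timestep = p$timestep,
         final_xyz = raw$final_xyz, n_contacts = nrow(t$contacts)),
    class = "sbm_trajectory"
  )
}

#' @export
print.sbm_trajectory <- function(x, ...) {
  cat(sprintf(
    "sbm_trajectory: %d frames at T = %.3f (seed %d), mean Q = %.3f\n",
    length(x$q_series), x$temperature, x$seed, mean(x$q_series)))
  invisible(x)
}

#' Generate an unfolded configuration
#'
#' Runs short high-temperature dynamics from the native state until the
#' final frame has Q below `q_threshold`; retries with doubled run length
#' (new derived seed) up to `max_tries`.
#'
#' @param t An `sbm_topology`.
#' @param high_temperature Reduced temperature well above the folding
#'   temperature.
#' @param seed Integer seed; retries use seeds derived from it.
#' @param q_threshold Unfolded acceptance threshold on Q. Default 0.2.
#' @param n_steps Initial run length. Default 2e5.
#' @param max_tries Retry cap. Default 6.
#' @return Coordinate matrix of an unfolded configuration.
#' @export
generate_unfolded <- function(t, high_temperature, seed = 1L,
                              q_threshold = 0.2, n_steps = 2e5,
                              max_tries = 6L) {
  xyz <- t$native_xyz
  if (fraction_native(xyz, t) < q_threshold) return(xyz)
  for (try in seq_len(max_tries)) {
    p <- sbm_params(temperature = high_temperature, n_steps = n_steps,
                    save_every = max(1000L, as.integer(n_steps / 100)),
                    seed = seed + 7919L * (try - 1L))
    traj <- run_dynamics(t, p, xyz)
    if (utils::tail(traj$q_series, 1L) < q_threshold) {
      return(traj$final_xyz)
    }
    n_steps <- n_steps * 2
  }
  stop("failed to unfold below Q < ", q_threshold, " within ", max_tries,
       " attempts; raise high_temperature")
}

# two-state population statistics of a Q series with a hysteresis band:
# the chain is "folded" once Q rises above band[2] and "unfolded" once it
# drops below band[1]; in between it keeps its last state. This suppresses
# barrier-top recrossing noise and, unlike a sharp Q threshold, is robust
# to where exactly the basins sit.
q_series_stats <- function(q, band = c(0.35, 0.65)) {
  state <- NA_integer_
  transitions <- 0L
  states <- integer(length(q))
  for (i in seq_along(q)) {
    qi <- q[i]
    s <- if (qi >= band[2]) 1L else if (qi <= band[1]) 0L else NA_integer_
    if (!is.na(s)) {
      if (!is.na(state) && s != state) transitions <- transitions + 1L
      state <- s
    }
    states[i] <- state
  }
  assigned <- states[!is.na(states)]
  list(folded_fraction = if (length(assigned)) mean(assigned) else
         NA_real_,
       transitions = transitions)
}

#' Locate the folding temperature Tf
#'
#' Bisects on the folded population: at each candidate temperature, runs
#' are started from both the native and an unfolded geometry and pooled;
#' Tf is accepted when the folded fraction lies inside `pop_window` and at
#' least `min_transitions` folding/unfolding transitions were observed.
#' When populations balance but transitions are scarce the run length is
#' doubled before the bracket is declared exhausted.
#'
#' @param t An `sbm_topology`.
#' @param t_bracket Length-2 reduced-temperature bracket containing the
#'   transition.
#' @param n_steps Steps per probe run (per starting structure). Default 2e6.
#' @param save_every Frame stride. Default 500.
#' @param pop_window Acceptable folded-fraction window. Default c(0.4, 0.6).
#' @param min_transitions Minimum observed transitions. Default 3.
#' @param max_iter Bisection iteration cap. Default 20.
#' @param seed Integer seed.
#' @return List with `tf`, `folded_fraction`, `transitions`, `trajectory`
#'   (the pooled accepted `sbm_trajectory` pair, as a list).
#' @export
find_tf <- function(t, t_bracket, n_steps = 2e6, save_every = 500L,
                    pop_window = c(0.4, 0.6), min_transitions = 3L,
                    max_iter = 20L, seed = 1L) {
  stopifnot(length(t_bracket) == 2L, t_bracket[1] < t_bracket[2])
  unfolded <- generate_unfolded(t, high_temperature = 2 * t_bracket[2],
                                seed = seed)
  probe <- function(temp, steps, sd_off) {
    p1 <- sbm_params(temperature = temp, n_steps = steps,
                     save_every = save_every, seed = seed + sd_off)
    p2 <- sbm_params(temperature = temp, n_steps = steps,
                     save_every = save_every, seed = seed + sd_off + 1L)
    tr1 <- run_dynamics(t, p1, t$native_xyz)
    tr2 <- run_dynamics(t, p2, unfolded)
    q <- c(tr1$q_series, tr2$q_series)
    c(q_series_stats(q), list(trajectories = list(tr1, tr2)))
  }
  lo <- t_bracket[1]
  hi <- t_bracket[2]
  s_lo <- probe(lo, n_steps, 100L)
  if (s_lo$folded_fraction < pop_window[1]) {
    stop("lower bracket temperature is not predominantly folded")
  }
  s_hi <- probe(hi, n_steps, 200L)
  if (s_hi$folded_fraction > pop_window[2]) {
    stop("upper bracket temperature is not predominantly unfolded")
  }
  steps <- n_steps
  for (iter in seq_len(max_iter)) {
    mid <- 0.5 * (lo + hi)
    s <- probe(mid, steps, 300L + 10L * iter)
    ff <- s$folded_fraction
    if (ff >= pop_window[1] && ff <= pop_window[2]) {
      if (s$transitions >= min_transitions) {
        return(list(tf = mid, folded_fraction = ff,
                    transitions = s$transitions,
                    trajectories = s$trajectories))
      }
      steps <- steps * 2 # balanced but under-sampled: run longer
    } else if (ff > pop_window[2]) {
      lo <- mid
    } else {
      hi <- mid
    }
    if (hi - lo < 1e-4 && steps > 16 * n_steps) break
  }
  stop("bracket exhausted without locating Tf (", max_iter, " iterations)")
}
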
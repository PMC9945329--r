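# Deterministic generators of toy structures, homolog pairs, and synthetic
# experimental data. Every generator is a pure function of its arguments
# (seed included): the global RNG state is saved and restored.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a compact toy bead fold
#'
#' Places `n_residues` single-bead (CA-only) residues along a serpentine
#' path through a cubic lattice (spacing 4.2 Angstrom), with a small seeded
#' jitter to break the collinear degeneracies of a perfect lattice. The
#' jitter is redrawn (deterministically) until no two beads are closer than
#' `min_dist`. The resulting fold is compact: lattice diagonals fall inside
#' a 6 Angstrom contact cutoff, giving many contacts including several with
#' sequence separation >= 12.
#'
#' @param n_residues Number of beads (>= 8, <= 64). Default 20.
#' @param seed Integer seed.
#' @param spacing Lattice spacing, Angstrom. Default 4.2.
#' @param jitter Jitter standard deviation, Angstrom. Default 0.15.
#' @param min_dist Guaranteed minimum inter-bead distance. Default 3.8.
#' @return A `protein_structure` of CA beads with a seeded random sequence.
#' @export
toy_fold <- function(n_residues = 20L, seed = 1L, spacing = 4.2,
                     jitter = 0.15, min_dist = 3.8) {
  n <- as.integer(n_residues)
  stopifnot(n >= 8L, n <= 64L)
  m <- ceiling(n^(1 / 3))
  # serpentine path through an m^3 lattice: x fastest, direction
  # alternating with y, y direction alternating with z
  path <- matrix(0L, nrow = m^3, ncol = 3L)
  r <- 1L
  for (z in 0:(m - 1L)) {
    ys <- if (z %% 2L == 0L) 0:(m - 1L) else (m - 1L):0
    for (y in ys) {
      xs <- if ((y + z) %% 2L == 0L) 0:(m - 1L) else (m - 1L):0
      for (x in xs) {
        path[r, ] <- c(x, y, z)
        r <- r + 1L
      }
    }
  }
  base <- path[seq_len(n), , drop = FALSE] * spacing
  with_seed(seed, {
    for (try in 1:100) {
      xyz <- base + matrix(stats::rnorm(3L * n, sd = jitter), ncol = 3L)
      if (min(stats::dist(xyz)) >= min_dist) break
      if (try == 100) stop("could not satisfy the self-avoidance bound")
    }
    aa <- sample(c("A", "V", "L", "I", "F", "G", "S", "T", "Y", "W"), n,
                 replace = TRUE)
    atoms <- data.frame(
      serial = seq_len(n), name = "CA", element = "C",
      residue_pos = 0:(n - 1L), author_resnum = seq_len(n), chain = "A",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE
    )
    residues <- data.frame(
      residue_pos = 0:(n - 1L), author_resnum = seq_len(n), chain = "A",
      aa = aa, stringsAsFactors = FALSE
    )
    s <- new_structure(atoms, residues,
                       source_id = sprintf("toy_fold(n=%d, seed=%d)", n, seed))
    attr(s, "excluded_radius") <- min_dist
    s
  })
}

#' Generate a homolog pair with a controlled long-range contact surplus
#'
#' Both homologs share the toy-fold geometry (identity alignment); the
#' donor's contact map is the parent's plus `n_extra` additional long-range
#' pairs whose endpoints all lie in a designated "core" subset, drawn from
#' real inter-bead distances in the 6-9.5 Angstrom shell so the native
#' structure remains the energy minimum of both SBM topologies. This
#' emulates a homolog whose core packs more long-range contacts.
#'
#' @param seed Integer seed.
#' @param n_residues Beads per homolog. Default 20.
#' @param n_extra Number of extra long-range core pairs in the donor.
#'   Default 4.
#' @param min_sep Sequence-separation floor of the maps (SBM convention).
#'   Default 4.
#' @param cutoff Contact cutoff of the maps, Angstrom. Default 6. The
#'   donor's extra pairs are drawn from the (cutoff, cutoff + 2.5] shell.
#' @return List with `parent`, `donor` (`protein_structure`), `aln`
#'   (identity `position_alignment`), `map_parent`, `map_donor`, `core`
#'   (0-based indices), `extra_pairs`, `n_extra`.
#' @export
homolog_pair <- function(seed = 1L, n_residues = 20L, n_extra = 4L,
                         min_sep = 4L, cutoff = 6.0) {
  parent <- toy_fold(n_residues, seed = seed)
  donor <- toy_fold(n_residues, seed = seed)
  donor$source_id <- sprintf("homolog_donor(n=%d, seed=%d)", n_residues, seed)
  with_seed(seed + 1L, {
    donor$residues$aa <- sample(c("A", "V", "L", "I", "F", "G", "S", "T",
                                  "Y", "W"), n_residues, replace = TRUE)
  })
  ac <- atom_contacts(parent, cutoff = cutoff, min_sep = min_sep)
  map_parent <- cutoff_residue_map(ac, parent$length)

  xyz <- ca_coords(parent)
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(xyz)
  cand <- which(upper.tri(d) & d > cutoff & d <= cutoff + 2.5,
                arr.ind = TRUE)
  cand_i <- cand[, 1] - 1L
  cand_j <- cand[, 2] - 1L
  lr <- (cand_j - cand_i) >= 12L
  cand_i <- cand_i[lr]; cand_j <- cand_j[lr]
  if (length(cand_i) < n_extra) {
    stop("not enough long-range candidates for n_extra = ", n_extra)
  }
  ord <- order(d[cbind(cand_i + 1L, cand_j + 1L)])
  pick <- ord[seq_len(n_extra)]
  extra <- cbind(cand_i[pick], cand_j[pick])

  map_donor <- new_contact_map(rbind(as.matrix(map_parent$pairs), extra),
                               n, kind = "cutoff")
  core <- sort(unique(c(extra[, 1], extra[, 2])))
  list(parent = parent, donor = donor,
       aln = identity_alignment(n),
       map_parent = map_parent, map_donor = map_donor,
       core = core, extra_pairs = extra, n_extra = as.integer(n_extra))
}

#' Synthetic single-exponential kinetic trace
#'
#' y(t) = A exp(-k t) + Y0 + drift * t with optional additive Gaussian
#' noise.
#'
#' @param k Rate constant, s^-1.
#' @param A Amplitude. Default 1.
#' @param Y0 Offset. Default 0.
#' @param drift Linear drift per second. Default 0.
#' @param noise_sigma Additive noise SD. Default 0.
#' @param n_points Number of points. Default 200.
#' @param seed Integer seed.
#' @param t_max Trace length, s. Default 7 / k.
#' @return data.frame with columns `t`, `y`; attribute `truth` holds the
#'   generating parameters.
#' @export
synthetic_trace <- function(k, A = 1, Y0 = 0, drift = 0, noise_sigma = 0,
                            n_points = 200L, seed = 1L, t_max = 7 / k) {
  stopifnot(k > 0, n_points >= 5L)
  t <- seq(0, t_max, length.out = n_points)
  y <- A * exp(-k * t) + Y0 + drift * t
  if (noise_sigma > 0) {
    y <- y + with_seed(seed, stats::rnorm(n_points, sd = noise_sigma))
  }
  out <- data.frame(t = t, y = y)
  attr(out, "truth") <- list(k = k, A = A, Y0 = Y0, drift = drift,
                             noise_sigma = noise_sigma, seed = seed)
  out
}

#' Synthetic chevron dataset
#'
#' Observed rates k_obs(x) = kf exp(mf x / RT) + ku exp(mu x / RT) on a
#' concentration grid, with optional multiplicative Gaussian noise.
#' Defaults to the kinetic parameters of wild-type hisactophilin in GuHCl
#' (kf = 26.0 s^-1, ku = 4.0e-4 s^-1, mf = -5.46, mu = 1.29 kcal/mol/M).
#'
#' @param truth A `chevron_fit` (see [chevron_parameters()]).
#' @param conc Concentration grid, M. Default 20 points on [0, 2].
#' @param rel_noise Multiplicative noise SD (e.g. 0.05 for 5%). Default 0.
#' @param seed Integer seed.
#' @return data.frame with columns `conc`, `k_obs`; attribute `truth`.
#' @export
synthetic_chevron <- function(truth = chevron_parameters(26.0, 4.0e-4,
                                                         -5.46, 1.29),
                              conc = seq(0, 2, length.out = 20L),
                              rel_noise = 0, seed = 1L) {
  stopifnot(inherits(truth, "chevron_fit"))
  RT <- truth$R * truth$T
  k <- truth$kf_h2o * exp(truth$mf * conc / RT) +
    truth$ku_h2o * exp(truth$mu * conc / RT)
  if (rel_noise > 0) {
    k <- k * (1 + with_seed(seed, stats::rnorm(length(k), sd = rel_noise)))
    k <- pmax(k, .Machine$double.xmin)
  }
  out <- data.frame(conc = conc, k_obs = k)
  attr(out, "truth") <- truth
  out
}

#' Synthetic two-state Q/energy series
#'
#' Draws Q from a specified double-well density (mixture of two truncated
#' Gaussian basins on [0, 1] whose common width is set from the requested
#' barrier height) and couples the potential energy linearly to Q:
#' E = e_intercept + e_slope * Q + Gaussian noise. The exact generating
#' probability mass per histogram bin, and the barrier implied by it, are
#' returned so recovery can be checked against the construction rather
#' than against an approximation.
#'
#' @param basin_centers Q positions of the unfolded and folded basins.
#'   Default c(0.2, 0.9).
#' @param basin_weights Basin populations (sum 1). Default c(0.5, 0.5).
#' @param barrier_height Target barrier in kB*T for the equal-weight
#'   symmetric reference construction. Default 3.
#' @param n_frames Number of frames. Default 1e5.
#' @param seed Integer seed.
#' @param e_slope,e_intercept,e_noise Linear E(Q) coupling and noise SD.
#'   Defaults -30, 0, 1.
#' @param temperature Nominal reduced sampling temperature recorded on the
#'   trajectory. Default 1.
#' @param bins Binning used for the exact generating profile. Default 50.
#' @return An `sbm_trajectory` (without coordinates or contact flags) with
#'   extra fields `true_bin_mass`, `true_barrier`, `generator` (the spec).
#' @export
two_state_q_series <- function(basin_centers = c(0.2, 0.9),
                               basin_weights = c(0.5, 0.5),
                               barrier_height = 3, n_frames = 1e5,
                               seed = 1L, e_slope = -30, e_intercept = 0,
                               e_noise = 1, temperature = 1, bins = 50L) {
  stopifnot(length(basin_centers) == 2L, basin_centers[1] < basin_centers[2],
            all(basin_centers > 0 & basin_centers < 1),
            length(basin_weights) == 2L, all(basin_weights > 0),
            barrier_height > 0, n_frames >= 1)
  w <- basin_weights / sum(basin_weights)
  d <- basin_centers[2] - basin_centers[1]
  # width giving the requested midpoint barrier for the symmetric case
  s <- d / sqrt(8 * (barrier_height + log(2)))

  grid_n <- 20000L
  edges <- seq(0, 1, length.out = grid_n + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- w[1] * stats::dnorm(mid, basin_centers[1], s) +
    w[2] * stats::dnorm(mid, basin_centers[2], s)
  mass <- dens / sum(dens)

  # exact generating mass per output bin, and the barrier it implies
  bin_idx <- pmin(pmax(floor(mid * bins), 0), bins - 1L) + 1L
  true_bin_mass <- vapply(seq_len(bins), function(b) sum(mass[bin_idx == b]),
                          numeric(1))
  f_true <- -log(true_bin_mass)
  basins <- locate_basins(ifelse(true_bin_mass > 0, f_true, NA_real_))
  true_barrier <- f_true[basins$barrier] -
    min(f_true[basins$unfolded], f_true[basins$folded])

  cell <- 1 / grid_n
  with_seed(seed, {
    cells <- sample.int(grid_n, n_frames, replace = TRUE, prob = mass)
    q <- edges[cells] + stats::runif(n_frames) * cell
    e <- e_intercept + e_slope * q +
      if (e_noise > 0) stats::rnorm(n_frames, sd = e_noise) else 0
    structure(
      list(q_series = q, e_series = e, ke_series = NULL,
           contact_formed = NULL, temperature = temperature,
           seed = as.integer(seed), save_every = 1L, timestep = NA_real_,
           final_xyz = NULL, n_contacts = NA_integer_,
           true_bin_mass = true_bin_mass, true_barrier = true_barrier,
           generator = list(basin_centers = basin_centers,
                            basin_weights = w,
                            barrier_height = barrier_height,
                            e_slope = e_slope, e_intercept = e_intercept,
                            e_noise = e_noise, bins = bins, width = s)),
      class = "sbm_trajectory"
    )
  })
}
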
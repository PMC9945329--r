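#' Write an SBM topology to JSON
#'
#' Documented JSON dialect: indices are 1-based in the file, coordinates in
#' Angstrom, energies in epsilon units. Round-trips through
#' [read_sbm_json()].
#'
#' @param t An `sbm_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbm_json <- function(t, path) {
  stopifnot(inherits(t, "sbm_topology"))
  obj <- list(
    n_beads = t$n_beads,
    native_xyz = unname(as.matrix(t$native_xyz)),
    bonds = unname(t$bonds) + 1L, bond_r0 = t$bond_r0,
    angles = unname(t$angles) + 1L, angle_t0 = t$angle_t0,
    dihedrals = unname(t$dihedrals) + 1L, dihedral_p0 = t$dihedral_p0,
    contacts = unname(t$contacts) + 1L, contact_r0 = t$contact_r0,
    k_bond = t$k_bond, k_angle = t$k_angle, k_dihedral = t$k_dihedral,
    energy_scale = t$energy_scale, excluded_radius = t$excluded_radius,
    min_sep = t$min_sep
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an SBM topology written by [write_sbm_json()]
#'
#' The repulsive pair list is reconstructed from `min_sep` and the contact
#' set rather than stored.
#'
#' @param path Input path.
#' @return An `sbm_topology`.
#' @export
read_sbm_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nc) {
    if (length(x) == 0L) matrix(integer(), ncol = nc) else
      matrix(as.integer(x), ncol = nc)
  }
  n <- o$n_beads
  contacts <- as_mat(o$contacts, 2L) - 1L
  pair_i <- rep(0:(n - 2L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(0:(n - 2L), function(i) (i + 1L):(n - 1L)))
  sel <- (pair_j - pair_i) >= o$min_sep
  pair_i <- pair_i[sel]; pair_j <- pair_j[sel]
  ckey <- contacts[, 1] * n + contacts[, 2]
  rep_sel <- !((pair_i * n + pair_j) %in% ckey)
  structure(
    list(
      n_beads = n,
      native_xyz = matrix(o$native_xyz, ncol = 3L),
      bonds = as_mat(o$bonds, 2L) - 1L, bond_r0 = as.numeric(o$bond_r0),
      angles = as_mat(o$angles, 3L) - 1L, angle_t0 = as.numeric(o$angle_t0),
      dihedrals = as_mat(o$dihedrals, 4L) - 1L,
      dihedral_p0 = as.numeric(o$dihedral_p0),
      contacts = contacts, contact_r0 = as.numeric(o$contact_r0),
      rep_pairs = cbind(pair_i[rep_sel], pair_j[rep_sel]),
      k_bond = o$k_bond, k_angle = o$k_angle, k_dihedral = o$k_dihedral,
      energy_scale = o$energy_scale, excluded_radius = o$excluded_radius,
      min_sep = as.integer(o$min_sep)
    ),
    class = "sbm_topology"
  )
}

#' Export native contacts as a SMOG-style pair list
#'
#' Whitespace-delimited `i j r0` lines, 1-based indices, native distances
#' in Angstrom.
#'
#' @param t An `sbm_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbm_pairs <- function(t, path) {
  stopifnot(inherits(t, "sbm_topology"))
  writeLines(sprintf("%d %d %.6f", t$contacts[, 1] + 1L,
                     t$contacts[, 2] + 1L, t$contact_r0), path)
  invisible(path)
}

#' Write a trajectory as columnar TSV
#'
#' Columns `frame`, `q`, `e_pot`, `e_kin`; a `#`-prefixed header line
#' carries temperature, seed, timestep, stride, and contact count. When the
#' trajectory recorded per-contact flags, an optional sidecar file stores
#' one hex-encoded bitmask per frame (contact order as in the topology).
#'
#' @param traj An `sbm_trajectory`.
#' @param path Output TSV path.
#' @param flags_path Optional sidecar path for the per-contact bitmasks.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path, flags_path = NULL) {
  stopifnot(inherits(traj, "sbm_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# temperature=%.10g seed=%d timestep=%.10g save_every=%d n_contacts=%d",
    traj$temperature, traj$seed, traj$timestep, traj$save_every,
    traj$n_contacts), con)
  writeLines("frame\tq\te_pot\te_kin", con)
  n <- length(traj$q_series)
  writeLines(sprintf("%d\t%.10g\t%.10g\t%.10g", seq_len(n), traj$q_series,
                     traj$e_series, traj$ke_series), con)
  if (!is.null(flags_path) && !is.null(traj$contact_formed)) {
    writeLines(apply(traj$contact_formed, 1L, bitmask_hex), flags_path)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_tsv()]
#'
#' @param path TSV path.
#' @param flags_path Optional sidecar path with per-frame contact bitmasks.
#' @return An `sbm_trajectory`.
#' @export
read_trajectory_tsv <- function(path, flags_path = NULL) {
  hdr <- readLines(path, n = 1L)
  get <- function(key) {
    as.numeric(sub(paste0(".*", key, "=([-0-9.eE+]+).*"), "\\1", hdr))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  n_contacts <- as.integer(get("n_contacts"))
  flags <- NULL
  if (!is.null(flags_path)) {
    flags <- t(vapply(readLines(flags_path), hex_bitmask, logical(n_contacts),
                      n = n_contacts, USE.NAMES = FALSE))
  }
  structure(
    list(q_series = tab$q, e_series = tab$e_pot, ke_series = tab$e_kin,
         contact_formed = flags,
         temperature = get("temperature"), seed = as.integer(get("seed")),
         save_every = as.integer(get("save_every")),
         timestep = get("timestep"), final_xyz = NULL,
         n_contacts = n_contacts),
    class = "sbm_trajectory"
  )
}

bitmask_hex <- function(bits) {
  pad <- (-length(bits)) %% 4L
  b <- c(as.logical(bits), rep(FALSE, pad))
  nyb <- matrix(b, nrow = 4L)
  vals <- as.integer(8 * nyb[1, ] + 4 * nyb[2, ] + 2 * nyb[3, ] + nyb[4, ])
  paste(format.hexmode(vals), collapse = "")
}

hex_bitmask <- function(s, n) {
  vals <- strtoi(strsplit(s, "")[[1]], base = 16L)
  bits <- as.logical(rbind(bitwAnd(vals, 8L) > 0, bitwAnd(vals, 4L) > 0,
                           bitwAnd(vals, 2L) > 0, bitwAnd(vals, 1L) > 0))
  bits[seq_len(n)]
}
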
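# Brute-force oracles and hand-written fixtures shared across tests.

# minimal PDB text writer: one atom per line from a data.frame with
# name, element, resname, chain, resno, x, y, z
write_mini_pdb <- function(df, path, model = NULL) {
  fmt <- function(i) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, df$name[i], df$resname[i], df$chain[i], df$resno[i],
            df$x[i], df$y[i], df$z[i], df$element[i])
  }
  lines <- vapply(seq_len(nrow(df)), fmt, character(1))
  if (!is.null(model)) {
    lines <- c(sprintf("MODEL     %4d", model), lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# O(n^2) atom-contact oracle on a protein_structure
brute_atom_contacts <- function(s, cutoff = 6.0, min_sep = 2L) {
  a <- s$atoms
  n <- nrow(a)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (abs(a$residue_pos[i] - a$residue_pos[j]) < min_sep) next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d < cutoff) {
        out[[length(out) + 1L]] <- c(min(a$residue_pos[i], a$residue_pos[j]),
                                     max(a$residue_pos[i], a$residue_pos[j]),
                                     i, j)
      }
    }
  }
  if (!length(out)) return(matrix(numeric(), ncol = 4))
  do.call(rbind, out)
}

# set-of-pairs comparison helper (order-free)
pair_key <- function(p, L) sort(p[, 1] * L + p[, 2])

# translate a rigid motion onto a structure
transform_structure <- function(s, rot, shift) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# pooled two-start trajectory at one temperature (fixture-scale)
pooled_tf_traj <- function(topo, temperature, n_steps, seed, unfolded,
                           save_every = 500L, record_flags = FALSE) {
  p1 <- sbm_params(temperature = temperature, n_steps = n_steps,
                   save_every = save_every, seed = seed,
                   record_flags = record_flags)
  p2 <- sbm_params(temperature = temperature, n_steps = n_steps,
                   save_every = save_every, seed = seed + 1L,
                   record_flags = record_flags)
  tr1 <- run_dynamics(topo, p1)
  tr2 <- run_dynamics(topo, p2, unfolded)
  flags <- if (record_flags) rbind(tr1$contact_formed, tr2$contact_formed)
    else NULL
  structure(list(q_series = c(tr1$q_series, tr2$q_series),
                 e_series = c(tr1$e_series, tr2$e_series),
                 ke_series = c(tr1$ke_series, tr2$ke_series),
                 contact_formed = flags,
                 temperature = temperature, seed = seed,
                 save_every = save_every, timestep = p1$timestep,
                 final_xyz = tr2$final_xyz,
                 n_contacts = nrow(topo$contacts)),
            class = "sbm_trajectory")
}
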
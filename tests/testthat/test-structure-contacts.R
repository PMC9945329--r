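test_that("PDB reading filters hydrogens and resolves models", {
  df <- data.frame(
    name = c("N", "CA", "H", "CA", "CA"),
    element = c("N", "C", "H", "C", "C"),
    resname = c("GLY", "GLY", "GLY", "ALA", "VAL"),
    chain = "A",
    resno = c(10L, 10L, 10L, 11L, 12L),
    x = c(0, 1.5, 2.0, 4.5, 8.0), y = 0, z = 0
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(df, path)

  s <- read_structure(path)
  expect_s3_class(s, "protein_structure")
  expect_equal(s$length, 3L)
  expect_equal(nrow(s$atoms), 4L) # the H atom is gone
  expect_false(any(s$atoms$element == "H"))
  expect_equal(s$residues$residue_pos, 0:2)
  expect_equal(s$residues$author_resnum, 10:12) # author numbering preserved
  expect_equal(s$residues$aa, c("G", "A", "V"))

  expect_error(read_structure(path, model_index = 2), "model")
  expect_error(read_structure(tempfile()), "not found")
  expect_error(read_structure(path, chain_filter = "Z"), "after filtering")
})

test_that("toy fold round-trips through PDB", {
  s <- toy_fold(20, seed = 7)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(s, path)
  s2 <- read_structure(path)
  expect_equal(s2$length, 20L)
  expect_equal(nrow(s2$atoms), 20L)
  expect_equal(ca_coords(s2), ca_coords(s), tolerance = 1e-3)
})

test_that("atom contacts honor the strict cutoff and separation floor", {
  df <- data.frame(
    name = "CA", element = "C", resname = "ALA", chain = "A",
    resno = 1:3,
    x = c(0, 100, 5.0), y = 0, z = 0
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(df, path)
  s <- read_structure(path)

  ac <- atom_contacts(s, cutoff = 6, min_sep = 2)
  expect_equal(nrow(ac), 1L) # residues 0 and 2, 5.0 apart
  expect_equal(ac$res_i, 0L)
  expect_equal(ac$res_j, 2L)
  expect_equal(ac$sep, 2L)

  # exactly at the cutoff: excluded (strict "less than")
  df$x[3] <- 6.0
  write_mini_pdb(df, path)
  expect_equal(nrow(atom_contacts(read_structure(path), 6, 2)), 0L)
})

test_that("atom and residue maps match the brute-force oracle", {
  for (seed in c(1, 2)) {
    for (n in c(20, 40)) {
      s <- toy_fold(n, seed = seed)
      ac <- atom_contacts(s, cutoff = 6, min_sep = 2)
      oracle <- brute_atom_contacts(s, cutoff = 6, min_sep = 2L)
      expect_equal(nrow(ac), nrow(oracle))
      expect_equal(pair_key(cbind(ac$res_i, ac$res_j), s$length * 10),
                   pair_key(oracle[, 1:2, drop = FALSE], s$length * 10))
      m <- cutoff_residue_map(ac, s$length)
      key_oracle <- sort(unique(oracle[, 1] * s$length + oracle[, 2]))
      expect_equal(sort(m$pairs$i * s$length + m$pairs$j), key_oracle)
    }
  }
})

test_that("residue map deduplicates and validates", {
  ac <- data.frame(atom_a = 1:2, atom_b = 3:4, res_i = c(0L, 0L),
                   res_j = c(5L, 5L), sep = 5L, dist = c(4, 5))
  m <- cutoff_residue_map(ac, 10L)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(nrow(cutoff_residue_map(ac[0, ], 10L)$pairs), 0L)
  bad <- ac
  bad$res_j <- 12L
  expect_error(cutoff_residue_map(bad, 10L), "outside")
})

test_that("shadow occlusion removes blocked pairs and nothing else", {
  # A and B 5 apart with C exactly at the midpoint: screened
  df <- data.frame(
    name = "CA", element = "C", resname = "ALA", chain = "A",
    resno = 1:3,
    x = c(0, 2.5, 5.0), y = 0, z = 0
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(df, path)
  s <- read_structure(path)
  msh <- shadow_residue_map(s, cutoff = 6, shadow_radius = 1, min_sep = 2)
  expect_false(any(msh$pairs$i == 0 & msh$pairs$j == 2))

  # remove the blocker: retained (no third atom anywhere near)
  s2 <- read_structure(path)
  s2$atoms <- s2$atoms[-2, ]
  s2$atoms$residue_pos <- c(0L, 1L)
  s2$residues <- s2$residues[-2, ]
  s2$residues$residue_pos <- c(0L, 1L)
  s2$length <- 2L
  msh2 <- shadow_residue_map(s2, cutoff = 6, shadow_radius = 1, min_sep = 1)
  expect_true(any(msh2$pairs$i == 0 & msh2$pairs$j == 1))

  # degenerate radius: shadow map equals the cutoff map
  s3 <- toy_fold(25, seed = 4)
  m_cut <- cutoff_residue_map(atom_contacts(s3, 6, 2), s3$length)
  m_sh0 <- shadow_residue_map(s3, 6, shadow_radius = 0, min_sep = 2)
  expect_equal(m_sh0$pairs, m_cut$pairs)
})

test_that("shadow map is a subset of the cutoff map", {
  for (seed in 1:3) {
    s <- toy_fold(30, seed = seed)
    m_cut <- cutoff_residue_map(atom_contacts(s, 6, 2), s$length)
    m_sh <- shadow_residue_map(s, 6, shadow_radius = 1, min_sep = 2)
    k_cut <- m_cut$pairs$i * s$length + m_cut$pairs$j
    k_sh <- m_sh$pairs$i * s$length + m_sh$pairs$j
    expect_true(all(k_sh %in% k_cut))
  }
})

test_that("contact maps are rigid-motion and renumbering invariant", {
  s <- toy_fold(24, seed = 5)
  m0 <- cutoff_residue_map(atom_contacts(s, 6, 2), s$length)
  sh0 <- shadow_residue_map(s, 6, 1, 2)

  s_rot <- transform_structure(s, rotation_z(0.7), c(11, -3, 42))
  m1 <- cutoff_residue_map(atom_contacts(s_rot, 6, 2), s$length)
  sh1 <- shadow_residue_map(s_rot, 6, 1, 2)
  expect_equal(m1$pairs, m0$pairs)
  expect_equal(sh1$pairs, sh0$pairs)

  s_ren <- s
  s_ren$atoms$author_resnum <- s_ren$atoms$author_resnum + 100L
  s_ren$residues$author_resnum <- s_ren$residues$author_resnum + 100L
  m2 <- cutoff_residue_map(atom_contacts(s_ren, 6, 2), s$length)
  expect_equal(m2$pairs, m0$pairs)
})

test_that("difference maps partition pairs under an alignment", {
  m_a <- new_contact_map(rbind(c(0, 5), c(1, 8), c(2, 9)), 10L)
  aln <- identity_alignment(10L)

  d0 <- difference_map(m_a, m_a, aln)
  expect_equal(nrow(d0$only_a), 0L)
  expect_equal(nrow(d0$only_b), 0L)
  expect_equal(nrow(d0$shared), 3L)

  m_b <- new_contact_map(rbind(c(0, 5), c(1, 8), c(2, 9), c(3, 7)), 10L)
  d1 <- difference_map(m_a, m_b, aln)
  expect_equal(nrow(d1$only_b), 1L)
  expect_equal(unlist(d1$only_b), c(i = 3L, j = 7L))

  # shifted alignment: oracle by set algebra on translated pairs
  hp <- homolog_pair(seed = 2, n_extra = 4)
  d2 <- difference_map(hp$map_parent, hp$map_donor, hp$aln)
  expect_equal(nrow(d2$shared), nrow(hp$map_parent$pairs))
  expect_equal(nrow(d2$only_a), 0L)
  expect_equal(nrow(d2$only_b), hp$n_extra)
  L <- hp$map_donor$L
  expect_setequal(d2$only_b$i * L + d2$only_b$j,
                  hp$extra_pairs[, 1] * L + hp$extra_pairs[, 2])

  bad_aln <- position_alignment(c(0, 99), c(0, 1))
  expect_error(difference_map(m_a, m_b, bad_aln), "outside")
})

test_that("contact maps round-trip through both output dialects", {
  s <- toy_fold(20, seed = 9)
  m <- cutoff_residue_map(atom_contacts(s, 6, 2), s$length)
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_contact_map(m, p1, "pairs")
  write_contact_map(m, p2, "json")
  expect_equal(read_contact_map(p1)$pairs, m$pairs)
  expect_equal(read_contact_map(p2)$pairs, m$pairs)
  expect_equal(read_contact_map(p1)$L, m$L)
  # 1-based "i j" dialect
  first_pair <- scan(p1, what = integer(), skip = 1, n = 2, quiet = TRUE)
  expect_equal(first_pair, c(m$pairs$i[1] + 1L, m$pairs$j[1] + 1L))
})
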
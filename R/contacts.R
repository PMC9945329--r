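#' Atom-level contacts within a distance cutoff
#'
#' Enumerates every unordered pair of heavy atoms strictly closer than
#' `cutoff` whose residues are at least `min_sep` apart in sequence. The
#' default `min_sep = 2` keeps pairs with |i - j| > 1, the separation floor
#' used by the absolute contact order.
#'
#' @param s A `protein_structure`.
#' @param cutoff Distance cutoff in Angstrom (strict `<`). Default 6.
#' @param min_sep Minimum residue sequence separation |i - j|. Default 2.
#' @return data.frame of class `atom_contacts` with columns `atom_a`,
#'   `atom_b` (row indices into `s$atoms`), `res_i`, `res_j` (0-based,
#'   i <= j), `sep` (= j - i), `dist` (Angstrom).
#' @export
atom_contacts <- function(s, cutoff = 6.0, min_sep = 2L) {
  stopifnot(inherits(s, "protein_structure"), cutoff > 0)
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  res <- a$residue_pos

  # vectorized upper-triangle scan, one row of the distance matrix at a time
  out <- vector("list", 0L)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      keep <- abs(res[j] - res[i]) >= min_sep
      if (!any(keep)) next
      j <- j[keep]
      d2 <- (xyz[j, 1] - xyz[i, 1])^2 + (xyz[j, 2] - xyz[i, 2])^2 +
        (xyz[j, 3] - xyz[i, 3])^2
      hit <- d2 < cutoff^2
      if (!any(hit)) next
      j <- j[hit]
      out[[length(out) + 1L]] <- data.frame(
        atom_a = i, atom_b = j,
        res_i = pmin(res[i], res[j]), res_j = pmax(res[i], res[j]),
        dist = sqrt(d2[hit])
      )
    }
  }
  res_df <- if (length(out)) do.call(rbind, out) else
    data.frame(atom_a = integer(), atom_b = integer(), res_i = integer(),
               res_j = integer(), dist = numeric())
  res_df$sep <- res_df$res_j - res_df$res_i
  res_df <- res_df[, c("atom_a", "atom_b", "res_i", "res_j", "sep", "dist")]
  rownames(res_df) <- NULL
  class(res_df) <- c("atom_contacts", "data.frame")
  attr(res_df, "L") <- s$length
  attr(res_df, "cutoff") <- cutoff
  attr(res_df, "min_sep") <- as.integer(min_sep)
  res_df
}

#' Construct a residue contact map
#'
#' @param pairs Two-column matrix or data.frame of 0-based residue index
#'   pairs; stored with i < j, deduplicated.
#' @param L Chain length.
#' @param kind Label recording how the map was built (`"cutoff"`,
#'   `"shadow"`, or free text).
#' @return Object of class `residue_contact_map`: list with `L`, `pairs`
#'   (data.frame `i`, `j`), `kind`.
#' @export
new_contact_map <- function(pairs, L, kind = "cutoff") {
  L <- as.integer(L)
  stopifnot(L >= 1L)
  p <- as.data.frame(pairs)
  if (nrow(p) == 0L) {
    p <- data.frame(i = integer(), j = integer())
  } else {
    names(p)[1:2] <- c("i", "j")
    i <- as.integer(pmin(p$i, p$j))
    j <- as.integer(pmax(p$i, p$j))
    if (any(i == j)) stop("self-pairs are not allowed in a contact map")
    if (any(i < 0L) || any(j >= L)) {
      stop("contact indices outside [0, L)")
    }
    key <- i * L + j
    keep <- !duplicated(key)
    p <- data.frame(i = i[keep], j = j[keep])
    p <- p[order(p$i, p$j), , drop = FALSE]
    rownames(p) <- NULL
  }
  structure(list(L = L, pairs = p, kind = kind),
            class = "residue_contact_map")
}

#' @export
print.residue_contact_map <- function(x, ...) {
  cat("residue_contact_map (", x$kind, "): L = ", x$L, ", ",
      nrow(x$pairs), " pairs\n", sep = "")
  invisible(x)
}

#' Project atom contacts onto a residue contact map
#'
#' A residue pair is in contact iff at least one qualifying heavy-atom
#' contact exists between the two residues.
#'
#' @param contacts An `atom_contacts` table (from one structure).
#' @param L Chain length of that structure.
#' @return A `residue_contact_map` of kind `"cutoff"`.
#' @export
cutoff_residue_map <- function(contacts, L) {
  new_contact_map(contacts[, c("res_i", "res_j")], L, kind = "cutoff")
}

#' Shadow-occlusion residue contact map
#'
#' Builds the cutoff atom-contact list, then removes every atom pair whose
#' line of sight is blocked by a third heavy atom: atom k (not one of the
#' pair) occludes when the sphere of radius `shadow_radius` centred on k
#' intersects the open line segment between the two atom centres (the
#' perpendicular foot must fall strictly between the endpoints). Surviving
#' atom contacts are projected to residues. The result is always a subset
#' of the plain cutoff map.
#'
#' @param s A `protein_structure`.
#' @param cutoff Distance cutoff in Angstrom. Default 6.
#' @param shadow_radius Occluding-sphere radius in Angstrom. Default 1.
#' @param min_sep Minimum residue separation. Default 2.
#' @return A `residue_contact_map` of kind `"shadow"`.
#' @export
shadow_residue_map <- function(s, cutoff = 6.0, shadow_radius = 1.0,
                               min_sep = 2L) {
  stopifnot(cutoff > shadow_radius, shadow_radius >= 0)
  ac <- atom_contacts(s, cutoff = cutoff, min_sep = min_sep)
  if (nrow(ac) == 0L) return(new_contact_map(ac[, 3:4], s$length, "shadow"))
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  keep <- !vapply(seq_len(nrow(ac)), function(r) {
    occluded_pair(xyz, ac$atom_a[r], ac$atom_b[r], shadow_radius)
  }, logical(1))
  new_contact_map(ac[keep, c("res_i", "res_j")], s$length, kind = "shadow")
}

# TRUE when some third atom blocks the open segment a--b
occluded_pair <- function(xyz, a, b, radius) {
  if (radius <= 0) return(FALSE)
  pa <- xyz[a, ]
  pb <- xyz[b, ]
  ab <- pb - pa
  len2 <- sum(ab^2)
  rel <- sweep(xyz, 2L, pa)
  t <- (rel %*% ab) / len2
  # foot of perpendicular strictly interior to the segment
  cand <- which(t > 0 & t < 1)
  cand <- setdiff(cand, c(a, b))
  if (!length(cand)) return(FALSE)
  foot <- outer(t[cand, 1], ab)
  d2 <- rowSums((rel[cand, , drop = FALSE] - foot)^2)
  any(d2 < radius^2)
}

#' Difference between two contact maps under an alignment
#'
#' Translates pairs of map a onto map b through a position alignment and
#' partitions them into shared pairs and pairs unique to either protein.
#' Pairs touching unaligned positions cannot be compared and are reported
#' as unique to their own protein.
#'
#' @param map_a,map_b `residue_contact_map` objects.
#' @param aln A `position_alignment` mapping positions of a onto b.
#' @return List with data.frames `shared` (columns `i_a`, `j_a`, `i_b`,
#'   `j_b`), `only_a` (`i`, `j` in a's indexing) and `only_b` (in b's).
#' @export
difference_map <- function(map_a, map_b, aln) {
  stopifnot(inherits(map_a, "residue_contact_map"),
            inherits(map_b, "residue_contact_map"),
            inherits(aln, "position_alignment"))
  if (any(aln$pos_a >= map_a$L) || any(aln$pos_b >= map_b$L)) {
    stop("alignment references positions outside a map")
  }
  pa <- map_a$pairs
  pb <- map_b$pairs
  key_b <- pb$i * map_b$L + pb$j

  ia <- aln_forward(aln, pa$i)
  ja <- aln_forward(aln, pa$j)
  img_i <- pmin(ia, ja)
  img_j <- pmax(ia, ja)
  aligned <- !is.na(img_i) & !is.na(img_j)
  in_b <- aligned & (img_i * map_b$L + img_j) %in% key_b

  shared <- data.frame(i_a = pa$i[in_b], j_a = pa$j[in_b],
                       i_b = img_i[in_b], j_b = img_j[in_b])
  only_a <- pa[!in_b, , drop = FALSE]
  rownames(only_a) <- NULL

  # pairs of b not hit by any translated pair of a
  hit_key <- (img_i * map_b$L + img_j)[in_b]
  only_b <- pb[!(key_b %in% hit_key), , drop = FALSE]
  rownames(only_b) <- NULL

  list(shared = shared, only_a = only_a, only_b = only_b)
}

#' Write a contact map as a pair list or JSON
#'
#' Pair-list dialect: whitespace-delimited `i j` lines, 1-based indices,
#' with a `#` header carrying L and the map kind. JSON dialect: object with
#' fields `L`, `kind`, `pairs` (array of 1-based two-element arrays).
#'
#' @param m A `residue_contact_map`.
#' @param path Output path.
#' @param format `"pairs"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(m, path, format = c("pairs", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "residue_contact_map"))
  if (format == "pairs") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# L=%d kind=%s", m$L, m$kind), con)
    if (nrow(m$pairs)) {
      writeLines(sprintf("%d %d", m$pairs$i + 1L, m$pairs$j + 1L), con)
    }
  } else {
    jsonlite::write_json(
      list(L = m$L, kind = m$kind,
           pairs = unname(as.matrix(m$pairs)) + 1L),
      path, auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#'
#' @param path Input path.
#' @param format `"auto"`, `"pairs"`, or `"json"`.
#' @return A `residue_contact_map`.
#' @export
read_contact_map <- function(path, format = c("auto", "pairs", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), "{")) "json" else "pairs"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pairs <- if (length(obj$pairs)) matrix(obj$pairs, ncol = 2L) - 1L else
      matrix(integer(), ncol = 2L)
    return(new_contact_map(pairs, obj$L, kind = obj$kind))
  }
  lines <- readLines(path)
  hdr <- lines[1]
  L <- as.integer(sub(".*L=(\\d+).*", "\\1", hdr))
  kind <- sub(".*kind=(\\S+).*", "\\1", hdr)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body)) {
    mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer))
    new_contact_map(mat - 1L, L, kind = kind)
  } else {
    new_contact_map(matrix(integer(), ncol = 2L), L, kind = kind)
  }
}
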
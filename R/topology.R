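#' Absolute contact order (ACO)
#'
#' Mean sequence separation over heavy-atom contacts,
#' ACO = (1/Nc) * sum |i - j|, taken over atom pairs with |i - j| > 1 that
#' lie within the contact cutoff.
#'
#' @param contacts An `atom_contacts` table (non-empty).
#' @return Dimensionless ACO.
#' @export
compute_aco <- function(contacts) {
  if (nrow(contacts) == 0L) {
    stop("ACO is undefined for an empty contact list")
  }
  mean(contacts$sep)
}

#' Long-range order (LRO)
#'
#' Number of residue contact pairs with sequence separation >= `threshold`
#' (default 12), normalized by chain length L.
#'
#' @param m A `residue_contact_map`.
#' @param threshold Minimum separation counting as long-range. Default 12.
#' @return Dimensionless LRO.
#' @export
compute_lro <- function(m, threshold = 12L) {
  stopifnot(inherits(m, "residue_contact_map"), m$L >= 1L)
  long_range_count(m, threshold) / m$L
}

#' Count of long-range residue contacts
#'
#' @inheritParams compute_lro
#' @return Integer count of pairs with j - i >= threshold.
#' @export
long_range_count <- function(m, threshold = 12L) {
  stopifnot(inherits(m, "residue_contact_map"))
  sum(m$pairs$j - m$pairs$i >= threshold)
}

#' Per-residue long-range contact accounting
#'
#' Attributes long-range contacts to individual residues the way core-swap
#' comparisons tally them: a long-range pair with both endpoints inside
#' `subset` adds `shared_weight` (default 0.5) to each endpoint, so the pair
#' contributes 1.0 to the subset total; a pair with exactly one endpoint in
#' the subset adds 1.0 to that endpoint.
#'
#' @param m A `residue_contact_map`.
#' @param subset Integer vector of 0-based residue indices.
#' @param shared_weight Weight per endpoint when both endpoints are in the
#'   subset. Default 0.5.
#' @param threshold Long-range separation threshold. Default 12.
#' @return List with `per_residue` (named numeric over all L residues,
#'   0-based names) and `subset_total`.
#' @export
per_residue_long_range <- function(m, subset, shared_weight = 0.5,
                                   threshold = 12L) {
  stopifnot(inherits(m, "residue_contact_map"))
  subset <- as.integer(subset)
  if (any(subset < 0L) || any(subset >= m$L)) {
    stop("subset indices outside [0, L)")
  }
  totals <- stats::setNames(numeric(m$L), as.character(0:(m$L - 1L)))
  lr <- m$pairs[m$pairs$j - m$pairs$i >= threshold, , drop = FALSE]
  in_sub_i <- lr$i %in% subset
  in_sub_j <- lr$j %in% subset
  both <- in_sub_i & in_sub_j
  one_i <- in_sub_i & !in_sub_j
  one_j <- in_sub_j & !in_sub_i
  add <- function(idx, w) {
    if (length(idx)) {
      t2 <- tapply(w, idx, sum)
      totals[names(t2)] <<- totals[names(t2)] + as.numeric(t2)
    }
  }
  add(c(lr$i[both], lr$j[both]), rep(shared_weight, 2L * sum(both)))
  add(lr$i[one_i], rep(1, sum(one_i)))
  add(lr$j[one_j], rep(1, sum(one_j)))
  list(per_residue = totals,
       subset_total = sum(totals[as.character(subset)]))
}

#' Topology report for a structure
#'
#' Convenience wrapper computing ACO (from atom contacts, |i - j| > 1) and
#' LRO (from a residue map) in one call, recording which map kind produced
#' the LRO.
#'
#' @param s A `protein_structure`.
#' @param map_kind `"cutoff"` or `"shadow"` residue map for LRO.
#' @param cutoff Contact cutoff, Angstrom. Default 6.
#' @param shadow_radius Occlusion radius for shadow maps. Default 1.
#' @param lro_threshold Long-range separation threshold. Default 12.
#' @return Object of class `topology_report`: list with `lro`, `aco`,
#'   `n_long_range`, `L`, `map_kind`.
#' @export
topology_report <- function(s, map_kind = c("cutoff", "shadow"),
                            cutoff = 6.0, shadow_radius = 1.0,
                            lro_threshold = 12L) {
  map_kind <- match.arg(map_kind)
  ac <- atom_contacts(s, cutoff = cutoff, min_sep = 2L)
  m <- if (map_kind == "cutoff") {
    cutoff_residue_map(ac, s$length)
  } else {
    shadow_residue_map(s, cutoff = cutoff, shadow_radius = shadow_radius,
                       min_sep = 2L)
  }
  structure(
    list(lro = compute_lro(m, lro_threshold),
         aco = compute_aco(ac),
         n_long_range = long_range_count(m, lro_threshold),
         L = s$length,
         map_kind = map_kind),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("topology_report (L = %d, %s map): LRO = %.3f, ACO = %.3f, %d long-range contacts\n",
              x$L, x$map_kind, x$lro, x$aco, x$n_long_range))
  invisible(x)
}

#' Write a topology report as TSV or JSON
#' @param x A `topology_report`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_topology_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rec <- list(lro = x$lro, aco = x$aco, n_long_range = x$n_long_range,
              L = x$L, map_kind = x$map_kind)
  if (format == "json") {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(rec), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
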
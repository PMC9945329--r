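#' Free-energy profile F(Q) from a Q series
#'
#' Bins Q into a histogram P(Q) and returns F = -ln P per occupied bin
#' (kB*T units at the sampling temperature). The unfolded and folded basins
#' are the two deepest local minima separated by the global interior
#' maximum between them; ties break toward extremal Q.
#'
#' @param q_series Numeric vector of Q values in [0, 1], or an
#'   `sbm_trajectory`.
#' @param bins Number of equal-width bins on [0, 1] (default 50, >= 2), or
#'   `"levels"` to place one bin per discrete Q level of a simulation
#'   trajectory (Q = k / n_contacts). Level binning avoids the aliasing a
#'   fixed bin width produces when the number of native contacts is not a
#'   multiple of the bin count; it requires an `sbm_trajectory` input (or
#'   `n_contacts` passed explicitly).
#' @param weights Optional per-frame weights (used by the reweighting).
#' @param require_two_state Error when no two-basin signature is found.
#'   Default TRUE.
#' @param min_count Minimum number of frames a bin needs before it can be
#'   considered in basin/barrier identification (its F is still reported).
#'   Guards against -ln P spikes from bins visited a handful of times.
#'   Default 5.
#' @param n_contacts Number of native contacts, needed only for
#'   `bins = "levels"` when `q_series` is a bare vector.
#' @return Object of class `free_energy_profile`: list with `bin_centers`,
#'   `f_values` (NA for empty bins), `counts`, `bin_width`,
#'   `basin_unfolded`, `basin_folded`, `barrier_bin` (bin indices), and
#'   `empty_bins`.
#' @export
free_energy_profile <- function(q_series, bins = 50L, weights = NULL,
                                require_two_state = TRUE, min_count = 5L,
                                n_contacts = NULL) {
  if (inherits(q_series, "sbm_trajectory")) {
    if (is.null(n_contacts)) n_contacts <- q_series$n_contacts
    q_series <- q_series$q_series
  }
  stopifnot(length(q_series) >= 1L)
  if (any(q_series < 0 | q_series > 1)) stop("Q values outside [0, 1]")
  if (is.null(weights)) weights <- rep(1, length(q_series))
  stopifnot(length(weights) == length(q_series), all(weights >= 0))

  if (identical(bins, "levels")) {
    if (is.null(n_contacts) || is.na(n_contacts)) {
      stop("bins = \"levels\" needs a trajectory with a contact count")
    }
    nc <- as.integer(n_contacts)
    bins <- nc + 1L
    idx <- pmin(pmax(round(q_series * nc), 0), nc) + 1L
    centers <- (0:nc) / nc
    width <- 1 / nc
  } else {
    stopifnot(bins >= 2L)
    bins <- as.integer(bins)
    width <- 1 / bins
    idx <- pmin(pmax(floor(q_series / width), 0), bins - 1L) + 1L
    centers <- (seq_len(bins) - 0.5) * width
  }
  mass <- vapply(seq_len(bins), function(b) sum(weights[idx == b]),
                 numeric(1))
  n_frames <- tabulate(idx, nbins = bins)
  p <- mass / sum(mass)
  f <- ifelse(p > 0, -log(p), NA_real_)

  basins <- locate_basins(smooth_profile(
    ifelse(n_frames >= min_count, f, NA_real_)))
  if (require_two_state && is.null(basins$barrier)) {
    stop("no two-state signature: fewer than two separated minima in F(Q)")
  }
  structure(
    list(bin_centers = centers, f_values = f, counts = mass,
         n_frames = n_frames, bin_width = width,
         basin_unfolded = basins$unfolded, basin_folded = basins$folded,
         barrier_bin = basins$barrier, empty_bins = which(p == 0)),
    class = "free_energy_profile"
  )
}

# light 1/4-1/2-1/4 running mean over the sequence of usable bins, used
# only to *locate* basins and barrier: single-bin notches (sub-state fine
# structure or residual sampling noise) otherwise masquerade as the
# dominant interior maximum. Reported F values remain raw.
smooth_profile <- function(f) {
  occ <- which(!is.na(f))
  if (length(occ) < 3L) return(f)
  v <- f[occ]
  k <- length(v)
  sm <- v
  sm[2:(k - 1L)] <- 0.25 * v[1:(k - 2L)] + 0.5 * v[2:(k - 1L)] +
    0.25 * v[3:k]
  sm[1] <- (2 * v[1] + v[2]) / 3
  sm[k] <- (2 * v[k] + v[k - 1L]) / 3
  out <- rep(NA_real_, length(f))
  out[occ] <- sm
  out
}

# basin identification: the barrier bin is the global maximum of F over
# the interior spanned by the outermost local minima; the basins are the
# deepest local minima on each side of it (ties toward extremal Q).
# Empty (NA) bins are excluded throughout.
locate_basins <- function(f) {
  none <- list(unfolded = NULL, folded = NULL, barrier = NULL)
  occ <- which(!is.na(f))
  if (length(occ) < 3L) return(none)
  fo <- f[occ]
  k <- length(occ)
  is_min <- vapply(seq_len(k), function(i) {
    left <- if (i > 1L) fo[i] <= fo[i - 1L] else TRUE
    right <- if (i < k) fo[i] <= fo[i + 1L] else TRUE
    left && right
  }, logical(1))
  mins <- occ[is_min]
  if (length(mins) < 2L) return(none)
  interior <- occ[occ > min(mins) & occ < max(mins)]
  if (!length(interior)) return(none)
  bar <- interior[which.max(f[interior])]
  left <- mins[mins < bar]
  right <- mins[mins > bar]
  if (!length(left) || !length(right)) return(none)
  # deepest minimum on each side; ties resolved toward extremal Q
  unfolded <- left[which.min(f[left] + 1e-12 * seq_along(left))]
  folded <- right[which.min(f[right] - 1e-12 * seq_along(right))]
  if (f[bar] <= max(f[unfolded], f[folded])) return(none)
  list(unfolded = unfolded, folded = folded, barrier = bar)
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("free_energy_profile: %d bins (width %.3g), %d empty\n",
              length(x$bin_centers), x$bin_width, length(x$empty_bins)))
  if (!is.null(x$barrier_bin)) {
    cat(sprintf("  basins at Q = %.2f / %.2f, barrier %.3f at Q = %.2f\n",
                x$bin_centers[x$basin_unfolded],
                x$bin_centers[x$basin_folded],
                barrier_height(x), x$bin_centers[x$barrier_bin]))
  }
  invisible(x)
}

#' Boltzmann-reweight a trajectory to equal basin free energies
#'
#' Single-histogram temperature reweighting: each frame is weighted by
#' exp(-(beta' - beta) * E) with beta' found by root-finding so that the
#' folded and unfolded basin minima of the reweighted F(Q) are equal; both
#' are then set to zero. Energies enter only through differences, so the
#' result is invariant to a uniform energy offset.
#'
#' @param traj An `sbm_trajectory` with per-frame potential energies.
#' @param bins Histogram bins (integer, or `"levels"` for one bin per
#'   discrete Q level). Default 50.
#' @param beta_range Search interval for beta'/beta. Default c(0.5, 2).
#' @return A `free_energy_profile` with equalized basins (`f_values`
#'   shifted so both basin minima are 0) plus fields `beta_prime_ratio`
#'   and `temperature`.
#' @export
reweight_equal_basins <- function(traj, bins = 50L,
                                  beta_range = c(0.5, 2)) {
  stopifnot(inherits(traj, "sbm_trajectory"))
  q <- traj$q_series
  e <- traj$e_series
  if (is.null(e) || !length(e)) stop("trajectory lacks per-frame energies")
  beta <- 1 / traj$temperature
  e0 <- e - mean(e) # gauge: offsets cancel in normalized weights
  nc <- traj$n_contacts

  base <- free_energy_profile(q, bins = bins, n_contacts = nc)
  split_q <- base$bin_centers[base$barrier_bin]

  gap <- function(ratio) {
    w <- exp(-(ratio - 1) * beta * e0)
    prof <- free_energy_profile(q, bins = bins, weights = w,
                                require_two_state = FALSE, n_contacts = nc)
    lowq <- prof$bin_centers < split_q
    fu <- suppressWarnings(min(prof$f_values[lowq], na.rm = TRUE))
    ff <- suppressWarnings(min(prof$f_values[!lowq], na.rm = TRUE))
    if (!is.finite(fu) || !is.finite(ff)) return(NA_real_)
    ff - fu
  }
  # take the equalizing beta' closest to the sampling temperature: far
  # roots correspond to reweightings whose effective sample size has
  # collapsed. Expand the bracket outward from ratio = 1 until the basin
  # gap changes sign, then root-find inside that bracket.
  g1 <- gap(1)
  if (!is.finite(g1)) stop("basins not resolvable at the sampling weights")
  if (abs(g1) < 1e-9) {
    ratio <- 1
  } else {
    ratio <- NA_real_
    delta <- 0.02
    repeat {
      lo <- max(beta_range[1], 1 - delta)
      hi <- min(beta_range[2], 1 + delta)
      g_lo <- gap(lo)
      g_hi <- gap(hi)
      if (is.finite(g_lo) && g_lo * g1 < 0) {
        ratio <- stats::uniroot(gap, c(lo, 1), tol = 1e-10)$root
        break
      }
      if (is.finite(g_hi) && g_hi * g1 < 0) {
        ratio <- stats::uniroot(gap, c(1, hi), tol = 1e-10)$root
        break
      }
      if (lo <= beta_range[1] && hi >= beta_range[2]) break
      delta <- delta * 2
    }
    if (!is.finite(ratio)) {
      stop("no beta' in the search range equalizes the basins")
    }
  }
  w <- exp(-(ratio - 1) * beta * e0)
  prof <- free_energy_profile(q, bins = bins, weights = w, n_contacts = nc)
  basin_val <- prof$f_values[prof$basin_folded]
  prof$f_values <- prof$f_values - basin_val
  prof$beta_prime_ratio <- ratio
  prof$temperature <- traj$temperature
  prof$equalized <- TRUE
  prof
}

#' Unfolding free-energy barrier height
#'
#' F at the barrier bin minus the basin value. For an equalized profile the
#' basins sit at 0 and the barrier is reported in kB*Tf units.
#'
#' @param p A `free_energy_profile`.
#' @return Barrier height (kB*T units).
#' @export
barrier_height <- function(p) {
  stopifnot(inherits(p, "free_energy_profile"))
  if (is.null(p$barrier_bin)) stop("profile has no identified barrier")
  p$f_values[p$barrier_bin] -
    min(p$f_values[p$basin_unfolded], p$f_values[p$basin_folded])
}

#' Q-resolved difference between two free-energy profiles
#'
#' Exports F_b(Q) - F_a(Q) over bins occupied in both profiles, for
#' plotting barrier-shape differences between designs.
#'
#' @param p_a,p_b `free_energy_profile` objects on the same binning.
#' @return data.frame with `q`, `f_a`, `f_b`, `delta`.
#' @export
profile_difference <- function(p_a, p_b) {
  stopifnot(length(p_a$bin_centers) == length(p_b$bin_centers))
  ok <- !is.na(p_a$f_values) & !is.na(p_b$f_values)
  data.frame(q = p_a$bin_centers[ok], f_a = p_a$f_values[ok],
             f_b = p_b$f_values[ok],
             delta = p_b$f_values[ok] - p_a$f_values[ok])
}

#' Average contact map at a target Q
#'
#' Pools all frames with |Q - q_target| <= tol and returns the per-contact
#' mean of the formation flags: the average partially folded structure at
#' that point of the folding reaction.
#'
#' @param traj An `sbm_trajectory` recorded with `record_flags = TRUE`.
#' @param q_target Target fraction of native contacts. Default 0.4.
#' @param tol Window half-width around `q_target`. Default half a default
#'   bin (0.01).
#' @return Object of class `average_contact_map`: list with `probability`
#'   (per contact, in contact order of the topology), `q_target`,
#'   `n_snapshots`.
#' @export
average_contact_map <- function(traj, q_target = 0.4, tol = 0.01) {
  stopifnot(inherits(traj, "sbm_trajectory"))
  if (is.null(traj$contact_formed)) {
    stop("trajectory was not recorded with per-contact flags")
  }
  sel <- abs(traj$q_series - q_target) <= tol
  if (!any(sel)) stop("no snapshots within |Q - ", q_target, "| <= ", tol)
  structure(
    list(probability = colMeans(traj$contact_formed[sel, , drop = FALSE]),
         q_target = q_target, n_snapshots = sum(sel)),
    class = "average_contact_map"
  )
}

#' Write a free-energy profile as TSV or JSON
#' @param p A `free_energy_profile`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(
      data.frame(q = p$bin_centers, f = p$f_values, count = p$counts),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(bin_centers = p$bin_centers, f_values = p$f_values,
           counts = p$counts, barrier = if (!is.null(p$barrier_bin))
             barrier_height(p) else NULL),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
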
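#' Long-range contact deficits between homologs at aligned core positions
#'
#' Tallies long-range contacts attributed to a chosen residue subset in a
#' parent protein and in a donor homolog at the structurally equivalent
#' positions (0.5 weighting when both endpoints of a pair are in the
#' subset), and reports the donor-minus-parent deficit.
#'
#' @param map_parent,map_donor `residue_contact_map` objects.
#' @param aln A `position_alignment` (parent positions -> donor positions).
#' @param positions 0-based parent residue indices (e.g. the conserved
#'   core); every position must be aligned.
#' @param shared_weight Weight per endpoint for subset-internal pairs.
#'   Default 0.5.
#' @param threshold Long-range separation threshold. Default 12.
#' @return List with `per_position` (data.frame `pos_parent`, `pos_donor`,
#'   `parent`, `donor`, `deficit`), `parent_total`, `donor_total`,
#'   `deficit` (= donor_total - parent_total).
#' @export
contact_deficits <- function(map_parent, map_donor, aln, positions,
                             shared_weight = 0.5, threshold = 12L) {
  positions <- as.integer(positions)
  donor_pos <- aln_forward(aln, positions)
  if (anyNA(donor_pos)) {
    stop("unaligned parent position(s) in subset: ",
         paste(positions[is.na(donor_pos)], collapse = ", "))
  }
  pr <- per_residue_long_range(map_parent, positions,
                               shared_weight = shared_weight,
                               threshold = threshold)
  dn <- per_residue_long_range(map_donor, donor_pos,
                               shared_weight = shared_weight,
                               threshold = threshold)
  per_pos <- data.frame(
    pos_parent = positions,
    pos_donor = donor_pos,
    parent = unname(pr$per_residue[as.character(positions)]),
    donor = unname(dn$per_residue[as.character(donor_pos)])
  )
  per_pos$deficit <- per_pos$donor - per_pos$parent
  list(per_position = per_pos,
       parent_total = pr$subset_total,
       donor_total = dn$subset_total,
       deficit = dn$subset_total - pr$subset_total)
}

#' Propose a core swap: graft donor residues onto the parent sequence
#'
#' Substitutes the donor's residues at the structurally equivalent parent
#' positions. Positions where the two proteins already agree are listed but
#' unchanged.
#'
#' @param parent_seq,donor_seq One-letter sequences (character scalars).
#' @param aln A `position_alignment` (parent -> donor).
#' @param positions 0-based parent positions to swap.
#' @return List of class `swap_proposal`: `positions`, `parent_residue`,
#'   `donor_residue`, `mutant_sequence`, `n_substitutions`.
#' @export
propose_core_swap <- function(parent_seq, donor_seq, aln, positions) {
  pc <- strsplit(parent_seq, "")[[1]]
  dc <- strsplit(donor_seq, "")[[1]]
  positions <- as.integer(positions)
  if (any(positions < 0L) || any(positions >= length(pc))) {
    stop("positions outside the parent sequence")
  }
  donor_pos <- aln_forward(aln, positions)
  if (anyNA(donor_pos)) {
    stop("alignment gap at requested position(s): ",
         paste(positions[is.na(donor_pos)], collapse = ", "))
  }
  if (any(donor_pos >= length(dc))) stop("alignment exceeds donor sequence")
  parent_res <- pc[positions + 1L]
  donor_res <- dc[donor_pos + 1L]
  mutant <- pc
  mutant[positions + 1L] <- donor_res
  structure(
    list(positions = positions,
         parent_residue = parent_res,
         donor_residue = donor_res,
         mutant_sequence = paste(mutant, collapse = ""),
         n_substitutions = sum(parent_res != donor_res)),
    class = "swap_proposal"
  )
}

#' @export
print.swap_proposal <- function(x, ...) {
  cat(sprintf("swap_proposal: %d position(s), %d substitution(s)\n",
              length(x$positions), x$n_substitutions))
  invisible(x)
}

#' Evaluate candidate design models by topology and predicted rates
#'
#' Computes LRO, ACO, and the predicted midpoint unfolding rates for each
#' model, flags interquartile-range outliers (a model is an outlier when
#' its LRO or ACO falls outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR] over the model
#' set, quartiles by linear interpolation), and reports deltas against the
#' parent. An external keep/drop vector can impose additional screens
#' (e.g. stereochemical quality) decided outside this package.
#'
#' @param models List of `protein_structure` models.
#' @param parent Optional parent `protein_structure` for deltas.
#' @param map_kind `"cutoff"` or `"shadow"`. Default `"shadow"`.
#' @param cutoff,shadow_radius Map parameters.
#' @param iqr_k Fence multiplier. Default 1.5.
#' @param keep Optional logical vector (length of `models`): FALSE drops a
#'   model regardless of its metrics.
#' @return data.frame of class `design_report`: `model_id`, `lro`, `aco`,
#'   `ku_pred_lro`, `ku_pred_aco`, `dlro_vs_parent`, `daco_vs_parent`,
#'   `outlier`, `kept`.
#' @export
evaluate_designs <- function(models, parent = NULL,
                             map_kind = c("shadow", "cutoff"),
                             cutoff = 6.0, shadow_radius = 1.0,
                             iqr_k = 1.5, keep = NULL) {
  map_kind <- match.arg(map_kind)
  stopifnot(length(models) >= 1L)
  reports <- lapply(models, topology_report, map_kind = map_kind,
                    cutoff = cutoff, shadow_radius = shadow_radius)
  lro <- vapply(reports, `[[`, numeric(1), "lro")
  aco <- vapply(reports, `[[`, numeric(1), "aco")
  ids <- names(models)
  if (is.null(ids)) ids <- paste0("model_", seq_along(models))

  fence <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    c(q[1] - iqr_k * iqr, q[2] + iqr_k * iqr)
  }
  out_l <- fence(lro)
  out_a <- fence(aco)
  outlier <- lro < out_l[1] | lro > out_l[2] | aco < out_a[1] | aco > out_a[2]

  if (!is.null(parent)) {
    pr <- topology_report(parent, map_kind = map_kind, cutoff = cutoff,
                          shadow_radius = shadow_radius)
    dlro <- lro - pr$lro
    daco <- aco - pr$aco
  } else {
    dlro <- rep(NA_real_, length(lro))
    daco <- rep(NA_real_, length(aco))
  }
  if (is.null(keep)) keep <- rep(TRUE, length(models))
  stopifnot(length(keep) == length(models))

  res <- data.frame(
    model_id = ids, lro = lro, aco = aco,
    ku_pred_lro = ku_from_lro(lro), ku_pred_aco = ku_from_aco(aco),
    dlro_vs_parent = dlro, daco_vs_parent = daco,
    outlier = outlier, kept = keep & !outlier
  )
  class(res) <- c("design_report", "data.frame")
  res
}
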
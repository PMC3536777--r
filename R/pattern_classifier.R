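#' The nine regulation-pattern archetypes
#'
#' Each archetype is a point in (unliganded fold, ligand fold) space with
#' components in \{0.5, 1, 2\}: RR = (0.5, 0.5), RO = (0.5, 1),
#' RI = (0.5, 2), OR = (1, 0.5), OO = (1, 1), OI = (1, 2), IR = (2, 0.5),
#' IO = (2, 1), II = (2, 2). Listing order is the tie-break order.
#'
#' @return Data frame with columns `label`, `fc_u`, `fc_l`.
#' @export
pattern_archetypes <- function() {
  fold <- c(R = 0.5, O = 1, I = 2)
  lab <- archetype_labels()
  data.frame(label = lab,
             fc_u = as.numeric(fold[substr(lab, 1L, 1L)]),
             fc_l = as.numeric(fold[substr(lab, 2L, 2L)]),
             stringsAsFactors = FALSE)
}

#' Clamp a fold change into \[0.5, 2\]
#'
#' Values > 2 become 2, values < 0.5 become 0.5, the rest pass through.
#' This bounds the influence of extreme responders before distance
#' computation.
#'
#' @param fc Positive fold change(s), linear scale.
#' @return Clamped fold change(s).
#' @export
clamp_fold_change <- function(fc) {
  if (any(!is.finite(fc)) || any(fc <= 0))
    stop("fold changes must be positive and finite")
  pmin(pmax(fc, 0.5), 2)
}

#' Assign nearest regulation archetype
#'
#' Clamps both fold-change components into \[0.5, 2\], computes the
#' Euclidean distance to each of the nine archetype vectors in linear
#' fold-change space, and assigns the minimizer. Ties are broken by
#' archetype listing order and flagged.
#'
#' @param fc_u Unliganded-axis fold change(s), linear scale, > 0.
#' @param fc_l Ligand-axis fold change(s), linear scale, > 0.
#' @return Data frame: `label`, `distance`, `clamped_u`, `clamped_l`,
#'   `input_u`, `input_l`, `tie` (logical).
#' @export
assign_pattern <- function(fc_u, fc_l) {
  if (length(fc_u) != length(fc_l)) stop("fc_u and fc_l lengths differ")
  cu <- clamp_fold_change(fc_u)
  cl <- clamp_fold_change(fc_l)
  arch <- pattern_archetypes()
  d2 <- outer(cu, arch$fc_u, "-")^2 + outer(cl, arch$fc_l, "-")^2
  idx <- max.col(-d2, ties.method = "first")
  dmin <- d2[cbind(seq_along(cu), idx)]
  tie <- rowSums(abs(d2 - dmin) < 1e-12) > 1L
  data.frame(label = arch$label[idx],
             distance = sqrt(dmin),
             clamped_u = cu, clamped_l = cl,
             input_u = fc_u, input_l = fc_l,
             tie = tie,
             stringsAsFactors = FALSE)
}

#' Classify significant probes into regulation patterns
#'
#' Joins the unliganded-effect and ligand-effect contrast results over a
#' common probe universe, gates eligibility on the BH-adjusted p-value,
#' converts log2 effects to linear folds, and assigns each eligible probe
#' its nearest archetype. OO assignments are retained in the assignment
#' table but excluded from the reported per-pattern counts, since OO means
#' no substantial response on either axis.
#'
#' @param de_unliganded Contrast results for the unliganded axis.
#' @param de_ligand Contrast results for the ligand axis (within-receptor
#'   T3 fold by convention).
#' @param alpha Adjusted-p eligibility cutoff.
#' @param eligibility Which contrast(s) must pass alpha: `"either"`
#'   (default), `"ligand_only"`, `"unliganded_only"`, or `"both"`.
#' @return List: `assignments` (one row per eligible probe, including OO),
#'   `counts` (named vector over the eight reportable patterns),
#'   `n_oo` (count of eligible probes absorbed by OO).
#' @export
classify_probe_set <- function(de_unliganded, de_ligand, alpha = 0.05,
                               eligibility = c("either", "ligand_only",
                                               "unliganded_only", "both")) {
  eligibility <- match.arg(eligibility)
  if (!setequal(de_unliganded$probe_id, de_ligand$probe_id))
    stop("the two contrast tables must cover the same probes")
  dl <- de_ligand[match(de_unliganded$probe_id, de_ligand$probe_id), ]
  pass_u <- de_unliganded$p_adj <= alpha
  pass_l <- dl$p_adj <= alpha
  keep <- switch(eligibility,
                 either = pass_u | pass_l,
                 ligand_only = pass_l,
                 unliganded_only = pass_u,
                 both = pass_u & pass_l)
  asg <- assign_pattern(2^de_unliganded$log2fc[keep], 2^dl$log2fc[keep])
  asg <- cbind(probe_id = de_unliganded$probe_id[keep], asg,
               stringsAsFactors = FALSE)
  reportable <- setdiff(archetype_labels(), "OO")
  counts <- stats::setNames(integer(length(reportable)), reportable)
  tab <- table(asg$label)
  counts[intersect(names(tab), reportable)] <-
    as.integer(tab[intersect(names(tab), reportable)])
  list(assignments = asg, counts = counts,
       n_oo = sum(asg$label == "OO"))
}
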
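#' Total-least-squares slope
#'
#' Orthogonal-regression slope of y on x via the principal eigenvector of
#' the 2 x 2 covariance matrix; appropriate when both axes are estimates.
#'
#' @param x,y Numeric vectors.
#' @return Slope (dy/dx of the first principal axis).
#' @export
tls_slope <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  v <- eigen(stats::cov(cbind(x, y)))$vectors[, 1L]
  if (abs(v[1L]) < .Machine$double.eps) return(Inf)
  v[2L] / v[1L]
}

#' TRalpha / TRbeta concordance at one time point
#'
#' Counts gate-passing probes per receptor and their overlap, and measures
#' agreement of effect sizes over the union of passers: Pearson correlation
#' of log2 fold changes and the total-least-squares slope of beta on alpha
#' (slope > 1 means stronger beta responses).
#'
#' @param deA,deB Contrast result tables for TRalpha and TRbeta over the
#'   same probes (typically the within-receptor T3 or interaction
#'   contrast).
#' @param fold_cutoff,alpha Gate parameters.
#' @param time_hr Optional label carried into the summary.
#' @return One-row data frame: `time_hr`, `n_alpha`, `n_beta`, `n_overlap`,
#'   `n_union`, `pearson_r`, `slope`, `undefined` (TRUE when the union is
#'   empty).
#' @export
concordance <- function(deA, deB, fold_cutoff = 2, alpha = 0.05,
                        time_hr = NA_real_) {
  if (!setequal(deA$probe_id, deB$probe_id))
    stop("concordance requires the same probes in both tables")
  deB <- deB[match(deA$probe_id, deB$probe_id), ]
  pa <- passes_gate(deA, fold_cutoff, alpha)
  pb <- passes_gate(deB, fold_cutoff, alpha)
  un <- pa | pb
  if (!any(un)) {
    return(data.frame(time_hr = time_hr, n_alpha = 0L, n_beta = 0L,
                      n_overlap = 0L, n_union = 0L, pearson_r = NA_real_,
                      slope = NA_real_, undefined = TRUE))
  }
  x <- deA$log2fc[un]; y <- deB$log2fc[un]
  data.frame(time_hr = time_hr,
             n_alpha = sum(pa), n_beta = sum(pb), n_overlap = sum(pa & pb),
             n_union = sum(un),
             pearson_r = if (sum(un) > 1) stats::cor(x, y) else NA_real_,
             slope = tls_slope(x, y),
             undefined = FALSE)
}

#' Kinetic classification of T3 responses
#'
#' Classifies each probe that passes the gate for at least one receptor at
#' some time point:
#' * `alpha_early` — passes with TRalpha at a pre-terminal time strictly
#'   before any TRbeta pass;
#' * `beta_late` — passes with TRbeta at the last time with
#'   `|log2fc_beta| >= beta_pref_factor * |log2fc_alpha|` there (the
#'   TRbeta-preferential criterion);
#' * `concordant` — first passes at the same time with fold ratio below
#'   `beta_pref_factor` both ways at that time;
#' * `discordant_other` — the remainder.
#'
#' @param resA,resB Named lists of contrast result tables, one per time
#'   point (names = time in hours), for TRalpha and TRbeta.
#' @param fold_cutoff,alpha Gate parameters.
#' @param beta_pref_factor Magnitude factor for the beta-preferential and
#'   concordance rules (default 2).
#' @return Data frame: `probe_id`, `class`, `earliest_pass_alpha`,
#'   `earliest_pass_beta` (NA when never passing).
#' @export
kinetic_classify <- function(resA, resB, fold_cutoff = 2, alpha = 0.05,
                             beta_pref_factor = 2) {
  times <- sort(as.numeric(names(resA)))
  if (length(times) < 2L) stop("need >= 2 time points per receptor")
  if (!setequal(names(resA), names(resB)))
    stop("time points differ between receptors")
  probes <- resA[[1L]]$probe_id
  pass_t <- function(res, t) {
    r <- res[[as.character(t)]]
    passes_gate(r, fold_cutoff, alpha)[match(probes, r$probe_id)]
  }
  lfc_t <- function(res, t) {
    r <- res[[as.character(t)]]
    r$log2fc[match(probes, r$probe_id)]
  }
  passA <- matrix(sapply(times, pass_t, res = resA), ncol = length(times))
  passB <- matrix(sapply(times, pass_t, res = resB), ncol = length(times))
  firstA <- apply(passA, 1L, function(z) if (any(z)) times[which(z)[1L]] else NA_real_)
  firstB <- apply(passB, 1L, function(z) if (any(z)) times[which(z)[1L]] else NA_real_)
  t_last <- times[length(times)]
  la <- abs(lfc_t(resA, t_last)); lb <- abs(lfc_t(resB, t_last))
  any_pass <- !is.na(firstA) | !is.na(firstB)
  fa <- ifelse(is.na(firstA), Inf, firstA)
  fb <- ifelse(is.na(firstB), Inf, firstB)
  alpha_early <- is.finite(fa) & fa < t_last & fa < fb
  beta_late <- passB[, length(times)] & lb >= beta_pref_factor * la
  same_first <- is.finite(fa) & fa == fb
  ratio_ok <- lb < beta_pref_factor * la & la < beta_pref_factor * lb
  concordant <- same_first & ratio_ok
  cls <- rep(NA_character_, length(probes))
  cls[any_pass] <- "discordant_other"
  cls[any_pass & concordant] <- "concordant"
  cls[any_pass & beta_late] <- "beta_late"
  cls[any_pass & alpha_early & !beta_late] <- "alpha_early"
  out <- data.frame(probe_id = probes, class = cls,
                    earliest_pass_alpha = firstA,
                    earliest_pass_beta = firstB,
                    stringsAsFactors = FALSE)
  out[any_pass, , drop = FALSE]
}

#' Direction-stratified overlap counts of flagged gene sets
#'
#' Takes named gated result tables (with `probe_id` and `direction`) and
#' returns intersection cardinalities for every non-empty combination of
#' sets, separately for induced and repressed probes. A probe flagged
#' induced in one set and repressed in another is excluded from both
#' direction strata and reported as discordant.
#'
#' @param sets Named list of data frames, each with columns `probe_id` and
#'   `direction` (as produced by [gate_significant()]).
#' @return List: `counts` (data frame with `combo`, `induced`, `repressed`)
#'   and `discordant` (character vector of probe ids).
#' @export
overlap_table <- function(sets) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  dir_of <- lapply(sets, function(s) stats::setNames(s$direction, s$probe_id))
  all_probes <- unique(unlist(lapply(sets, `[[`, "probe_id")))
  dirs <- sapply(all_probes, function(p) {
    d <- unique(stats::na.omit(sapply(dir_of, function(m) m[p])))
    if (length(d) > 1L) "discordant" else d
  })
  discordant <- all_probes[dirs == "discordant"]
  nm <- names(sets)
  combos <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(combos, function(cm) {
    ids <- Reduce(intersect, lapply(sets[cm], `[[`, "probe_id"))
    ids <- setdiff(ids, discordant)
    data.frame(combo = paste(cm, collapse = "&"),
               induced = sum(dirs[ids] == "induced"),
               repressed = sum(dirs[ids] == "repressed"),
               stringsAsFactors = FALSE)
  })
  list(counts = do.call(rbind, rows), discordant = discordant)
}

#' Per-pattern overlap between two archetype assignments
#'
#' For each of the eight reportable patterns, counts probes assigned that
#' label with TRalpha, with TRbeta, and with both.
#'
#' @param assignA,assignB Assignment tables from [classify_probe_set()]
#'   (`$assignments`), over the same probe universe.
#' @return Data frame: `label`, `n_alpha`, `n_beta`, `overlap`.
#' @export
pattern_overlap <- function(assignA, assignB) {
  labs <- setdiff(archetype_labels(), "OO")
  rows <- lapply(labs, function(lb) {
    a <- assignA$probe_id[assignA$label == lb]
    b <- assignB$probe_id[assignB$label == lb]
    data.frame(label = lb, n_alpha = length(a), n_beta = length(b),
               overlap = length(intersect(a, b)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
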
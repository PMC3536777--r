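#' Persistence ratio of the T3 response under cycloheximide
#'
#' For each probe, the T3 response without CHX is
#' `delta_free = mean log2(T3) - mean log2(control)` and the response under
#' translation blockade is `delta_chx = mean log2(T3+CHX) - mean log2(CHX)`
#' (or vs the untreated control when `baseline = "control"`). The ratio
#' `delta_chx / delta_free` is signed, so full persistence of a repression
#' also yields ~1. Probes whose `|delta_free|` falls below `floor` get an
#' NA ratio (near-zero denominator).
#'
#' @param mat Expression matrix containing the four 3 h CHX-arm conditions.
#' @param design Matching design sheet.
#' @param receptor `"TRA"` or `"TRB"`.
#' @param probes Optional probe subset (usually probes passing the T3
#'   significance gate).
#' @param floor Minimum `|delta_free|` in log2 units for a defined ratio.
#' @param baseline Reference for the CHX-context response: `"chx"`
#'   (CHX-alone, default — isolates the T3 increment under blockade) or
#'   `"control"`.
#' @return Data frame: `probe_id`, `receptor`, `delta_free`, `delta_chx`,
#'   `persistence`.
#' @export
persistence_ratio <- function(mat, design, receptor, probes = NULL,
                              floor = 0.1, baseline = c("chx", "control")) {
  baseline <- match.arg(baseline)
  design <- align_design(mat, design)
  sub <- design[design$receptor == receptor, , drop = FALSE]
  pick <- function(lig, chx) {
    ids <- sub$sample_id[sub$ligand == lig & sub$chx == chx]
    if (length(ids) < 2L)
      stop(sprintf("condition (%s, chx=%s) needs >= 2 replicates for %s",
                   lig, chx, receptor))
    rowMeans(mat[, ids, drop = FALSE])
  }
  ctrl <- pick("vehicle", FALSE)
  t3 <- pick("T3", FALSE)
  chx <- pick("vehicle", TRUE)
  t3chx <- pick("T3", TRUE)
  delta_free <- t3 - ctrl
  delta_chx <- t3chx - (if (baseline == "chx") chx else ctrl)
  out <- data.frame(probe_id = rownames(mat), receptor = receptor,
                    delta_free = delta_free, delta_chx = delta_chx,
                    persistence = ifelse(abs(delta_free) >= floor,
                                         delta_chx / delta_free, NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(probes)) out <- out[out$probe_id %in% probes, , drop = FALSE]
  out
}

#' Call direct / attenuated / indirect TR targets
#'
#' Applies the persistence criterion: a T3 response retained at >= 100%
#' under CHX marks a direct target (no intermediate protein synthesis
#' needed); a response reduced to <= `indirect_cut` (default 25%) is called
#' indirect (secondary); the middle band is `attenuated`, reflecting
#' partial persistence. Super-persistence (> 100%, CHX amplification) is
#' still called direct; the ratio is reported so such genes can be
#' separated downstream.
#'
#' @inheritParams persistence_ratio
#' @param direct_cut Persistence at or above which the call is `direct`.
#' @param indirect_cut Persistence at or below which the call is
#'   `indirect`.
#' @return The [persistence_ratio()] table plus `call` (NA where the ratio
#'   is undefined) and `chx_alone_effect` (mean log2 CHX-alone vs control).
#' @export
call_direct_targets <- function(mat, design, receptor, probes = NULL,
                                floor = 0.1, baseline = c("chx", "control"),
                                direct_cut = 1.0, indirect_cut = 0.25) {
  pr <- persistence_ratio(mat, design, receptor, probes, floor, baseline)
  design <- align_design(mat, design)
  sub <- design[design$receptor == receptor, , drop = FALSE]
  ctrl <- rowMeans(mat[, sub$sample_id[sub$ligand == "vehicle" & !sub$chx],
                       drop = FALSE])
  chx <- rowMeans(mat[, sub$sample_id[sub$ligand == "vehicle" & sub$chx],
                      drop = FALSE])
  chx_eff <- (chx - ctrl)[match(pr$probe_id, rownames(mat))]
  eps <- 1e-9  # guard against float error exactly at the printed boundaries
  pr$call <- ifelse(is.na(pr$persistence), NA_character_,
             ifelse(pr$persistence >= direct_cut - eps, "direct",
             ifelse(pr$persistence <= indirect_cut + eps, "indirect", "attenuated")))
  pr$chx_alone_effect <- as.numeric(chx_eff)
  pr
}

#' Flag receptor-selective CHX-alone de-repression
#'
#' Tests the CHX-alone vs control contrast within each receptor line with
#' the moderated t machinery and flags probes whose CHX effect passes the
#' standard fold/alpha gate with one receptor but not the other.
#'
#' @param mat Expression matrix with the CHX arm.
#' @param design Matching design sheet.
#' @param fold_cutoff,alpha Gate parameters (defaults 2-fold, 0.05).
#' @return Data frame: `probe_id`, `log2fc_TRA`, `log2fc_TRB`,
#'   `pass_TRA`, `pass_TRB`, `flag` in
#'   \{`"TRA_selective"`, `"TRB_selective"`, `"both"`, `"none"`\}.
#' @export
chx_derepression_flags <- function(mat, design, fold_cutoff = 2, alpha = 0.05) {
  design <- align_design(mat, design)
  res <- list()
  for (rec in c("TRA", "TRB")) {
    sub <- design[design$receptor == rec & design$ligand == "vehicle", ,
                  drop = FALSE]
    if (!any(sub$chx) || !any(!sub$chx))
      stop("CHX-alone and control conditions required for ", rec)
    m <- mat[, sub$sample_id, drop = FALSE]
    fit <- fit_cell_means(m, sub, by = "chx")
    mod <- moderate_variances(fit$s2, fit$df)
    w <- stats::setNames(c(1, -1), c("TRUE", "FALSE"))
    res[[rec]] <- test_contrast(fit, mod, w, name = paste0("chx_", rec))
  }
  pa <- passes_gate(res$TRA, fold_cutoff, alpha)
  pb <- passes_gate(res$TRB, fold_cutoff, alpha)
  data.frame(probe_id = res$TRA$probe_id,
             log2fc_TRA = res$TRA$log2fc, log2fc_TRB = res$TRB$log2fc,
             pass_TRA = pa, pass_TRB = pb,
             flag = ifelse(pa & pb, "both",
                    ifelse(pa, "TRA_selective",
                    ifelse(pb, "TRB_selective", "none"))),
             stringsAsFactors = FALSE)
}
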
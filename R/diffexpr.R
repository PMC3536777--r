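#' Fit per-gene condition-cell means
#'
#' Cell-means parameterization of the factorial design: genes are fit
#' independently, each condition cell (by default receptor x ligand) gets
#' its arithmetic mean of log2 values, and the residual variance is pooled
#' within cells with `df = n_samples - n_cells`.
#'
#' @param mat Expression matrix (probes x samples, log2).
#' @param design Design sheet covering exactly the matrix columns.
#' @param by Design columns whose combinations define the cells.
#' @return List of class `cell_fit`: `means` (genes x cells), `s2` (pooled
#'   residual variance per gene), `df` (residual degrees of freedom,
#'   scalar), `n` (samples per cell), `avg_expr` (per-gene mean over all
#'   samples), `cells` (cell labels).
#' @export
fit_cell_means <- function(mat, design, by = c("receptor", "ligand")) {
  design <- align_design(mat, design)
  miss <- setdiff(by, names(design))
  if (length(miss)) stop("unknown design column(s): ", paste(miss, collapse = ", "))
  cell <- do.call(paste, c(design[by], sep = "."))
  cells <- unique(cell)
  n <- table(factor(cell, levels = cells))
  if (ncol(mat) - length(cells) < 1L)
    stop("no residual degrees of freedom: every design cell is a singleton")
  ind <- outer(cell, cells, "==") * 1
  means <- mat %*% sweep(ind, 2L, colSums(ind), "/")
  colnames(means) <- cells
  resid <- mat - means[, match(cell, cells), drop = FALSE]
  df <- ncol(mat) - length(cells)
  structure(list(
    means = means,
    s2 = rowSums(resid^2) / df,
    df = df,
    n = as.numeric(n), cells = cells,
    avg_expr = rowMeans(mat)
  ), class = "cell_fit")
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear; needed to moment-match the prior df.
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Assumes the hierarchical model in which true gene variances follow a
#' scaled inverse-chi-square prior with `d0` degrees of freedom and scale
#' `s0^2`, so observed `s^2` values follow `s0^2` times an F distribution.
#' `(d0, s0^2)` are estimated by moment-matching the mean and variance of
#' `log s^2` using digamma/trigamma identities, and each gene's variance is
#' shrunk to the posterior mean `(d0 s0^2 + df s^2) / (d0 + df)`.
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar or per-gene).
#' @param d0_override Optional fixed prior df (e.g. 0 disables shrinkage,
#'   `Inf` collapses every variance to the prior scale).
#' @return List of class `var_mod`: `s2_post`, `d0`, `s0_2`.
#' @export
moderate_variances <- function(s2, df, d0_override = NULL) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  # With infinite prior df the hierarchy degenerates to one shared variance,
  # whose natural estimate is the plain mean of s2 (exact when all s2 are
  # equal); the log-moment formula applies only to a proper prior.
  s0_from_d0 <- function(d0, e) {
    if (is.infinite(d0)) mean(s2[ok]) else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  if (!is.null(d0_override)) {
    d0 <- d0_override
    s0_2 <- if (length(e) && d0 > 0) s0_from_d0(d0, e) else NA_real_
  } else if (sum(ok) < 10L) {
    warning("fewer than 10 usable genes; variance moderation disabled (d0 = 0)")
    d0 <- 0
    s0_2 <- NA_real_
  } else {
    evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * .trigamma_inverse(evar)
      s0_2 <- s0_from_d0(d0, e)
    } else {
      d0 <- Inf
      s0_2 <- s0_from_d0(d0, e)
    }
  }
  s2_post <- if (is.infinite(d0)) {
    rep_len(s0_2, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_2 + df * s2) / (d0 + df)
  }
  structure(list(s2_post = s2_post, d0 = d0, s0_2 = s0_2), class = "var_mod")
}

#' Contrast constructors for the factorial TR design
#'
#' Returns a named weight vector over `receptor.ligand` cells:
#' * `unliganded` — receptor effect without hormone:
#'   (receptor, vehicle) - (parental, vehicle);
#' * `interaction` — the T3 x over-expression interaction:
#'   \[(receptor, T3) - (receptor, vehicle)\] -
#'   \[(parental, T3) - (parental, vehicle)\];
#' * `t3_within` — plain T3 effect within the receptor line:
#'   (receptor, T3) - (receptor, vehicle).
#'
#' @param type One of `"unliganded"`, `"interaction"`, `"t3_within"`.
#' @param receptor `"TRA"` or `"TRB"`.
#' @return Named numeric weight vector summing to 0.
#' @export
make_contrast <- function(type = c("unliganded", "interaction", "t3_within"),
                          receptor = c("TRA", "TRB")) {
  type <- match.arg(type)
  receptor <- match.arg(receptor)
  switch(type,
    unliganded = stats::setNames(c(1, -1),
      c(paste0(receptor, ".vehicle"), "parental.vehicle")),
    interaction = stats::setNames(c(1, -1, -1, 1),
      c(paste0(receptor, ".T3"), paste0(receptor, ".vehicle"),
        "parental.T3", "parental.vehicle")),
    t3_within = stats::setNames(c(1, -1),
      c(paste0(receptor, ".T3"), paste0(receptor, ".vehicle")))
  )
}

#' Test a contrast with the moderated t statistic
#'
#' `log2fc = sum_c w_c mean_c`; its standard error uses the moderated
#' variance and per-cell sample counts; `t = log2fc / se` is referred to a
#' t distribution on `df + d0` degrees of freedom, two-sided, and BH
#' adjustment is applied across genes.
#'
#' @param fit A `cell_fit` from [fit_cell_means()].
#' @param mod A `var_mod` from [moderate_variances()] on the same fit.
#' @param contrast Named weight vector over cells (see [make_contrast()]).
#' @param name Label stored in the result.
#' @return Data frame: `probe_id`, `log2fc`, `avg_expr`, `t_mod`, `p_raw`,
#'   `p_adj`, `df_total`, `contrast`.
#' @export
test_contrast <- function(fit, mod, contrast, name = NULL) {
  stopifnot(inherits(fit, "cell_fit"), inherits(mod, "var_mod"))
  bad <- setdiff(names(contrast), fit$cells)
  if (length(bad)) stop("contrast references empty/unknown cell(s): ",
                        paste(bad, collapse = ", "))
  idx <- match(names(contrast), fit$cells)
  log2fc <- as.numeric(fit$means[, idx, drop = FALSE] %*% contrast)
  u <- sum(contrast^2 / fit$n[idx])
  se <- sqrt(mod$s2_post * u)
  df_total <- fit$df + mod$d0
  t_mod <- ifelse(se > 0, log2fc / se,
                  ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
  p_raw <- ifelse(is.finite(t_mod),
                  2 * stats::pt(-abs(t_mod), df = df_total),
                  0)
  p_raw[se == 0 & log2fc == 0] <- 1
  data.frame(
    probe_id = rownames(fit$means),
    log2fc = log2fc,
    avg_expr = fit$avg_expr,
    t_mod = t_mod,
    p_raw = p_raw,
    p_adj = adjust_bh(p_raw),
    df_total = df_total,
    contrast = if (is.null(name)) NA_character_ else name,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR correction via [stats::p.adjust()], with input validation.
#'
#' @param p Raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significance gate: fold change and adjusted p
#'
#' A probe passes iff `|log2fc| >= log2(fold_cutoff)` AND
#' `p_adj <= alpha` (both boundaries inclusive). Direction is read from the
#' sign of `log2fc`.
#'
#' @param results A contrast result table from [test_contrast()].
#' @param fold_cutoff Linear fold-change cutoff (default 2).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return The passing subset with a `direction` column
#'   (`"induced"`/`"repressed"`).
#' @seealso [passes_gate()] for the logical vector over all probes.
#' @export
gate_significant <- function(results, fold_cutoff = 2, alpha = 0.05) {
  keep <- passes_gate(results, fold_cutoff, alpha)
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "induced", "repressed")
  rownames(out) <- NULL
  out
}

#' @rdname gate_significant
#' @export
passes_gate <- function(results, fold_cutoff = 2, alpha = 0.05) {
  if (!nrow(results)) stop("empty result table")
  abs(results$log2fc) >= log2(fold_cutoff) & results$p_adj <= alpha
}

#' Run the standard contrast battery at one time point
#'
#' Subsets the design to one time point of one cell line (non-CHX samples),
#' fits cell means per receptor x ligand, moderates variances, and tests
#' the unliganded, interaction and within-receptor T3 contrasts for both
#' receptors.
#'
#' @param mat Expression matrix.
#' @param design Matching design sheet.
#' @param time_hr Time point to analyse.
#' @param cell_line Optional cell-line filter.
#' @param d0_override Passed to [moderate_variances()].
#' @return Named list of contrast result tables:
#'   `unliganded_TRA`, `unliganded_TRB`, `interaction_TRA`,
#'   `interaction_TRB`, `t3_TRA`, `t3_TRB`.
#' @export
de_timepoint <- function(mat, design, time_hr, cell_line = NULL,
                         d0_override = NULL) {
  design <- align_design(mat, design)
  keep <- design$time_hr == time_hr & !design$chx
  if (!is.null(cell_line)) keep <- keep & design$cell_line == cell_line
  if (!any(keep)) stop("no samples at time ", time_hr)
  sub <- design[keep, , drop = FALSE]
  m <- mat[, sub$sample_id, drop = FALSE]
  fit <- fit_cell_means(m, sub)
  mod <- moderate_variances(fit$s2, fit$df, d0_override = d0_override)
  out <- list()
  for (rec in intersect(c("TRA", "TRB"), unique(sub$receptor))) {
    for (type in c("unliganded", "interaction", "t3_within")) {
      nm <- paste0(sub("_within", "", type), "_", rec)
      out[[nm]] <- test_contrast(fit, mod, make_contrast(type, rec), name = nm)
    }
  }
  out
}
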
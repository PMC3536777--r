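#' Null-simulation false discovery calibration
#'
#' Repeats an all-null simulation (every gene OO, no effects anywhere) and
#' measures the fraction of genes whose BH-adjusted interaction p-value
#' falls at or below `alpha`. Under a correct null model and BH control
#' this fraction averages well below `alpha`.
#'
#' @param n_sims Number of replicate null simulations.
#' @param n_genes Genes per simulation.
#' @param replicates Replicates per design cell.
#' @param alpha Adjusted-p threshold being calibrated.
#' @param seed Base seed; simulation i uses `seed + i`.
#' @return List: `mean_fraction`, `per_sim` (vector), `n_genes`, `n_sims`.
#' @export
benchmark_null_fdr <- function(n_sims = 20, n_genes = 5000, replicates = 3,
                               alpha = 0.05, seed = 1) {
  p <- stats::setNames(rep(0, 9), archetype_labels()); p["OO"] <- 1
  per_sim <- vapply(seq_len(n_sims), function(i) {
    cfg <- sim_config(n_genes = n_genes, archetype_proportions = p,
                      replicates = replicates,
                      times = c(3, 24),
                      kinetic_weights = rbind(TRA = c(1, 0.8), TRB = c(0.5, 1.2)),
                      seed = seed + i)
    eff <- draw_gene_effects(cfg)
    tc <- simulate_timecourse(eff, cfg)
    de <- de_timepoint(tc$matrix, tc$design, 3)
    mean(de$interaction_TRA$p_adj <= alpha)
  }, numeric(1))
  list(mean_fraction = mean(per_sim), per_sim = per_sim,
       n_genes = n_genes, n_sims = n_sims)
}

#' Archetype recovery on a calibrated cohort
#'
#' Simulates genes with log2 effects of exactly +/-1 on each active axis
#' (the fold scale of the archetype vectors themselves) at a given noise
#' level, runs the 3 h TRalpha contrasts, classifies patterns, and scores
#' the fraction of truly responsive (non-OO) genes whose generating
#' archetype is recovered. The TRalpha arm is used because its 3 h kinetic
#' weight is 1, so effects are transmitted unattenuated; the late-beta
#' subset is disabled for the same reason.
#'
#' @param n_genes Cohort size.
#' @param sigma Residual standard deviation (log2 units) for every gene.
#' @param seed Simulation seed.
#' @return List: `rate`, `n_responsive`, `n_recovered`.
#' @export
benchmark_pattern_recovery <- function(n_genes = 600, sigma = 0.1, seed = 1) {
  p <- stats::setNames(rep(1 / 9, 9), archetype_labels())
  cfg <- sim_config(n_genes = n_genes, archetype_proportions = p,
                    effect_meanlog = 0, effect_sdlog = 0,
                    noise_df0 = Inf, noise_scale = sigma^2,
                    late_beta_fraction = 0, seed = seed)
  eff <- draw_gene_effects(cfg)
  tc <- simulate_timecourse(eff, cfg)
  de <- de_timepoint(tc$matrix, tc$design, 3)
  cls <- classify_probe_set(de$unliganded_TRA, de$t3_TRA)
  truth <- eff[eff$archetype != "OO", c("probe_id", "archetype")]
  got <- cls$assignments$label[match(truth$probe_id, cls$assignments$probe_id)]
  n_rec <- sum(!is.na(got) & got == truth$archetype)
  list(rate = n_rec / nrow(truth), n_responsive = nrow(truth),
       n_recovered = n_rec)
}

#' Direct-target call agreement with generative truth
#'
#' Simulates the CHX arm at a given noise level, gates T3-responsive genes
#' with the standard fold/alpha gate on the within-receptor T3 contrast,
#' calls directness from the persistence ratio, and scores binary agreement
#' with the generator's direct flag. Calls of `direct` and `attenuated`
#' both count as direct: partial persistence indicates a response that
#' does not require new protein synthesis to occur, even if its magnitude
#' is reduced.
#'
#' @param sigma Residual sd (log2); use a tiny value for the noiseless
#'   limit.
#' @param n_genes Cohort size.
#' @param seed Simulation seed.
#' @return List: `agreement`, `n_called`.
#' @export
benchmark_directness <- function(sigma = 0.2, n_genes = 600, seed = 1) {
  cfg <- sim_config(n_genes = n_genes, noise_df0 = Inf,
                    noise_scale = sigma^2, chx_attenuation = 0,
                    late_beta_fraction = 0, seed = seed)
  eff <- draw_gene_effects(cfg)
  arm <- simulate_chx_arm(eff, cfg)
  de <- de_timepoint(arm$matrix, arm$design, cfg$times[1L])
  gated <- gate_significant(de$t3_TRA)
  calls <- call_direct_targets(arm$matrix, arm$design, "TRA",
                               probes = gated$probe_id)
  calls <- calls[!is.na(calls$call), , drop = FALSE]
  truth <- eff$direct[match(calls$probe_id, eff$probe_id)]
  ok <- !is.na(truth)
  agree <- (calls$call[ok] != "indirect") == truth[ok]
  list(agreement = mean(agree), n_called = sum(ok))
}

#' EC50 recovery and subtype-shift detection
#'
#' Two sub-experiments: (1) a cohort of induced genes with EC50s drawn
#' log-uniformly over the configured range is fit per gene (TRalpha arm)
#' and the median absolute log10 estimation error reported; (2) a small
#' set of genes built with a fixed TRbeta/TRalpha EC50 ratio is fit for
#' both receptors with bootstrap intervals and the recovered ratio and
#' shift flags reported.
#'
#' @param n_genes Cohort size for the recovery sweep.
#' @param sigma Residual sd (log2 units).
#' @param shift_ratio Generative EC50 ratio for the shift experiment.
#' @param seed Simulation seed.
#' @return List: `median_log10_error`, `n_fit`, `shift_ratio_est`
#'   (median recovered ratio), `shift_flagged_fraction`.
#' @export
benchmark_ec50 <- function(n_genes = 50, sigma = 0.15, shift_ratio = 10,
                           seed = 1) {
  p <- stats::setNames(rep(0, 9), archetype_labels()); p["OI"] <- 1
  cfg <- sim_config(n_genes = n_genes, archetype_proportions = p,
                    effect_meanlog = log(1.8), effect_sdlog = 0.2,
                    noise_df0 = Inf, noise_scale = sigma^2, seed = seed)
  eff <- draw_gene_effects(cfg)
  ds <- simulate_dose_series(eff, cfg)
  sub <- ds$design[ds$design$receptor == "TRA", ]
  est <- vapply(eff$probe_id, function(pid)
    fit_hill(sub$dose_nM, ds$matrix[pid, sub$sample_id], n_boot = 0)$ec50,
    numeric(1))
  err <- stats::median(abs(log10(est / eff$ec50_TRA)))

  eff2 <- eff[1:3, , drop = FALSE]
  eff2$ec50_TRA <- 1
  eff2$ec50_TRB <- shift_ratio
  eff2$l_TRA <- eff2$l_TRB <- 2
  cfg2 <- sim_config(n_genes = 3, noise_df0 = Inf, noise_scale = sigma^2,
                     seed = seed + 1)
  ds2 <- simulate_dose_series(eff2, cfg2)
  tab <- fit_dose_response(ds2$matrix, ds2$design, n_boot = 100,
                           seed = seed + 2)
  list(median_log10_error = err, n_fit = n_genes,
       shift_ratio_est = stats::median(tab$ratio),
       shift_flagged_fraction = mean(tab$shifted))
}

#' Kinetic-asymmetry reproduction under default weights
#'
#' Simulates the default time-course (alpha-early / beta-late kinetic
#' weights, late-beta subset included) and reports the gate-passing counts
#' per receptor at the first and last time points plus the fold-fold
#' total-least-squares slope at the last time point.
#'
#' @param n_genes Cohort size.
#' @param seed Simulation seed.
#' @return List: `n_alpha_early`, `n_beta_early`, `n_alpha_late`,
#'   `n_beta_late`, `slope_late` plus the two concordance rows.
#' @export
benchmark_kinetics <- function(n_genes = 1500, seed = 1) {
  cfg <- sim_config(n_genes = n_genes, seed = seed)
  eff <- draw_gene_effects(cfg)
  tc <- simulate_timecourse(eff, cfg)
  t1 <- cfg$times[1L]; tL <- cfg$times[length(cfg$times)]
  de1 <- de_timepoint(tc$matrix, tc$design, t1)
  deL <- de_timepoint(tc$matrix, tc$design, tL)
  cc1 <- concordance(de1$t3_TRA, de1$t3_TRB, time_hr = t1)
  ccL <- concordance(deL$t3_TRA, deL$t3_TRB, time_hr = tL)
  list(n_alpha_early = cc1$n_alpha, n_beta_early = cc1$n_beta,
       n_alpha_late = ccL$n_alpha, n_beta_late = ccL$n_beta,
       slope_late = ccL$slope, early = cc1, late = ccL)
}

#' Moderated versus ordinary t power at matched empirical FDR
#'
#' Benchmarks the variance-moderated test against the unmoderated t on one
#' seeded two-condition experiment with 2 replicates per condition: a
#' fraction of genes carry a true log2 effect, both tests are run on the
#' same data, and each method's power is read off at the largest rejection
#' set whose ground-truth empirical FDR stays at or below `fdr_target`.
#'
#' @param n_genes Number of genes.
#' @param frac_de Fraction of genes with a true effect.
#' @param lfc True absolute log2 effect size.
#' @param replicates Replicates per condition.
#' @param fdr_target Matched empirical FDR level.
#' @param seed Simulation seed.
#' @return List: `power_moderated`, `power_ordinary`, `d0_estimate`.
#' @export
benchmark_moderation <- function(n_genes = 2000, frac_de = 0.1, lfc = 1,
                                 replicates = 2, fdr_target = 0.05,
                                 seed = 1) {
  set.seed(seed)
  sig2 <- 4 * 0.04 / stats::rchisq(n_genes, 4)
  is_de <- stats::runif(n_genes) < frac_de
  beta <- ifelse(is_de, sample(c(-lfc, lfc), n_genes, replace = TRUE), 0)
  des <- validate_design(data.frame(
    sample_id = sprintf("s%d", seq_len(2 * replicates)),
    cell_line = "HepG2", receptor = "TRA",
    ligand = rep(c("vehicle", "T3"), each = replicates),
    dose_nM = rep(c(0, 100), each = replicates),
    time_hr = 3, chx = FALSE, replicate = rep(seq_len(replicates), 2),
    stringsAsFactors = FALSE))
  mu <- outer(beta, c(rep(0, replicates), rep(1, replicates)))
  mat <- 8 + mu + matrix(stats::rnorm(n_genes * 2 * replicates),
                         n_genes) * sqrt(sig2)
  dimnames(mat) <- list(sprintf("g%05d", seq_len(n_genes)), des$sample_id)
  fit <- fit_cell_means(mat, des)
  w <- make_contrast("t3_within", "TRA")
  mod <- moderate_variances(fit$s2, fit$df)
  ord <- moderate_variances(fit$s2, fit$df, d0_override = 0)
  p_mod <- test_contrast(fit, mod, w)$p_raw
  p_ord <- test_contrast(fit, ord, w)$p_raw
  power_at_fdr <- function(p) {
    o <- order(p)
    fp <- cumsum(!is_de[o]); tp <- cumsum(is_de[o])
    efdr <- fp / seq_along(p)
    keep <- which(efdr <= fdr_target)
    if (!length(keep)) return(0)
    tp[max(keep)] / sum(is_de)
  }
  list(power_moderated = power_at_fdr(p_mod),
       power_ordinary = power_at_fdr(p_ord),
       d0_estimate = mod$d0)
}
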
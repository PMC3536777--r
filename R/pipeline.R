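#' Run the full analysis pipeline on a simulated cohort
#'
#' Ties every stage together: draw gene effects, simulate the time-course,
#' CHX and dose arms, quantile-normalize, run the contrast battery at each
#' time point, classify regulation patterns at the first time point, call
#' direct targets from the CHX arm, summarise subtype concordance and
#' kinetic classes, and fit EC50s for a subset of responsive genes. All
#' stage outputs are returned and, when `out_dir` is given, written as
#' tab-delimited tables with a `#` header recording package version and
#' seed so a rerun with the same config reproduces them.
#'
#' @param config A [sim_config()] (its `seed` drives all randomness).
#' @param out_dir Optional output directory (created if missing).
#' @param fold_cutoff,alpha Significance gate.
#' @param gate_on Contrast family used for gating time-course responses:
#'   `"interaction"` (default) or `"t3"` (within-receptor T3 effect).
#' @param eligibility Pattern-classifier eligibility mode.
#' @param chx_baseline Baseline mode for the persistence ratio.
#' @param n_ec50_genes Number of gate-passing genes carried into the EC50
#'   stage (kept small; Hill fitting with bootstrap dominates runtime).
#' @param n_boot Bootstrap resamples for EC50 intervals.
#' @return List with elements `effects`, `timecourse`, `chx`, `dose`,
#'   `de` (per-time contrast tables), `patterns`, `pattern_overlap`,
#'   `direct_calls`, `concordance`, `kinetics`, `overlaps`, `ec50`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(seed = 1), out_dir = NULL,
                         fold_cutoff = 2, alpha = 0.05,
                         gate_on = c("interaction", "t3"),
                         eligibility = "either",
                         chx_baseline = "chx",
                         n_ec50_genes = 10, n_boot = 100) {
  gate_on <- match.arg(gate_on)
  effects <- draw_gene_effects(config)
  tc <- simulate_timecourse(effects, config)
  chx <- simulate_chx_arm(effects, config)
  dose <- simulate_dose_series(effects, config)
  tc$matrix <- quantile_normalize(tc$matrix)

  de <- lapply(stats::setNames(config$times, config$times), function(t_hr)
    de_timepoint(tc$matrix, tc$design, t_hr))

  t1 <- as.character(config$times[1L])
  patterns <- lapply(c(TRA = "TRA", TRB = "TRB"), function(rec)
    classify_probe_set(de[[t1]][[paste0("unliganded_", rec)]],
                       de[[t1]][[paste0("t3_", rec)]],
                       alpha = alpha, eligibility = eligibility))
  pat_overlap <- pattern_overlap(patterns$TRA$assignments,
                                 patterns$TRB$assignments)

  gate_name <- function(rec) paste0(if (gate_on == "t3") "t3" else "interaction",
                                    "_", rec)
  chx_de <- lapply(c(TRA = "TRA", TRB = "TRB"), function(rec) {
    sub <- chx$design[chx$design$receptor %in% c("parental", rec) &
                        !chx$design$chx, , drop = FALSE]
    de_timepoint(chx$matrix[, sub$sample_id], sub,
                 config$times[1L])[[gate_name(rec)]]
  })
  direct_calls <- lapply(c(TRA = "TRA", TRB = "TRB"), function(rec) {
    gated <- gate_significant(chx_de[[rec]], fold_cutoff, alpha)
    call_direct_targets(chx$matrix, chx$design, rec,
                        probes = gated$probe_id, baseline = chx_baseline)
  })

  conc <- do.call(rbind, lapply(config$times, function(t_hr) {
    d <- de[[as.character(t_hr)]]
    concordance(d[[gate_name("TRA")]], d[[gate_name("TRB")]],
                fold_cutoff, alpha, time_hr = t_hr)
  }))
  kin <- kinetic_classify(
    lapply(de, `[[`, gate_name("TRA")),
    lapply(de, `[[`, gate_name("TRB")),
    fold_cutoff, alpha)
  t_last <- as.character(config$times[length(config$times)])
  ov <- overlap_table(list(
    TRA = gate_significant(de[[t_last]][[gate_name("TRA")]], fold_cutoff, alpha),
    TRB = gate_significant(de[[t_last]][[gate_name("TRB")]], fold_cutoff, alpha)))

  gated_last <- gate_significant(de[[t_last]][[gate_name("TRB")]],
                                 fold_cutoff, alpha)
  ec50_probes <- utils::head(gated_last$probe_id[order(-abs(gated_last$log2fc))],
                             n_ec50_genes)
  ec50 <- if (length(ec50_probes)) {
    fit_dose_response(dose$matrix, dose$design, ec50_probes,
                      n_boot = n_boot,
                      seed = if (!is.null(config$seed)) config$seed + 4L else NULL)
  } else NULL

  manifest <- list(package_version = as.character(utils::packageVersion("trtargets")),
                   seed = config$seed, n_genes = config$n_genes,
                   times = config$times, fold_cutoff = fold_cutoff,
                   alpha = alpha, gate_on = gate_on)
  out <- list(effects = effects, timecourse = tc, chx = chx, dose = dose,
              de = de, patterns = patterns, pattern_overlap = pat_overlap,
              direct_calls = direct_calls, concordance = conc,
              kinetics = kin, overlaps = ov, ec50 = ec50,
              manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir, manifest)
  out
}

.write_pipeline_outputs <- function(out, out_dir, manifest) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# trtargets %s | seed=%s",
                 manifest$package_version,
                 if (is.null(manifest$seed)) "none" else manifest$seed)
  wt <- function(df, name) {
    con <- file(file.path(out_dir, name), "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_expression(out$timecourse$matrix,
                   file.path(out_dir, "timecourse_matrix.tsv"), comment = hdr)
  write_design(out$timecourse$design,
               file.path(out_dir, "timecourse_design.tsv"))
  write_gene_effects(out$effects, file.path(out_dir, "ground_truth.tsv"))
  for (t in names(out$de))
    for (cn in names(out$de[[t]]))
      wt(out$de[[t]][[cn]], sprintf("de_%sh_%s.tsv", t, cn))
  wt(out$pattern_overlap, "pattern_table.tsv")
  for (rec in names(out$patterns))
    wt(out$patterns[[rec]]$assignments, sprintf("patterns_%s.tsv", rec))
  for (rec in names(out$direct_calls))
    wt(out$direct_calls[[rec]], sprintf("direct_calls_%s.tsv", rec))
  wt(out$concordance, "concordance.tsv")
  wt(out$kinetics, "kinetic_classes.tsv")
  wt(out$overlaps$counts, "overlap_counts.tsv")
  if (!is.null(out$ec50)) wt(out$ec50, "ec50_table.tsv")
  writeLines(c(hdr, paste0(names(manifest), "=",
                           sapply(manifest, paste, collapse = ","))),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
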
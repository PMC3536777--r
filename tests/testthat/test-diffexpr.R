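test_that("cell means and pooled variance match hand arithmetic", {
  mat <- matrix(c(0, 2, 4, 6), 1, 4,
                dimnames = list("g1", sprintf("s%02d", 1:4)))
  des <- toy_design(rep("TRA", 4), rep(c("vehicle", "T3"), each = 2))
  fit <- fit_cell_means(mat, des)
  expect_equal(unname(fit$means[1, ]), c(1, 5))
  expect_equal(unname(fit$s2), 2)
  expect_equal(fit$df, 2)
})

test_that("cell means equal an explicit one-way ANOVA decomposition", {
  set.seed(31)
  des <- toy_design(rep(c("parental", "TRA", "TRB"), each = 6),
                    rep(rep(c("vehicle", "T3"), each = 3), 3))
  mat <- matrix(rnorm(50 * 18, 8), 50, 18,
                dimnames = list(sprintf("g%02d", 1:50), des$sample_id))
  fit <- fit_cell_means(mat, des)
  groups <- paste(des$receptor, des$ligand, sep = ".")
  for (g in c(1, 17, 50)) {
    o <- oracle_pooled_var(mat[g, ], groups)
    expect_equal(sort(unname(fit$means[g, ])), sort(unname(o$means)),
                 tolerance = 1e-12)
    expect_equal(unname(fit$s2[g]), o$s2, tolerance = 1e-12)
    expect_equal(fit$df, o$df)
  }
  expect_error(fit_cell_means(mat[, c(1, 4, 7, 10, 13, 16)],
                              des[c(1, 4, 7, 10, 13, 16), ]),
               "singleton")
})

test_that("variance moderation handles the degenerate and no-shrinkage limits", {
  s2 <- rep(0.3, 100)
  mod <- moderate_variances(s2, df = 4)
  expect_equal(mod$s0_2, 0.3)
  expect_equal(mod$s2_post, s2)
  expect_true(is.infinite(mod$d0))

  set.seed(1)
  s2r <- 0.1 * rchisq(100, 4) / 4
  mod0 <- moderate_variances(s2r, df = 4, d0_override = 0)
  expect_identical(mod0$s2_post, s2r)
  expect_warning(moderate_variances(s2r[1:5], df = 4), "moderation disabled")
})

test_that("moderation recovers the generating variance prior", {
  set.seed(41)
  n <- 5000; d0_true <- 4; s0_true <- 0.04; df <- 4
  sig2 <- d0_true * s0_true / rchisq(n, d0_true)
  s2 <- sig2 * rchisq(n, df) / df
  mod <- moderate_variances(s2, df)
  expect_gt(mod$d0, 2.5); expect_lt(mod$d0, 6.5)
  expect_lt(abs(mod$s0_2 - s0_true) / s0_true, 0.25)
  expect_true(all(diff(mod$s2_post[order(s2)]) >= -1e-12))  # monotone in s2
})

test_that("moderation agrees with the limma hierarchy on the same input", {
  skip_if_not_installed("limma")
  set.seed(17)
  s2 <- (4 * 0.04 / rchisq(3000, 4)) * rchisq(3000, 6) / 6
  mod <- moderate_variances(s2, 6)
  sq <- limma::squeezeVar(s2, 6)
  expect_equal(mod$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(mod$s0_2, sq$var.prior, tolerance = 0.05)
  expect_equal(mod$s2_post, sq$var.post, tolerance = 0.02)
})

test_that("contrasts recover generative effects in the noiseless limit", {
  cfg <- sim_config(n_genes = 3, seed = 2,
                    kinetic_weights = rbind(TRA = c(1, 1, 1), TRB = c(1, 1, 1)))
  eff <- manual_effects(c("RO", "OI", "OO"), u = c(-1, 0, 0), l = c(0, 2, 0),
                        sigma = 1e-9)
  tc <- simulate_timecourse(eff, cfg)
  # 3 genes: the moderation fallback warning is expected here
  de <- suppressWarnings(de_timepoint(tc$matrix, tc$design, 3))
  expect_equal(de$unliganded_TRA$log2fc, c(-1, 0, 0), tolerance = 1e-6)
  expect_equal(de$interaction_TRB$log2fc, c(0, 2, 0), tolerance = 1e-6)
  expect_equal(de$t3_TRA$log2fc, c(0, 2, 0), tolerance = 1e-6)
})

test_that("the interaction contrast nulls out receptor-independent T3 response", {
  # same T3 delta in parental and receptor cells -> interaction = 0
  des <- toy_design(rep(c("parental", "TRA"), each = 4),
                    rep(rep(c("vehicle", "T3"), each = 2), 2))
  base <- c(5, 5, 6.5, 6.5)  # T3 adds 1.5 in both lines
  mat <- rbind(g1 = c(base, base + 0.3), g2 = rnorm(8, 8, 0.01))
  colnames(mat) <- des$sample_id
  fit <- fit_cell_means(mat, des)
  mod <- moderate_variances(fit$s2, fit$df, d0_override = 0)
  res <- test_contrast(fit, mod, make_contrast("interaction", "TRA"))
  expect_equal(res$log2fc[1], 0, tolerance = 1e-9)
  t3 <- test_contrast(fit, mod, make_contrast("t3_within", "TRA"))
  expect_equal(t3$log2fc[1], 1.5, tolerance = 1e-9)
  expect_error(test_contrast(fit, mod, setNames(c(1, -1), c("TRB.T3", "TRB.vehicle"))),
               "TRB")
})

test_that("raw p-values are uniform under the null", {
  p <- setNames(rep(0, 9), archetype_labels()); p["OO"] <- 1
  cfg <- sim_config(n_genes = 5000, archetype_proportions = p, seed = 13)
  eff <- draw_gene_effects(cfg)
  tc <- simulate_timecourse(eff, cfg)
  de <- de_timepoint(tc$matrix, tc$design, 6)
  expect_gt(ks.test(de$interaction_TRA$p_raw, "punif")$p.value, 0.01)
  expect_gt(ks.test(de$unliganded_TRB$p_raw, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
})

test_that("the significance gate is inclusive at both printed boundaries", {
  res <- data.frame(probe_id = c("a", "b", "c", "d"),
                    log2fc = c(1.0, 0.99, -1.2, 2),
                    p_adj = c(0.05, 0.001, 0.01, 0.6))
  g <- gate_significant(res)
  expect_setequal(g$probe_id, c("a", "c"))
  expect_equal(g$direction[g$probe_id == "c"], "repressed")
  # predicate oracle on a random table
  set.seed(8)
  rt <- data.frame(probe_id = paste0("p", 1:500),
                   log2fc = rnorm(500, 0, 1.2), p_adj = runif(500))
  expect_equal(passes_gate(rt),
               abs(rt$log2fc) >= 1 & rt$p_adj <= 0.05)
})

test_that("strong effects at moderate noise are detected almost always", {
  # 4-fold effects, sigma 0.3, 3 replicates: power sanity
  cfg <- sim_config(n_genes = 300, noise_df0 = Inf, noise_scale = 0.09,
                    effect_meanlog = log(2), effect_sdlog = 0, seed = 55,
                    late_beta_fraction = 0,
                    archetype_proportions = setNames(
                      c(0, 0, 0, 0, 0.5, 0.5, 0, 0, 0), archetype_labels()))
  eff <- draw_gene_effects(cfg)
  tc <- simulate_timecourse(eff, cfg)
  de <- de_timepoint(tc$matrix, tc$design, 3)
  resp <- eff$archetype == "OI"
  rate <- mean(passes_gate(de$t3_TRA)[resp])
  expect_gte(rate, 0.95)
})

test_that("moderated tests agree with limma end to end", {
  skip_if_not_installed("limma")
  cfg <- sim_config(n_genes = 200, seed = 77)
  eff <- draw_gene_effects(cfg)
  tc <- simulate_timecourse(eff, cfg)
  sub <- tc$design[tc$design$time_hr == 3, ]
  m <- tc$matrix[, sub$sample_id]
  de <- de_timepoint(tc$matrix, tc$design, 3)

  grp <- factor(paste(sub$receptor, sub$ligand, sep = "."))
  design <- model.matrix(~ 0 + grp)
  colnames(design) <- levels(grp)
  fit <- limma::lmFit(m, design)
  cm <- limma::makeContrasts(
    inter = (TRA.T3 - TRA.vehicle) - (parental.T3 - parental.vehicle),
    levels = design)
  eb <- limma::eBayes(limma::contrasts.fit(fit, cm))
  expect_equal(de$interaction_TRA$log2fc, unname(eb$coefficients[, 1]),
               tolerance = 1e-8)
  expect_equal(de$interaction_TRA$t_mod, unname(eb$t[, 1]), tolerance = 0.02)
  expect_equal(de$interaction_TRA$p_raw, unname(eb$p.value[, 1]),
               tolerance = 0.02)
})
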
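test_that("config validation enforces invariants", {
  expect_error(sim_config(replicates = 1), "replicates")
  p <- default_archetype_proportions()
  expect_equal(sum(p), 1)
  p_bad <- p; p_bad["OO"] <- p_bad["OO"] + 0.2
  expect_error(sim_config(archetype_proportions = p_bad), "sum to 1")
  expect_error(sim_config(direct_fraction = 1.2), "\\[0, 1\\]")
})

test_that("an all-OO configuration yields zero effects everywhere", {
  p <- setNames(rep(0, 9), archetype_labels()); p["OO"] <- 1
  eff <- draw_gene_effects(sim_config(n_genes = 50, archetype_proportions = p,
                                      seed = 1))
  expect_true(all(eff$u_TRA == 0) && all(eff$u_TRB == 0))
  expect_true(all(eff$l_TRA == 0) && all(eff$l_TRB == 0))
  expect_true(all(is.na(eff$direct)))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 40, seed = 99)
  e1 <- draw_gene_effects(cfg); e2 <- draw_gene_effects(cfg)
  expect_identical(e1, e2)
  expect_identical(simulate_timecourse(e1, cfg)$matrix,
                   simulate_timecourse(e2, cfg)$matrix)
  expect_identical(simulate_chx_arm(e1, cfg)$matrix,
                   simulate_chx_arm(e2, cfg)$matrix)
  expect_identical(simulate_dose_series(e1, cfg)$matrix,
                   simulate_dose_series(e2, cfg)$matrix)
})

test_that("archetype frequencies converge to their proportions", {
  p <- setNames(rep(1 / 9, 9), archetype_labels())
  eff <- draw_gene_effects(sim_config(n_genes = 10000,
                                      archetype_proportions = p, seed = 5))
  freq <- table(factor(eff$archetype, levels = archetype_labels())) / 10000
  se <- sqrt((1 / 9) * (8 / 9) / 10000)
  expect_true(all(abs(freq - 1 / 9) < 3 * se))
})

test_that("archetype letters fix the signs of the generated effects", {
  eff <- draw_gene_effects(sim_config(n_genes = 2000, seed = 3))
  su <- c(R = -1, O = 0, I = 1)[substr(eff$archetype, 1, 1)]
  sl <- c(R = -1, O = 0, I = 1)[substr(eff$archetype, 2, 2)]
  expect_equal(sign(eff$u_TRA), unname(su))
  expect_equal(sign(eff$l_TRB), unname(sl))
  expect_true(all(eff$sigma > 0) && all(eff$ec50_TRA > 0) && all(eff$hill > 0))
})

test_that("the time-course generative model has the stated cell means", {
  cfg <- sim_config(n_genes = 1,
                    kinetic_weights = rbind(TRA = c(1, 1, 1), TRB = c(1, 1, 1)),
                    seed = 1)
  eff <- manual_effects("RO", u = -1, l = 1, baseline = 8, sigma = 1e-9)
  tc <- simulate_timecourse(eff, cfg)
  d <- tc$design
  col_mean <- function(rec, lig, t)
    mean(tc$matrix[1, d$sample_id[d$receptor == rec & d$ligand == lig &
                                    d$time_hr == t]])
  expect_equal(col_mean("TRA", "vehicle", 3), 7, tolerance = 1e-6)
  expect_equal(col_mean("TRA", "T3", 3), 8, tolerance = 1e-6)
  expect_equal(col_mean("parental", "vehicle", 3), 8, tolerance = 1e-6)
  expect_equal(col_mean("parental", "T3", 24), 8, tolerance = 1e-6)
})

test_that("per-gene sample variances are consistent with the generating prior", {
  cfg <- sim_config(n_genes = 1000, seed = 21)
  eff <- draw_gene_effects(cfg)
  tc <- simulate_timecourse(eff, cfg)
  sub <- tc$design[tc$design$time_hr == 3, ]
  fit <- fit_cell_means(tc$matrix[, sub$sample_id], sub)
  # Reference draws from the same hierarchy: sigma2 ~ scaled-inv-chisq(4, .04),
  # s2 | sigma2 ~ sigma2 * chisq(df) / df.
  set.seed(22)
  sig2 <- cfg$noise_df0 * cfg$noise_scale / rchisq(20000, cfg$noise_df0)
  ref <- sig2 * rchisq(20000, fit$df) / fit$df
  expect_gt(suppressWarnings(ks.test(fit$s2, ref))$p.value, 0.01)
})

test_that("CHX arm encodes direct and indirect behaviour in expectation", {
  cfg <- sim_config(n_genes = 2, chx_attenuation = 0, seed = 2,
                    kinetic_weights = rbind(TRA = c(1, 1, 1), TRB = c(1, 1, 1)))
  eff <- manual_effects(c("OI", "OI"), u = 0, l = c(1.5, 1.5),
                        direct = c(TRUE, FALSE), sigma = 1e-9)
  arm <- simulate_chx_arm(eff, cfg)
  d <- arm$design
  mn <- function(g, rec, lig, chx)
    mean(arm$matrix[g, d$sample_id[d$receptor == rec & d$ligand == lig &
                                     d$chx == chx]])
  # direct gene: T3 effect identical with and without CHX
  expect_equal(mn(1, "TRA", "T3", TRUE) - mn(1, "TRA", "vehicle", TRUE),
               mn(1, "TRA", "T3", FALSE) - mn(1, "TRA", "vehicle", FALSE),
               tolerance = 1e-6)
  # indirect gene with attenuation 0: T3+CHX collapses onto CHX-alone
  expect_equal(mn(2, "TRB", "T3", TRUE), mn(2, "TRB", "vehicle", TRUE),
               tolerance = 1e-6)
  # downstream persistence ratio in the noiseless limit
  pr <- persistence_ratio(arm$matrix, arm$design, "TRA")
  expect_equal(pr$persistence, c(1, 0), tolerance = 1e-5)
})

test_that("dose-series expectations follow the Hill equation exactly", {
  grid <- c(0, 0.01, 0.1, 0.3, 1, 3, 10, 30, 100)
  cfg <- sim_config(n_genes = 1, dose_grid = grid, replicates = 2, seed = 4)
  eff <- manual_effects("OI", u = 0, l = 2, ec50_a = 1, hill = 1,
                        baseline = 5, sigma = 1e-9)
  ds <- simulate_dose_series(eff, cfg)
  d <- ds$design
  for (dose in grid) {
    ids <- d$sample_id[d$receptor == "TRA" & d$dose_nM == dose]
    expected <- 5 + 2 * if (dose == 0) 0 else dose / (dose + 1)
    expect_equal(mean(ds$matrix[1, ids]), expected, tolerance = 1e-6)
  }
  # Hill midpoint: at d = ec50 the induction is half of l_effect
  mid <- d$sample_id[d$receptor == "TRA" & d$dose_nM == 1]
  expect_equal(mean(ds$matrix[1, mid]), 5 + 1, tolerance = 1e-6)
})

test_that("late-beta genes get the promised kinetic-weight gap at 24 h", {
  cfg <- sim_config(n_genes = 2000, late_beta_fraction = 0.3, seed = 12)
  eff <- draw_gene_effects(cfg)
  lb <- eff$late_beta & !is.na(eff$direct)
  expect_gt(sum(lb), 10)
  w_a <- trtargets:::.kinetic_weight(eff, cfg, "TRA", 3L)
  w_b <- trtargets:::.kinetic_weight(eff, cfg, "TRB", 3L)
  expect_true(all(w_b[lb] / w_a[lb] >= cfg$late_beta_factor))
})

test_that("ground-truth tables round-trip through text files", {
  eff <- draw_gene_effects(sim_config(n_genes = 30, seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_effects(eff, path)
  back <- read_gene_effects(path)
  expect_equal(back$probe_id, eff$probe_id)
  expect_equal(back$archetype, eff$archetype)
  expect_equal(back$sigma, eff$sigma, tolerance = 1e-10)
  expect_equal(back$direct, eff$direct)
})
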
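fake_results <- function(probe_id, log2fc, p_adj = 0.01) {
  data.frame(probe_id = probe_id, log2fc = log2fc, p_adj = p_adj,
             stringsAsFactors = FALSE)
}

test_that("identical result tables give perfect concordance", {
  set.seed(5)
  de <- fake_results(paste0("p", 1:50), rnorm(50, 0, 1.5), runif(50))
  cc <- concordance(de, de)
  expect_equal(cc$pearson_r, 1)
  expect_equal(cc$slope, 1, tolerance = 1e-10)
  expect_equal(cc$n_overlap, cc$n_alpha)
  expect_equal(cc$n_beta, cc$n_alpha)
  expect_true(cc$n_overlap <= min(cc$n_alpha, cc$n_beta))
})

test_that("a pure scaling of effects appears as the TLS slope", {
  set.seed(6)
  deA <- fake_results(paste0("p", 1:80), rnorm(80, 0, 1.4), 0.001)
  deB <- deA; deB$log2fc <- 1.5 * deA$log2fc
  cc <- concordance(deA, deB)
  expect_equal(cc$slope, 1.5, tolerance = 1e-10)
  expect_equal(cc$pearson_r, 1, tolerance = 1e-12)
})

test_that("an empty union is flagged undefined", {
  de0 <- fake_results(paste0("p", 1:10), rep(0.1, 10), 0.9)
  cc <- concordance(de0, de0)
  expect_true(cc$undefined)
  expect_equal(cc$n_union, 0L)
  expect_true(is.na(cc$pearson_r))
})

test_that("kinetic classes follow the decision rules on crafted cases", {
  probes <- c("early", "late_beta", "both3", "neverA")
  mk <- function(lfc, padj) fake_results(probes, lfc, padj)
  resA <- list(
    `3` = mk(c(1.5, 0.3, 1.2, 0.1), c(0.01, 0.9, 0.01, 0.9)),
    `6` = mk(c(1.5, 0.3, 1.2, 0.1), c(0.01, 0.9, 0.01, 0.9)),
    `24` = mk(c(1.4, 0.9, 1.2, 0.1), c(0.01, 0.9, 0.01, 0.9)))
  resB <- list(
    `3` = mk(c(0.4, 0.3, 1.1, 0.2), c(0.5, 0.9, 0.01, 0.8)),
    `6` = mk(c(0.8, 0.5, 1.1, 0.2), c(0.2, 0.7, 0.01, 0.8)),
    `24` = mk(c(1.3, 2.4, 1.3, 1.4), c(0.01, 0.01, 0.01, 0.01)))
  kc <- kinetic_classify(resA, resB)
  cls <- setNames(kc$class, kc$probe_id)
  expect_equal(unname(cls["early"]), "alpha_early")     # alpha at 3 h, beta only at 24 h
  expect_equal(unname(cls["late_beta"]), "beta_late")   # 2.4 vs 0.9 at 24 h
  expect_equal(unname(cls["both3"]), "concordant")      # same first time, ratio < 2
  expect_equal(unname(cls["neverA"]), "beta_late")      # beta-only late responder
  expect_equal(kc$earliest_pass_alpha[kc$probe_id == "early"], 3)
  expect_true(is.na(kc$earliest_pass_alpha[kc$probe_id == "neverA"]))
})

test_that("default kinetics produce the early-alpha / late-beta asymmetry", {
  cfg <- sim_config(n_genes = 800, seed = 42)
  eff <- draw_gene_effects(cfg)
  tc <- simulate_timecourse(eff, cfg)
  de3 <- de_timepoint(tc$matrix, tc$design, 3)
  de24 <- de_timepoint(tc$matrix, tc$design, 24)
  cc3 <- concordance(de3$t3_TRA, de3$t3_TRB, time_hr = 3)
  cc24 <- concordance(de24$t3_TRA, de24$t3_TRB, time_hr = 24)
  expect_gt(cc3$n_alpha, cc3$n_beta)
  expect_gt(cc24$n_beta, cc24$n_alpha)
  expect_gt(cc24$slope, 1)
})

test_that("recovered beta_late fraction tracks the generator setting", {
  cfg <- sim_config(n_genes = 600, late_beta_fraction = 0.1,
                    noise_df0 = Inf, noise_scale = 0.01,
                    effect_meanlog = log(1.5), effect_sdlog = 0, seed = 9)
  eff <- draw_gene_effects(cfg)
  tc <- simulate_timecourse(eff, cfg)
  de <- lapply(setNames(cfg$times, cfg$times), function(t)
    de_timepoint(tc$matrix, tc$design, t))
  kc <- kinetic_classify(lapply(de, `[[`, "t3_TRA"),
                         lapply(de, `[[`, "t3_TRB"))
  resp <- eff$probe_id[!is.na(eff$direct)]
  got <- mean(kc$class[kc$probe_id %in% resp] == "beta_late")
  n <- sum(kc$probe_id %in% resp)
  expect_lt(abs(got - 0.1), 3 * sqrt(0.1 * 0.9 / n) + 0.02)
})

test_that("overlap counts equal brute-force set intersections", {
  a <- fake_results(c("a", "b", "c"), c(1.2, 1.5, -1.3))
  a$direction <- ifelse(a$log2fc > 0, "induced", "repressed")
  b <- fake_results(c("b", "c", "d"), c(1.4, -1.2, -2))
  b$direction <- ifelse(b$log2fc > 0, "induced", "repressed")
  ov <- overlap_table(list(A = a, B = b))
  cnt <- ov$counts
  expect_equal(cnt$induced[cnt$combo == "A&B"], 1)   # b
  expect_equal(cnt$repressed[cnt$combo == "A&B"], 1) # c
  expect_equal(cnt$induced[cnt$combo == "A"] + cnt$repressed[cnt$combo == "A"], 3)
  expect_length(ov$discordant, 0)

  # identical sets overlap at full size
  ov2 <- overlap_table(list(X = a, Y = a))
  expect_equal(sum(ov2$counts[ov2$counts$combo == "X&Y", c("induced", "repressed")]), 3)

  # random sets against a brute-force oracle
  set.seed(15)
  for (i in 1:5) {
    ids1 <- sample(letters, 10); ids2 <- sample(letters, 12)
    s1 <- fake_results(ids1, abs(rnorm(10)) + 1.1)
    s1$direction <- "induced"
    s2 <- fake_results(ids2, abs(rnorm(12)) + 1.1)
    s2$direction <- "induced"
    ov3 <- overlap_table(list(P = s1, Q = s2))
    expect_equal(ov3$counts$induced[ov3$counts$combo == "P&Q"],
                 length(intersect(ids1, ids2)))
    # inclusion-exclusion: |P| + |Q| - |P&Q| = |P u Q|
    cn <- ov3$counts
    expect_equal(cn$induced[cn$combo == "P"] + cn$induced[cn$combo == "Q"] -
                   cn$induced[cn$combo == "P&Q"],
                 length(union(ids1, ids2)))
  }
})

test_that("direction-discordant probes are excluded and reported", {
  a <- data.frame(probe_id = c("x", "y"), direction = c("induced", "induced"))
  b <- data.frame(probe_id = c("x", "y"), direction = c("repressed", "induced"))
  ov <- overlap_table(list(A = a, B = b))
  expect_equal(ov$discordant, "x")
  expect_equal(ov$counts$induced[ov$counts$combo == "A&B"], 1)
})

test_that("pattern overlaps match per-label brute force", {
  asgA <- data.frame(probe_id = paste0("p", 1:6),
                     label = c("RO", "RO", "IO", "II", "RR", "OI"))
  asgB <- data.frame(probe_id = paste0("p", 1:6),
                     label = c("RO", "IO", "IO", "II", "RO", "OI"))
  po <- pattern_overlap(asgA, asgB)
  expect_equal(po$overlap[po$label == "RO"], 1)
  expect_equal(po$overlap[po$label == "IO"], 1)
  expect_equal(po$overlap[po$label == "II"], 1)
  expect_equal(po$n_alpha[po$label == "RO"], 2)
  expect_equal(po$n_beta[po$label == "RO"], 2)
  # identical assignments: overlap equals per-label count
  po2 <- pattern_overlap(asgA, asgA)
  expect_equal(po2$overlap, po2$n_alpha)
  # disjoint labelings: all overlaps zero
  asgC <- asgA; asgC$label <- c("II", "II", "RR", "RO", "IO", "IR")
  expect_true(all(pattern_overlap(asgA, asgC)$overlap == 0))
})
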
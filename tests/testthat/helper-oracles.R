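# Independent brute-force oracles used across tests. These deliberately
# re-derive results by the most literal method available so they stay
# independent of the package's implementation paths.

# Quantile normalization by explicit sort / average / unsort, one column at
# a time, no tie handling (use only on tie-free matrices).
oracle_quantile_normalize <- function(mat) {
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) out[, j] <- ref[rank(mat[, j])]
  out
}

# Exhaustive 9-way nearest-archetype search on clamped fold changes.
oracle_assign_pattern <- function(fc_u, fc_l) {
  arch <- pattern_archetypes()
  cu <- min(max(fc_u, 0.5), 2)
  cl <- min(max(fc_l, 0.5), 2)
  d <- sqrt((cu - arch$fc_u)^2 + (cl - arch$fc_l)^2)
  arch$label[which.min(d)]
}

# One-way ANOVA residual decomposition for a single gene.
oracle_pooled_var <- function(values, groups) {
  gs <- split(values, groups)
  ss <- sum(vapply(gs, function(v) sum((v - mean(v))^2), numeric(1)))
  df <- length(values) - length(gs)
  list(means = vapply(gs, mean, numeric(1)), s2 = ss / df, df = df)
}

# A minimal design sheet for hand-built matrices.
toy_design <- function(receptor, ligand, chx = FALSE, time_hr = 3,
                       cell_line = "HepG2") {
  n <- length(receptor)
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    cell_line = cell_line, receptor = receptor, ligand = ligand,
    dose_nM = ifelse(ligand == "T3", 100, 0),
    time_hr = time_hr, chx = rep_len(chx, n),
    replicate = stats::ave(seq_len(n),
                           paste(receptor, ligand, rep_len(chx, n)),
                           FUN = seq_along),
    stringsAsFactors = FALSE)
}

# Hand-built gene_effects table for targeted generative checks.
manual_effects <- function(archetype, u, l, direct = TRUE, sigma = 1e-8,
                           baseline = 8, ec50_a = 1, ec50_b = 1, hill = 1,
                           chx_a = 0, chx_b = 0, late_beta = FALSE) {
  n <- length(archetype)
  structure(data.frame(
    probe_id = sprintf("g%03d", seq_len(n)),
    archetype = archetype,
    u_TRA = u, u_TRB = u, l_TRA = l, l_TRB = l,
    direct = direct, late_beta = rep_len(late_beta, n),
    chx_TRA = rep_len(chx_a, n), chx_TRB = rep_len(chx_b, n),
    ec50_TRA = rep_len(ec50_a, n), ec50_TRB = rep_len(ec50_b, n),
    hill = rep_len(hill, n), sigma = rep_len(sigma, n),
    baseline = rep_len(baseline, n),
    stringsAsFactors = FALSE), class = c("gene_effects", "data.frame"))
}
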
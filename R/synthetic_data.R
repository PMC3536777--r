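#' Regulation-pattern archetype labels
#'
#' Nine two-letter codes: first letter = unliganded axis, second = ligand
#' axis; R = repressed (fold 0.5), O = no effect (fold 1), I = induced
#' (fold 2). Order follows the canonical listing (RR, RO, RI, OR, OO, OI,
#' IR, IO, II) used for tie-breaking in the classifier.
#'
#' @return Character vector of the nine labels.
#' @export
archetype_labels <- function() {
  c("RR", "RO", "RI", "OR", "OO", "OI", "IR", "IO", "II")
}

#' Default archetype mixture for simulated cohorts
#'
#' Most genes are unresponsive (OO); the responsive remainder is spread over
#' the eight reportable patterns in proportions resembling a hepatocyte-like
#' cohort where the RO (de-repression by ligand) and IO (de-induction)
#' patterns dominate.
#'
#' @param responsive_mass Total probability assigned to non-OO archetypes.
#' @return Named probability vector over the nine archetypes, summing to 1.
#' @export
default_archetype_proportions <- function(responsive_mass = 0.4) {
  stopifnot(responsive_mass >= 0, responsive_mass <= 1)
  w <- c(RR = 67, RO = 1587, RI = 202, OR = 124, OI = 153,
         IR = 156, IO = 1011, II = 36)
  p <- responsive_mass * w / sum(w)
  out <- c(p["RR"], p["RO"], p["RI"], p["OR"], OO = 1 - responsive_mass,
           p["OI"], p["IR"], p["IO"], p["II"])
  names(out) <- archetype_labels()
  out
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study: cohort size and archetype
#' mixture, log2 effect-size distribution, per-receptor kinetic weights over
#' the time grid, the late TRbeta-preferential subset, direct-target
#' fraction and CHX behaviour, the variance prior behind per-gene noise,
#' replication, and the T3 dose grid.
#'
#' @param n_genes Number of probes to simulate.
#' @param archetype_proportions Named probability vector over the nine
#'   archetypes (see [archetype_labels()]); must sum to 1.
#' @param effect_meanlog,effect_sdlog Parameters of the lognormal from which
#'   |log2 effect| magnitudes are drawn (defaults centre magnitudes at 1,
#'   i.e. 2-fold, so the significance gate is exercised from both sides).
#'   `effect_sdlog = 0` fixes every magnitude at `exp(effect_meanlog)`.
#' @param times Time points in hours for the time-course arm.
#' @param kinetic_weights 2 x length(times) matrix (rows `TRA`, `TRB`)
#'   multiplying the ligand effect at each time. Defaults front-load TRalpha
#'   (1.0, 1.0, 0.8) and back-load TRbeta (0.5, 0.8, 1.2), reproducing the
#'   early-alpha / late-beta asymmetry.
#' @param late_beta_fraction Fraction of responsive genes made strongly
#'   TRbeta-preferential at late times.
#' @param late_beta_factor For that subset, TRalpha kinetic weights are
#'   divided by this factor, so the TRbeta weight at 24 h exceeds the
#'   effective TRalpha weight by at least this factor.
#' @param direct_fraction Fraction of T3-responsive genes whose response
#'   persists under cycloheximide (direct targets).
#' @param chx_attenuation Multiplier on the T3 effect of indirect genes in
#'   the T3+CHX condition (0 = abolished).
#' @param chx_derepress_fraction Fraction of genes given a TRalpha-selective
#'   CHX-alone induction (emulating CHX-dependent de-repression).
#' @param chx_derepress_lfc log2 magnitude of that CHX-alone induction.
#' @param noise_df0,noise_scale Prior degrees of freedom and scale of the
#'   scaled inverse-chi-square from which per-gene residual variances are
#'   drawn (`sigma^2 = df0 * scale / rchisq(df0)`); `noise_df0 = Inf` fixes
#'   `sigma^2 = noise_scale` for every gene.
#' @param replicates Replicates per condition cell (>= 2).
#' @param dose_grid T3 concentrations in nM for the dose-series arm; must
#'   include 0.
#' @param ec50_log10_range Range of log10 EC50 (nM) from which per-gene,
#'   per-receptor EC50s are drawn uniformly (default 0.1 to ~32 nM).
#' @param hill_slope Hill coefficient used in the generative dose model.
#' @param baseline_mean,baseline_sd Normal parameters of per-gene log2
#'   baseline intensity.
#' @param cell_line Label stamped on the design sheet.
#' @param seed Integer seed; `NULL` leaves the RNG state alone. The effect
#'   draw uses `seed`, and the time-course, CHX and dose arms use
#'   `seed + 1`, `+ 2`, `+ 3` so each arm is reproducible independently.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       archetype_proportions = default_archetype_proportions(),
                       effect_meanlog = 0,
                       effect_sdlog = 0.5,
                       times = c(3, 6, 24),
                       kinetic_weights = rbind(TRA = c(1.0, 1.0, 0.8),
                                               TRB = c(0.5, 0.8, 1.2)),
                       late_beta_fraction = 0.1,
                       late_beta_factor = 4,
                       direct_fraction = 0.8,
                       chx_attenuation = 0,
                       chx_derepress_fraction = 0,
                       chx_derepress_lfc = 1.5,
                       noise_df0 = 4,
                       noise_scale = 0.04,
                       replicates = 3,
                       dose_grid = c(0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100),
                       ec50_log10_range = c(-1, log10(32)),
                       hill_slope = 1,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       cell_line = "HepG2",
                       seed = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (replicates < 2) stop("replicates must be >= 2")
  p <- archetype_proportions
  if (is.null(names(p)) || !setequal(names(p), archetype_labels()))
    stop("archetype_proportions must be named with the nine archetype labels")
  p <- p[archetype_labels()]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("archetype_proportions must be nonnegative and sum to 1")
  kinetic_weights <- as.matrix(kinetic_weights)
  if (!identical(rownames(kinetic_weights), c("TRA", "TRB")) ||
      ncol(kinetic_weights) != length(times))
    stop("kinetic_weights must be a 2 x length(times) matrix with rows TRA, TRB")
  colnames(kinetic_weights) <- as.character(times)
  for (f in c(late_beta_fraction, direct_fraction, chx_attenuation,
              chx_derepress_fraction))
    if (f < 0 || f > 1) stop("fractions/attenuation must lie in [0, 1]")
  if (noise_scale <= 0 || noise_df0 <= 0) stop("noise prior must be positive")
  if (any(dose_grid < 0)) stop("dose_grid must be nonnegative")
  if (hill_slope <= 0) stop("hill_slope must be > 0")
  structure(list(
    n_genes = as.integer(n_genes), archetype_proportions = p,
    effect_meanlog = effect_meanlog, effect_sdlog = effect_sdlog,
    times = times, kinetic_weights = kinetic_weights,
    late_beta_fraction = late_beta_fraction, late_beta_factor = late_beta_factor,
    direct_fraction = direct_fraction, chx_attenuation = chx_attenuation,
    chx_derepress_fraction = chx_derepress_fraction,
    chx_derepress_lfc = chx_derepress_lfc,
    noise_df0 = noise_df0, noise_scale = noise_scale,
    replicates = as.integer(replicates), dose_grid = dose_grid,
    ec50_log10_range = ec50_log10_range, hill_slope = hill_slope,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    cell_line = cell_line, seed = seed
  ), class = "sim_config")
}

.axis_sign <- function(letter) c(R = -1, O = 0, I = 1)[letter]

#' Draw per-gene ground-truth effect specifications
#'
#' Assigns each gene an archetype by sampling `archetype_proportions`, draws
#' signed log2 effect magnitudes for the unliganded and ligand axes (shared
#' between receptor subtypes; subtype differences come from kinetic
#' weights), per-gene residual sigma from the scaled inverse-chi-square
#' prior, per-receptor EC50s, and the direct / late-beta / CHX-derepression
#' flags.
#'
#' @param config A [sim_config()].
#' @return Data frame of class `gene_effects`, one row per gene: `probe_id`,
#'   `archetype`, `u_TRA`, `u_TRB`, `l_TRA`, `l_TRB` (log2 effects),
#'   `direct` (NA for non-responsive genes), `late_beta`, `chx_TRA`,
#'   `chx_TRB` (CHX-alone log2 effects), `ec50_TRA`, `ec50_TRB` (nM),
#'   `hill`, `sigma`, `baseline`.
#' @export
draw_gene_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_genes
  arch <- sample(archetype_labels(), n, replace = TRUE,
                 prob = config$archetype_proportions)
  su <- .axis_sign(substr(arch, 1L, 1L))
  sl <- .axis_sign(substr(arch, 2L, 2L))
  mag_u <- stats::rlnorm(n, config$effect_meanlog, config$effect_sdlog)
  mag_l <- stats::rlnorm(n, config$effect_meanlog, config$effect_sdlog)
  u <- su * mag_u
  l <- sl * mag_l
  responsive <- sl != 0
  direct <- rep(NA, n)
  direct[responsive] <- stats::runif(sum(responsive)) < config$direct_fraction
  late_beta <- rep(FALSE, n)
  late_beta[responsive] <- stats::runif(sum(responsive)) < config$late_beta_fraction
  chx_a <- rep(0, n)
  if (config$chx_derepress_fraction > 0) {
    chx_a[stats::runif(n) < config$chx_derepress_fraction] <- config$chx_derepress_lfc
  }
  sigma <- if (is.infinite(config$noise_df0)) {
    rep(sqrt(config$noise_scale), n)
  } else {
    sqrt(config$noise_df0 * config$noise_scale /
           stats::rchisq(n, df = config$noise_df0))
  }
  r10 <- config$ec50_log10_range
  structure(data.frame(
    probe_id = sprintf("probe_%05d", seq_len(n)),
    archetype = arch,
    u_TRA = u, u_TRB = u,
    l_TRA = l, l_TRB = l,
    direct = direct, late_beta = late_beta,
    chx_TRA = chx_a, chx_TRB = 0,
    ec50_TRA = 10^stats::runif(n, r10[1L], r10[2L]),
    ec50_TRB = 10^stats::runif(n, r10[1L], r10[2L]),
    hill = config$hill_slope,
    sigma = sigma,
    baseline = stats::rnorm(n, config$baseline_mean, config$baseline_sd),
    stringsAsFactors = FALSE
  ), class = c("gene_effects", "data.frame"))
}

# Effective kinetic weight for gene g with receptor r at time index ti:
# the configured weight, with TRalpha attenuated for the late-beta subset.
.kinetic_weight <- function(effects, config, receptor, time_idx) {
  w <- config$kinetic_weights[receptor, time_idx]
  if (receptor == "TRA") {
    ifelse(effects$late_beta, w / config$late_beta_factor, w)
  } else {
    rep(w, nrow(effects))
  }
}

.new_design <- function(sample_id, cell_line, receptor, ligand, dose_nM,
                        time_hr, chx, replicate) {
  validate_design(data.frame(
    sample_id = sample_id, cell_line = cell_line, receptor = receptor,
    ligand = ligand, dose_nM = dose_nM, time_hr = time_hr, chx = chx,
    replicate = replicate, stringsAsFactors = FALSE
  ))
}

.add_noise <- function(mu, sigma) {
  mu + matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) * sigma
}

#' Simulate the factorial T3 time-course arm
#'
#' One sample per (receptor in parental/TRA/TRB) x (vehicle/T3) x time x
#' replicate. Expected log2 value of gene g in receptor r with T3 at time t
#' is `baseline + u_r + w(r, t) * l_r`; vehicle drops the ligand term;
#' parental cells carry baseline only (no endogenous receptor is modelled).
#' i.i.d. Gaussian noise with the gene's sigma is added to every entry.
#'
#' @param effects A `gene_effects` table from [draw_gene_effects()].
#' @param config The matching [sim_config()].
#' @return List with `matrix` (probes x samples, log2) and `design`.
#' @export
simulate_timecourse <- function(effects, config) {
  stopifnot(inherits(effects, "gene_effects"), nrow(effects) > 0)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  cols <- list(); des <- list()
  for (rec in c("parental", "TRA", "TRB")) {
    u <- if (rec == "parental") 0 else effects[[paste0("u_", rec)]]
    for (ti in seq_along(config$times)) {
      t_hr <- config$times[ti]
      for (lig in c("vehicle", "T3")) {
        lterm <- if (lig == "T3" && rec != "parental") {
          .kinetic_weight(effects, config, rec, ti) * effects[[paste0("l_", rec)]]
        } else 0
        mu <- effects$baseline + u + lterm
        for (r in seq_len(config$replicates)) {
          id <- sprintf("%s.%s.%s.%gh.r%d", config$cell_line, rec, lig, t_hr, r)
          cols[[id]] <- mu
          des[[id]] <- data.frame(
            sample_id = id, cell_line = config$cell_line, receptor = rec,
            ligand = lig, dose_nM = if (lig == "T3") 100 else 0,
            time_hr = t_hr, chx = FALSE, replicate = r,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  mu <- do.call(cbind, cols)
  rownames(mu) <- effects$probe_id
  list(matrix = .add_noise(mu, effects$sigma),
       design = validate_design(do.call(rbind, des)))
}

#' Simulate the cycloheximide (CHX) arm at 3 h
#'
#' Adds the four 3 h conditions (control, T3, CHX, T3+CHX) for parental,
#' TRalpha and TRbeta cells. Direct genes retain the full T3 effect under
#' CHX; indirect genes have it multiplied by `chx_attenuation` (default 0,
#' abolished). CHX-alone effects (`chx_TRA`/`chx_TRB` in the effects table)
#' emulate selective CHX-dependent de-repression.
#'
#' @inheritParams simulate_timecourse
#' @return List with `matrix` and `design` (all samples at `time_hr` equal
#'   to the first configured time point, 3 h by default).
#' @export
simulate_chx_arm <- function(effects, config) {
  stopifnot(inherits(effects, "gene_effects"), nrow(effects) > 0)
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  t_hr <- config$times[1L]
  persist <- ifelse(is.na(effects$direct) | effects$direct, 1, config$chx_attenuation)
  cols <- list(); des <- list()
  for (rec in c("parental", "TRA", "TRB")) {
    u <- if (rec == "parental") 0 else effects[[paste0("u_", rec)]]
    chx_eff <- if (rec == "parental") 0 else effects[[paste0("chx_", rec)]]
    l3 <- if (rec == "parental") 0 else
      .kinetic_weight(effects, config, rec, 1L) * effects[[paste0("l_", rec)]]
    cond <- list(
      control = effects$baseline + u,
      T3      = effects$baseline + u + l3,
      CHX     = effects$baseline + u + chx_eff,
      T3CHX   = effects$baseline + u + chx_eff + persist * l3
    )
    lig <- c(control = "vehicle", T3 = "T3", CHX = "vehicle", T3CHX = "T3")
    chx <- c(control = FALSE, T3 = FALSE, CHX = TRUE, T3CHX = TRUE)
    for (cn in names(cond)) {
      for (r in seq_len(config$replicates)) {
        id <- sprintf("%s.%s.%s.chx%d.%gh.r%d", config$cell_line, rec,
                      lig[[cn]], as.integer(chx[[cn]]), t_hr, r)
        cols[[id]] <- cond[[cn]]
        des[[id]] <- data.frame(
          sample_id = id, cell_line = config$cell_line, receptor = rec,
          ligand = lig[[cn]], dose_nM = if (lig[[cn]] == "T3") 100 else 0,
          time_hr = t_hr, chx = chx[[cn]], replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  mu <- do.call(cbind, cols)
  rownames(mu) <- effects$probe_id
  list(matrix = .add_noise(mu, effects$sigma),
       design = validate_design(do.call(rbind, des)))
}

#' Simulate the T3 dose-series arm
#'
#' For TRalpha and TRbeta cells at the last configured time point, expected
#' induction of gene g at dose d follows the Hill form
#' `baseline + l_r * d^h / (d^h + ec50_r^h)`; dose 0 equals baseline in
#' expectation.
#'
#' @inheritParams simulate_timecourse
#' @return List with `matrix` and `design`.
#' @export
simulate_dose_series <- function(effects, config) {
  stopifnot(inherits(effects, "gene_effects"), nrow(effects) > 0)
  if (!length(config$dose_grid)) stop("dose_grid is empty")
  if (!is.null(config$seed)) set.seed(config$seed + 3L)
  t_hr <- config$times[length(config$times)]
  h <- effects$hill
  cols <- list(); des <- list()
  for (rec in c("TRA", "TRB")) {
    l <- effects[[paste0("l_", rec)]]
    ec50 <- effects[[paste0("ec50_", rec)]]
    for (d in config$dose_grid) {
      frac <- if (d == 0) 0 else d^h / (d^h + ec50^h)
      mu <- effects$baseline + l * frac
      for (r in seq_len(config$replicates)) {
        id <- sprintf("%s.%s.d%g.r%d", config$cell_line, rec, d, r)
        cols[[id]] <- mu
        des[[id]] <- data.frame(
          sample_id = id, cell_line = config$cell_line, receptor = rec,
          ligand = if (d > 0) "T3" else "vehicle", dose_nM = d,
          time_hr = t_hr, chx = FALSE, replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  mu <- do.call(cbind, cols)
  rownames(mu) <- effects$probe_id
  list(matrix = .add_noise(mu, effects$sigma),
       design = validate_design(do.call(rbind, des)))
}

#' Write / read a ground-truth gene-effects table
#'
#' Tab-delimited round trip for the `gene_effects` table so simulated
#' cohorts can ship their truth alongside the matrices.
#'
#' @param effects `gene_effects` data frame.
#' @param path File path.
#' @rdname gene_effects_io
#' @export
write_gene_effects <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gene_effects_io
#' @export
read_gene_effects <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$direct <- as.logical(df$direct)
  df$late_beta <- as.logical(df$late_beta)
  structure(df, class = c("gene_effects", "data.frame"))
}
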
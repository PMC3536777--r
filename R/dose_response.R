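#' Fit a four-parameter Hill dose-response curve
#'
#' Least-squares fit of `response = bottom + (top - bottom) * d^h /
#' (d^h + ec50^h)` to log2 expression over a T3 dose grid. Dose 0 is the
#' exact lower asymptote (no log-dose transform of the model); the
#' optimizer works on `log10(ec50)` and `log(h)`. For fixed (ec50, h) the
#' model is linear in (bottom, top), so those are profiled out by a linear
#' solve and the nonlinear search runs over a log-spaced ec50 multistart
#' grid spanning the positive dose range, which avoids local minima.
#' Bootstrap intervals resample replicates within each dose.
#'
#' @param doses Dose vector in nM, one entry per observation (replicates
#'   repeat the dose); must contain >= 4 distinct doses including 0.
#' @param responses log2 expression, same length as `doses`.
#' @param hill_fixed Optional fixed Hill coefficient (e.g. 1); default free.
#' @param n_boot Bootstrap resamples for the EC50 interval (0 disables).
#' @param direction Optional expected direction (`"induced"`/`"repressed"`);
#'   a fitted span of the opposite sign whose bootstrap CI excludes 0 sets
#'   the non-responsive flag.
#' @param seed Optional seed for the bootstrap.
#' @return List of class `hill_fit`: `ec50`, `hill`, `bottom`, `top`,
#'   `rss`, `converged`, `non_responsive`, `extrapolated`, `ec50_ci`,
#'   `boot_ec50`, `span_ci`, `direction`.
#' @export
fit_hill <- function(doses, responses, hill_fixed = NULL, n_boot = 200,
                     direction = NULL, seed = NULL) {
  stopifnot(length(doses) == length(responses))
  if (any(!is.finite(responses)) || any(doses < 0))
    stop("responses must be finite and doses nonnegative")
  ud <- sort(unique(doses))
  if (length(ud) < 4L || ud[1L] != 0)
    stop("need >= 4 distinct doses including dose 0")
  fit1 <- .hill_ls(doses, responses, hill_fixed)
  boot_ec50 <- numeric(0)
  span_ci <- c(NA_real_, NA_real_)
  ec50_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    idx_by_dose <- split(seq_along(doses), doses)
    be <- numeric(n_boot); bs <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(idx_by_dose, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      fb <- .hill_ls(doses[idx], responses[idx], hill_fixed,
                     starts = log10(fit1$ec50))
      be[b] <- fb$ec50; bs[b] <- fb$top - fb$bottom
    }
    boot_ec50 <- be
    ec50_ci <- unname(stats::quantile(be, c(0.025, 0.975)))
    span_ci <- unname(stats::quantile(bs, c(0.025, 0.975)))
  }
  span <- fit1$top - fit1$bottom
  # Non-responsive: the Hill term explains nothing beyond a flat line
  # (F test), or the fitted span contradicts the stated direction with a
  # bootstrap interval excluding zero.
  rss0 <- sum((responses - mean(responses))^2)
  n <- length(responses)
  fstat <- ((rss0 - fit1$rss) / 3) / (fit1$rss / max(n - 4, 1))
  flat <- !is.finite(fstat) || stats::pf(fstat, 3, max(n - 4, 1),
                                         lower.tail = FALSE) > 0.05
  wrong_sign <- !is.null(direction) && n_boot > 0 &&
    ((direction == "induced" && span < 0 && span_ci[2L] < 0) ||
     (direction == "repressed" && span > 0 && span_ci[1L] > 0))
  structure(list(
    ec50 = fit1$ec50, hill = fit1$hill,
    bottom = fit1$bottom, top = fit1$top, rss = fit1$rss,
    converged = fit1$converged,
    non_responsive = flat || wrong_sign,
    extrapolated = fit1$ec50 < min(ud[ud > 0]) || fit1$ec50 > max(ud),
    ec50_ci = ec50_ci, boot_ec50 = boot_ec50, span_ci = span_ci,
    direction = if (is.null(direction)) NA_character_ else direction
  ), class = "hill_fit")
}

# Profiled least squares: for fixed (log10 ec50, log h) solve the linear
# (bottom, span) subproblem; nlminb over the nonlinear pair from multiple
# starts.
.hill_ls <- function(doses, responses, hill_fixed = NULL, starts = NULL) {
  frac <- function(le, lh) {
    e <- 10^le; h <- exp(lh)
    ifelse(doses == 0, 0, doses^h / (doses^h + e^h))
  }
  lin_rss <- function(f) {
    X <- cbind(1, f)
    cf <- tryCatch(qr.coef(qr(X), responses), error = function(e) c(mean(responses), 0))
    cf[is.na(cf)] <- 0
    r <- responses - X %*% cf
    list(coef = cf, rss = sum(r^2))
  }
  obj <- function(par) {
    lh <- if (is.null(hill_fixed)) par[2L] else log(hill_fixed)
    lin_rss(frac(par[1L], lh))$rss
  }
  pos <- sort(unique(doses[doses > 0]))
  grid <- if (is.null(starts)) {
    seq(log10(min(pos)), log10(max(pos)), length.out = 7L)
  } else starts
  best <- NULL
  for (le in grid) {
    par0 <- if (is.null(hill_fixed)) c(le, 0) else le
    lower <- if (is.null(hill_fixed)) c(log10(min(pos)) - 2, log(0.2)) else log10(min(pos)) - 2
    upper <- if (is.null(hill_fixed)) c(log10(max(pos)) + 2, log(5)) else log10(max(pos)) + 2
    o <- tryCatch(
      stats::nlminb(par0, obj, lower = lower, upper = upper,
                    control = list(rel.tol = 1e-12, iter.max = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$objective < best$objective)) best <- o
  }
  # Convergence by relative RSS change: a polish restart from the best
  # point must not improve the objective appreciably (nlminb return codes
  # are unreliable near machine-precision optima).
  polish <- tryCatch(
    stats::nlminb(best$par, obj,
                  lower = if (is.null(hill_fixed)) c(log10(min(pos)) - 2, log(0.2)) else log10(min(pos)) - 2,
                  upper = if (is.null(hill_fixed)) c(log10(max(pos)) + 2, log(5)) else log10(max(pos)) + 2,
                  control = list(rel.tol = 1e-12, iter.max = 500)),
    error = function(e) best)
  converged <- (best$objective - polish$objective) <=
    1e-10 * max(best$objective, 1e-8)
  if (polish$objective <= best$objective) best <- polish
  le <- best$par[1L]
  lh <- if (is.null(hill_fixed)) best$par[2L] else log(hill_fixed)
  ls <- lin_rss(frac(le, lh))
  list(ec50 = 10^le, hill = exp(lh),
       bottom = unname(ls$coef[1L]),
       top = unname(ls$coef[1L] + ls$coef[2L]),
       rss = ls$rss,
       converged = converged)
}

#' Compare EC50 between receptor subtypes
#'
#' Ratio `ec50_beta / ec50_alpha` with a percentile interval from paired
#' bootstrap draws; a gene is flagged subtype-shifted when the interval
#' excludes 1.
#'
#' @param fitA,fitB `hill_fit` objects for the same gene with TRalpha and
#'   TRbeta (both must have converged and carry bootstrap draws).
#' @return List: `ratio`, `ci`, `shifted`.
#' @export
compare_ec50 <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "hill_fit"), inherits(fitB, "hill_fit"))
  if (!fitA$converged || !fitB$converged)
    stop("EC50 comparison undefined: a fit did not converge")
  ratio <- fitB$ec50 / fitA$ec50
  nb <- min(length(fitA$boot_ec50), length(fitB$boot_ec50))
  if (nb == 0) return(list(ratio = ratio, ci = c(NA_real_, NA_real_), shifted = NA))
  draws <- fitB$boot_ec50[seq_len(nb)] / fitA$boot_ec50[seq_len(nb)]
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  list(ratio = ratio, ci = ci, shifted = ci[1L] > 1 || ci[2L] < 1)
}

#' EC50 report over a dose-series matrix
#'
#' Fits per-gene Hill curves for TRalpha and TRbeta from a dose-series
#' expression matrix and design, and assembles the per-gene EC50 table with
#' the subtype ratio and shift flag.
#'
#' @param mat Dose-series expression matrix.
#' @param design Matching design sheet (doses in `dose_nM`).
#' @param probes Probes to fit (default all).
#' @param hill_fixed,n_boot,seed Passed to [fit_hill()].
#' @return Data frame: `probe_id`, `ec50_TRA`, `ec50_TRB`, `hill_TRA`,
#'   `hill_TRB`, `ratio`, `ci_lo`, `ci_hi`, `shifted`, `converged`,
#'   `non_responsive`.
#' @export
fit_dose_response <- function(mat, design, probes = rownames(mat),
                              hill_fixed = NULL, n_boot = 200, seed = NULL) {
  design <- align_design(mat, design)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(probes, function(p) {
    fits <- lapply(c(TRA = "TRA", TRB = "TRB"), function(rec) {
      sub <- design[design$receptor == rec, , drop = FALSE]
      fit_hill(sub$dose_nM, mat[p, sub$sample_id], hill_fixed = hill_fixed,
               n_boot = n_boot)
    })
    cmp <- if (fits$TRA$converged && fits$TRB$converged && n_boot > 0) {
      compare_ec50(fits$TRA, fits$TRB)
    } else list(ratio = fits$TRB$ec50 / fits$TRA$ec50,
                ci = c(NA_real_, NA_real_), shifted = NA)
    data.frame(probe_id = p,
               ec50_TRA = fits$TRA$ec50, ec50_TRB = fits$TRB$ec50,
               hill_TRA = fits$TRA$hill, hill_TRB = fits$TRB$hill,
               ratio = cmp$ratio, ci_lo = cmp$ci[1L], ci_hi = cmp$ci[2L],
               shifted = cmp$shifted,
               converged = fits$TRA$converged && fits$TRB$converged,
               non_responsive = fits$TRA$non_responsive || fits$TRB$non_responsive,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
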
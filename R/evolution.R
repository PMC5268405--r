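#' Robertson-Price estimate of genetic change
#'
#' The additive genetic covariance between a trait and relative fitness,
#' \eqn{\sigma_A(z, \omega)}, is the rate of genetic change per generation
#' according to the secondary theorem of selection; used retrospectively it
#' estimates the mean evolutionary change over the study period. Per-year
#' rates divide by the mean generation time sample-wise.
#'
#' @param fit A `qg_animal_model` with fitness.
#' @param trait Focal trait.
#' @param T_gen Mean generation time (years).
#' @param fitness_trait Fitness trait name.
#' @return List: `per_generation`, `per_year` (posterior vectors), `mode`,
#'   `hpd` (per-year), `p_mcmc`.
#' @export
price_genetic_change <- function(fit, trait = "mass", T_gen,
                                 fitness_trait = "omega") {
  i <- .trait_index(fit, trait)
  j <- .trait_index(fit, fitness_trait)
  if (T_gen <= 0) stop("generation time must be positive")
  pg <- fit$G[i, j, ]
  py <- pg / T_gen
  list(per_generation = pg, per_year = py,
       mode = posterior_mode(py), hpd = hpd(py), p_mcmc = p_mcmc(py))
}

# least-squares slope of cohort means against cohort year
.cohort_slope <- function(values, cohorts) {
  cm <- tapply(values, cohorts, mean)
  yrs <- as.numeric(names(cm))
  if (length(cm) < 3) stop("need >= 3 cohorts for a trend")
  unname(stats::coef(stats::lm(cm ~ yrs))[2])
}

#' Trend in predicted breeding values with full uncertainty propagation
#'
#' For every posterior sample of the breeding values, computes cohort means
#' and the least-squares slope of those means on cohort year. The slope is
#' therefore a posterior distribution that carries both the non-independence
#' of the predictions and their sampling variance; summarizing predicted
#' breeding values first and regressing once would understate the
#' uncertainty.
#'
#' @param fit A `qg_animal_model` fitted with `store_bv = TRUE`.
#' @param trait Trait name.
#' @param cohorts Optional named vector of cohorts (defaults to the
#'   pedigree cohorts stored in the fit).
#' @param min_cohort,max_cohort Optional cohort range restriction.
#' @return A `qg_trend` list: `slopes` (posterior), `mode`, `hpd`,
#'   `p_mcmc`, and `cohort_means` (cohort x sample matrix).
#' @export
blup_trend <- function(fit, trait = "mass", cohorts = NULL,
                       min_cohort = -Inf, max_cohort = Inf) {
  if (is.null(fit$bv)) stop("fit was run without store_bv = TRUE")
  t <- .trait_index(fit, trait)
  if (is.null(cohorts)) cohorts <- fit$cohorts
  keep <- names(cohorts)[cohorts >= min_cohort & cohorts <= max_cohort]
  bv <- fit$bv[keep, t, , drop = FALSE]
  coh <- cohorts[keep]
  if (length(unique(coh)) < 3) stop("need >= 3 cohorts for a trend")
  S <- dim(bv)[3]
  yrs <- sort(unique(coh))
  cm <- matrix(NA_real_, length(yrs), S,
               dimnames = list(yrs, NULL))
  slopes <- numeric(S)
  X <- cbind(1, yrs)
  XtXi <- solve(crossprod(X))
  for (s in seq_len(S)) {
    m <- tapply(bv[, 1, s], coh, mean)
    cm[, s] <- m[as.character(yrs)]
    slopes[s] <- (XtXi %*% crossprod(X, cm[, s]))[2]
  }
  out <- list(slopes = slopes, mode = posterior_mode(slopes),
              hpd = hpd(slopes), p_mcmc = p_mcmc(slopes),
              cohort_means = cm, cohort_years = yrs)
  class(out) <- "qg_trend"
  out
}

#' @export
print.qg_trend <- function(x, ...) {
  cat("Breeding-value trend:", format(x$mode, digits = 3), "per year, 95% HPD [",
      format(x$hpd[1], digits = 3), ",", format(x$hpd[2], digits = 3),
      "], p_MCMC =", format(x$p_mcmc, digits = 2), "\n")
  invisible(x)
}

#' Gene-dropping drift null for the breeding-value trend
#'
#' For each posterior sample of the additive variance, simulates neutral
#' breeding values down the observed pedigree (founders `N(0, V_A)`,
#' offspring = midparent + Mendelian sampling `N(0, V_A (1 -
#' (F_s + F_d)/2) / 2)`), computes the same cohort-mean slope as
#' [blup_trend()], and compares the observed slope distribution with the
#' paired drift distribution. The pairing matters: large posterior `V_A`
#' produces both large estimated change and large drift variance, so the
#' exceedance probability must be computed pairwise.
#'
#' @param ped A `qg_pedigree`.
#' @param va_samples Posterior draws of the additive genetic variance.
#' @param observed_slopes Paired posterior draws of the observed per-year
#'   rate of genetic change (same length and order as `va_samples`), e.g.
#'   the Robertson-Price `per_year` samples or [blup_trend()] slopes.
#' @param n_sims Number of drift replicates (recycled over posterior
#'   samples; default one replicate per sample, 1000 samples).
#' @param seed Integer seed.
#' @param tail `"one"` (exceedance in the observed direction, the default)
#'   or `"two"` (absolute).
#' @param min_cohort,max_cohort Cohort range used for the slope.
#' @return A `qg_drift` list: `drift_slopes`, `p_drift`, `direction`,
#'   `n_sims`.
#' @export
gene_drop_drift <- function(ped, va_samples, observed_slopes = NULL,
                            n_sims = length(va_samples), seed = 1,
                            tail = c("one", "two"),
                            min_cohort = -Inf, max_cohort = Inf) {
  tail <- match.arg(tail)
  if (!length(va_samples)) stop("va_samples is empty")
  if (any(va_samples < 0)) stop("negative variance sample")
  set.seed(seed)
  f <- unname(inbreeding(ped))
  keep <- ped$cohort >= min_cohort & ped$cohort <= max_cohort
  coh <- ped$cohort[keep]
  if (length(unique(coh)) < 3) stop("need >= 3 cohorts for a trend")
  yrs <- sort(unique(coh))
  X <- cbind(1, yrs)
  XtXi_Xt <- solve(crossprod(X)) %*% t(X)
  idx <- rep_len(seq_along(va_samples), n_sims)
  drift <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    va <- va_samples[idx[s]]
    bv <- if (va == 0) matrix(0, nrow(ped), 1) else
      simulate_breeding_values(ped, matrix(va, 1, 1), f = f)
    m <- tapply(bv[keep, 1], coh, mean)
    drift[s] <- (XtXi_Xt %*% m[as.character(yrs)])[2]
  }
  out <- list(drift_slopes = drift, n_sims = n_sims, tail = tail)
  if (!is.null(observed_slopes)) {
    obs <- observed_slopes[idx]
    dir <- sign(stats::median(obs))
    p <- if (tail == "one") {
      if (dir < 0) mean(drift <= obs) else mean(drift >= obs)
    } else {
      mean(abs(drift) >= abs(obs))
    }
    out$observed_slopes <- obs
    out$direction <- dir
    out$p_drift <- max(p, 1 / n_sims)
  }
  class(out) <- "qg_drift"
  out
}

#' @export
print.qg_drift <- function(x, ...) {
  cat("Gene-drop drift null:", x$n_sims, "replicates; drift slope sd =",
      format(stats::sd(x$drift_slopes), digits = 3), "\n")
  if (!is.null(x$p_drift)) {
    cat("P(drift as extreme as observed, ", x$tail, "-tailed) = ",
        format(x$p_drift, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Convert a per-year rate of change to Darwins
#'
#' One Darwin is an e-fold change of the trait mean per million years. For
#' a one-year step of size `rate` on a mean of `mean_trait`, the rate in
#' Darwins is \eqn{|\ln((\bar{z} + rate)/\bar{z})| \times 10^6}. The
#' formula is returned alongside the number because conventions vary in
#' which mean and interval are used.
#'
#' @param rate Per-year change in trait units.
#' @param mean_trait Trait mean (same units); must be positive.
#' @return List: `darwins`, `formula`.
#' @export
to_darwins <- function(rate, mean_trait) {
  if (mean_trait <= 0) stop("trait mean must be positive")
  list(darwins = abs(log((mean_trait + rate) / mean_trait)) * 1e6,
       formula = "abs(ln((mean + rate_per_year)/mean)) * 1e6")
}
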
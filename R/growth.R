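#' MCMC settings for the growth/survival sampler
#'
#' Default is a desk-scale preset; `growth_mcmc_long()` is the
#' publication-grade preset (6.3M iterations, 300k burn-in, thinning
#' 6,000).
#' @param n_iter,burnin,thin Chain settings.
#' @param n_chains Number of chains (run serially, seeds offset).
#' @param seed Integer seed.
#' @return Settings list.
#' @export
growth_mcmc_settings <- function(n_iter = 20000, burnin = 5000, thin = 15,
                                 n_chains = 3, seed = 1) {
  stopifnot(n_iter > burnin, thin >= 1, n_chains >= 1)
  list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
       thin = as.integer(thin), n_chains = as.integer(n_chains),
       seed = as.integer(seed))
}

#' @rdname growth_mcmc_settings
#' @export
growth_mcmc_long <- function(seed = 1) {
  growth_mcmc_settings(6300000, 300000, 6000, n_chains = 3, seed = seed)
}

#' Fit the joint growth-curve / overwinter-survival model
#'
#' Bayesian model of juvenile capture histories: each juvenile grows along
#' a monomolecular curve `m(t) = a (1 - exp(-k (t - t0)))` from its
#' litter's conception-scale birth date `t0`; masses are observed with
#' fixed measurement-error SD; litters within a mother-year are latent (at
#' most 5, at least 20 days apart, inside the season window); and
#' overwinter survival follows a logistic regression on sex and predicted
#' adult mass `a`, optionally interacting with the number of days between
#' birth (`t0`) and the first snowfall. `a` is the "predicted (potential)
#' adult mass": the asymptote the juvenile would reach, making individuals
#' comparable at the same developmental stage irrespective of capture age.
#'
#' @param captures Data.frame `id`, `mother`, `year`, `julian_day`, `mass`
#'   (one row per juvenile capture).
#' @param snow Data.frame `year`, `snowmelt_day`, `first_snowfall_day`
#'   covering all capture years.
#' @param survival Data.frame `id`, `sex`, `survived` (0/1 overwinter).
#' @param use_snow Include days-to-snowfall and its interaction with `a`
#'   in the survival regression.
#' @param meas_sd Fixed measurement-error SD in grams.
#' @param max_first_capture_age Maximum conception-to-first-capture time in
#'   days (soft constraint). Like the litter-spacing and maximum-litters
#'   rules, a study-design bound: per-session capture probability is near
#'   one, so a juvenile's first capture happens at the first trapping
#'   session after emergence, and the offset cannot exceed the emergence
#'   age plus that year's widest between-session gap. `NULL` (default)
#'   derives the bound per year from the observed session schedule as
#'   `emergence_allowance` + the year's largest session gap; a scalar
#'   applies one bound everywhere (sensitivity analyses). Without this
#'   bound the ridge-shaped growth likelihood lets birth dates drift early
#'   (see the methods vignette).
#' @param emergence_allowance Upper bound, in days, on the
#'   conception-to-trappability age used when deriving the per-year bound.
#' @param window_before_melt Days before snowmelt that the earliest
#'   conception date may fall.
#' @param hyper Hyperprior `c(mean_a, var_a, mean_logk, var_logk)` for the
#'   population mean of `(a, log k)`. The default anchors the asymptote at
#'   the 97.5% quantile of observed juvenile masses (variance 9 g^2):
#'   the asymptote extrapolates beyond the season's capture window, so an
#'   anchor at the near-asymptotic masses actually observed (equivalently,
#'   the adult mass of the population) is required for a stable scale.
#' @param sigma_prior `c(V_a, V_logk, nu)` for the inverse-Wishart prior
#'   on the population covariance of `(a, log k)`.
#' @param gamma_sd Normal prior SD of the survival coefficients.
#' @param mcmc [growth_mcmc_settings()].
#' @param init Optional named list of starting values (`a`, `logk`, `t0`,
#'   `litter`, `tau`) overriding the default profile-grid initialisation;
#'   mainly for sensitivity checks of the ridge-shaped posterior.
#' @return A `qg_growth` object: posterior matrices `a`, `k`, `t0`,
#'   `litter` (juvenile x sample), `gamma` (5 x sample: intercept, sexM,
#'   mass, days, mass x days), `mu`, `Sigma` (rows `var_a`, `cov`,
#'   `var_logk`), `tau` (group x 5 x sample litter dates), metadata and
#'   convergence diagnostics (split/multi-chain R-hat).
#' @export
fit_growth_survival <- function(captures, snow, survival,
                                use_snow = TRUE,
                                meas_sd = 2.05,
                                max_first_capture_age = NULL,
                                emergence_allowance = 30,
                                window_before_melt = 0,
                                hyper = NULL,
                                sigma_prior = c(25, 0.04, 15),
                                gamma_sd = 100,
                                mcmc = growth_mcmc_settings(),
                                init = NULL) {
  stopifnot(all(c("id", "mother", "year", "julian_day", "mass") %in%
                  names(captures)),
            all(c("year", "snowmelt_day", "first_snowfall_day") %in%
                  names(snow)),
            all(c("id", "sex", "survived") %in% names(survival)))
  yrs_missing <- setdiff(unique(captures$year), snow$year)
  if (length(yrs_missing)) {
    stop("snow table does not cover year(s): ",
         paste(yrs_missing, collapse = ", "))
  }
  smelt <- stats::setNames(snow$snowmelt_day, snow$year)
  if (any(captures$julian_day < smelt[as.character(captures$year)])) {
    bad <- captures[captures$julian_day <
                      smelt[as.character(captures$year)], ]
    stop("capture(s) predate snowmelt, e.g. id ", bad$id[1],
         " day ", bad$julian_day[1], " in ", bad$year[1])
  }
  # The capture window rarely reaches the asymptote and most juveniles have
  # one or two captures, so the absolute growth timescale (k) and with it
  # t0 and a are only weakly identified by the likelihood: flat-curve
  # configurations (small k, early t0, inflated a) are preferred by
  # integrated volume. As with the externally fixed measurement-error SD,
  # the timescale must come from prior knowledge of the system: the default
  # centres log k at log(0.02)/day (90% of asymptotic mass ~115 days after
  # conception) with SD 0.2. Override `hyper`/`sigma_prior` for sensitivity.
  if (is.null(hyper)) {
    hyper <- c(unname(stats::quantile(captures$mass, 0.975)) + 1, 9,
               log(0.02), 0.04)
  }
  # canonical ordering first: the fit must not depend on input row order
  cap <- captures[order(captures$id, captures$julian_day), , drop = FALSE]
  surv <- survival[match(unique(cap$id), survival$id), , drop = FALSE]
  if (anyNA(surv$survived)) {
    stop("missing survival outcome for: ",
         paste(utils::head(unique(cap$id)[is.na(surv$survived)], 5),
               collapse = ", "))
  }

  juv_ids <- surv$id
  jn <- length(juv_ids)
  jidx <- match(cap$id, juv_ids)
  mom_of <- tapply(cap$mother, cap$id, function(x) x[1])[juv_ids]
  yr_of <- tapply(cap$year, cap$id, function(x) x[1])[juv_ids]
  gkey <- paste(mom_of, yr_of, sep = ":")
  glev <- sort(unique(gkey))
  jgroup <- match(gkey, glev)
  gyear <- as.integer(sub(".*:", "", glev))
  glo <- smelt[as.character(gyear)] - window_before_melt
  gsnow <- stats::setNames(snow$first_snowfall_day,
                           snow$year)[as.character(gyear)]
  ghi <- gsnow
  # detection window: emergence allowance plus the year's widest session gap
  if (is.null(max_first_capture_age)) {
    gap_of <- vapply(split(cap$julian_day, cap$year), function(d) {
      d <- sort(unique(d))
      if (length(d) < 2) 25 else max(diff(d))
    }, 0)
    gmax <- emergence_allowance + unname(gap_of[as.character(gyear)])
  } else {
    gmax <- rep(max_first_capture_age, length(gyear))
  }

  # centre the survival covariates internally (sampling geometry only; the
  # reported coefficients are transformed back to the raw scale)
  jmin <- tapply(cap$julian_day, cap$id, min)[juv_ids]
  center_a <- mean(tapply(cap$mass, cap$id, max)[juv_ids]) + 2
  center_d <- mean(unname(gsnow[jgroup]) - (unname(jmin) - 40))

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + 1000L * (ch - 1L))
    chains[[ch]] <- growth_gibbs_cpp(
      rec_day = cap$julian_day, rec_mass = cap$mass, rec_j = jidx,
      jgroup = jgroup, jsex = as.integer(surv$sex == "M"),
      jsurv = as.integer(surv$survived),
      grp_lo = unname(glo), grp_hi = unname(ghi), grp_snow = unname(gsnow),
      meas_sd = meas_sd, use_snow = use_snow,
      grp_max_age = unname(gmax),
      center_a = center_a, center_d = center_d,
      hyper = hyper, sig0 = sigma_prior, gamma_sd = gamma_sd,
      n_iter = mcmc$n_iter, burnin = mcmc$burnin, thin = mcmc$thin,
      init = init)
  }
  bindc <- function(name) do.call(cbind, lapply(chains, `[[`, name))
  tau <- do.call(function(...) {
    arrs <- list(...)
    array(unlist(arrs), dim = c(dim(arrs[[1]])[1:2],
                                sum(vapply(arrs, function(x) dim(x)[3], 0L))))
  }, lapply(chains, `[[`, "tau"))

  out <- list(
    a = structure(bindc("a"), dimnames = list(juv_ids, NULL)),
    k = structure(bindc("k"), dimnames = list(juv_ids, NULL)),
    t0 = structure(bindc("t0"), dimnames = list(juv_ids, NULL)),
    litter = structure(bindc("litter"), dimnames = list(juv_ids, NULL)),
    gamma = .uncenter_gamma(bindc("gamma"), center_a, center_d, use_snow),
    mu = structure(bindc("mu"), dimnames = list(c("mu_a", "mu_logk"), NULL)),
    Sigma = structure(bindc("Sigma"),
                      dimnames = list(c("var_a", "cov", "var_logk"), NULL)),
    tau = tau,
    juveniles = data.frame(id = juv_ids, group = jgroup,
                           mother = unname(mom_of), year = unname(yr_of),
                           sex = surv$sex, survived = surv$survived),
    groups = data.frame(group = seq_along(glev), key = glev, year = gyear,
                        lo = unname(glo), hi = unname(ghi),
                        first_snowfall = unname(gsnow)),
    captures = cap, snow = snow,
    use_snow = use_snow, meas_sd = meas_sd, mcmc = mcmc,
    n_chains = mcmc$n_chains,
    chain_sizes = vapply(chains, function(x) ncol(x$a), 0L))
  # hierarchical correlation of (a, log k)
  out$corr_a_logk <- out$Sigma["cov", ] /
    sqrt(out$Sigma["var_a", ] * out$Sigma["var_logk", ])
  out$diagnostics <- .growth_rhat(out)
  class(out) <- "qg_growth"
  out
}

# map survival coefficients sampled on centred covariates back to raw scale
.uncenter_gamma <- function(g, ca, cd, use_snow) {
  out <- g
  if (use_snow) {
    out[3, ] <- g[3, ] - g[5, ] * cd
    out[4, ] <- g[4, ] - g[5, ] * ca
    out[1, ] <- g[1, ] - g[3, ] * ca - g[4, ] * cd + g[5, ] * ca * cd
  } else {
    out[1, ] <- g[1, ] - g[3, ] * ca
  }
  dimnames(out) <- list(c("intercept", "sexM", "mass", "days",
                          "mass_x_days"), NULL)
  out
}

# multi-chain (or split-chain) potential scale reduction factor
.growth_rhat <- function(fit) {
  scalars <- rbind(fit$gamma[if (fit$use_snow) 1:5 else 1:3, , drop = FALSE],
                   fit$mu, fit$Sigma)
  sizes <- fit$chain_sizes
  splits <- if (length(sizes) > 1) {
    ends <- cumsum(sizes)
    mapply(function(a, b) seq(a, b), c(1, utils::head(ends, -1) + 1), ends,
           SIMPLIFY = FALSE)
  } else {
    n <- ncol(scalars)
    list(seq_len(n %/% 2), seq(n %/% 2 + 1, n))
  }
  rhat <- apply(scalars, 1, function(x) {
    ch <- lapply(splits, function(ix) x[ix])
    m <- length(ch); n <- min(lengths(ch))
    ch <- lapply(ch, function(v) v[seq_len(n)])
    means <- vapply(ch, mean, 0)
    vars <- vapply(ch, stats::var, 0)
    B <- n * stats::var(means)
    W <- mean(vars)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
  list(rhat = rhat)
}

#' @export
print.qg_growth <- function(x, ...) {
  cat("qg_growth:", nrow(x$a), "juveniles,", nrow(x$groups),
      "mother-year groups,", ncol(x$a), "posterior samples (",
      x$n_chains, "chains)\n")
  cat("mean predicted adult mass:",
      round(posterior_mode(x$mu["mu_a", ]), 1), "g; corr(a, log k):",
      round(posterior_mode(x$corr_a_logk), 3), "\n")
  cat("max R-hat:", round(max(x$diagnostics$rhat), 3), "\n")
  invisible(x)
}

#' Viability selection on predicted adult mass by year group
#'
#' From the interaction model, the logit-scale selection gradient on
#' predicted adult mass for a set of years is `gamma_mass +
#' gamma_interaction x days`, integrated over the posterior birth-date
#' distribution of the juveniles born in those years (per posterior
#' sample). Also returns survival-vs-mass curves per group.
#'
#' @param fit A `qg_growth`.
#' @param year_groups Named list of year vectors, e.g.
#'   `list(long = 2006:2007, short = 2008:2014)`.
#' @param a_grid Grid of predicted adult masses for the curves.
#' @return List per group: `slope` samples (logit/g), `summary`, `curve`
#'   (data.frame `a`, `survival`).
#' @export
selection_on_adult_mass <- function(fit, year_groups,
                                    a_grid = seq(25, 60, by = 1)) {
  stopifnot(inherits(fit, "qg_growth"))
  S <- ncol(fit$a)
  out <- list()
  for (nm in names(year_groups)) {
    jix <- which(fit$juveniles$year %in% year_groups[[nm]])
    if (!length(jix)) stop("no juveniles born in year group '", nm, "'")
    snow_i <- stats::setNames(fit$snow$first_snowfall_day, fit$snow$year)
    days <- sweep(-fit$t0[jix, , drop = FALSE], 1,
                  unname(snow_i[as.character(fit$juveniles$year[jix])]), `+`)
    mean_days <- colMeans(days)
    slope <- fit$gamma["mass", ] +
      (if (fit$use_snow) fit$gamma["mass_x_days", ] * mean_days else 0)
    curve <- vapply(a_grid, function(av) {
      eta <- fit$gamma["intercept", ] +
        fit$gamma["sexM", ] * mean(fit$juveniles$sex[jix] == "M") +
        fit$gamma["mass", ] * av +
        (if (fit$use_snow)
          fit$gamma["days", ] * mean_days +
            fit$gamma["mass_x_days", ] * av * mean_days else 0)
      mean(stats::plogis(eta))
    }, 0)
    out[[nm]] <- list(
      slope = slope,
      mean_days = mean(mean_days),
      n = length(jix),
      summary = data.frame(group = nm, mode = posterior_mode(slope),
                           lower = hpd(slope)[1], upper = hpd(slope)[2],
                           p_mcmc = p_mcmc(slope)),
      curve = data.frame(a = a_grid, survival = curve))
  }
  out
}

#' Snowmelt-to-first-birth phenology regression
#'
#' Regresses the earliest posterior-mean birth (conception) date of each
#' year on that year's snowmelt date and reports the mean onset lag with
#' its standard error. With no variation in snowmelt the slope is
#' undefined; the function warns and returns the mean lag only.
#'
#' @param fit A `qg_growth`.
#' @return List: `lag_mean`, `lag_se`, `slope`, `slope_p`, `per_year`
#'   (data.frame `year`, `snowmelt_day`, `earliest_birth`).
#' @export
phenology_regression <- function(fit) {
  stopifnot(inherits(fit, "qg_growth"))
  t0_mean <- rowMeans(fit$t0)
  yr <- fit$juveniles$year
  earliest <- tapply(t0_mean, yr, min)
  yrs <- as.integer(names(earliest))
  if (length(yrs) < 3) stop("need >= 3 years for the phenology regression")
  sm <- stats::setNames(fit$snow$snowmelt_day, fit$snow$year)[as.character(yrs)]
  lag <- unname(earliest) - unname(sm)
  out <- list(lag_mean = mean(lag), lag_se = stats::sd(lag) / sqrt(length(lag)),
              per_year = data.frame(year = yrs, snowmelt_day = unname(sm),
                                    earliest_birth = unname(earliest)))
  if (stats::sd(sm) == 0) {
    warning("snowmelt identical across years; slope undefined, ",
            "reporting mean lag only")
    out$slope <- NA_real_
    out$slope_p <- NA_real_
  } else {
    f <- stats::lm(unname(earliest) ~ unname(sm))
    out$slope <- unname(stats::coef(f)[2])
    out$slope_p <- summary(f)$coefficients[2, 4]
  }
  out
}

#' Predicted population-level change in juvenile survival
#'
#' Integrates the fitted survival curve over the observed joint
#' distribution of covariates (each juvenile's days-to-snowfall, sex),
#' shifting every predicted adult mass by `delta_a`, and returns the
#' posterior of the change in mean survival probability.
#'
#' @param fit A `qg_growth`.
#' @param delta_a Shift in predicted adult mass (g), e.g. a cohort-mean
#'   decline.
#' @return List: `samples` (change in survival probability), `mode`,
#'   `hpd`.
#' @export
population_survival_shift <- function(fit, delta_a) {
  stopifnot(inherits(fit, "qg_growth"))
  rng <- range(fit$a)
  if (abs(delta_a) > 2 * diff(rng)) {
    warning("delta_a far outside the observed support of predicted adult mass")
  }
  snow_i <- stats::setNames(fit$snow$first_snowfall_day, fit$snow$year)
  fsn <- unname(snow_i[as.character(fit$juveniles$year)])
  sexm <- as.numeric(fit$juveniles$sex == "M")
  S <- ncol(fit$a)
  delta <- numeric(S)
  for (s in seq_len(S)) {
    days <- fsn - fit$t0[, s]
    eta0 <- fit$gamma["intercept", s] + fit$gamma["sexM", s] * sexm +
      fit$gamma["mass", s] * fit$a[, s]
    etad <- fit$gamma["intercept", s] + fit$gamma["sexM", s] * sexm +
      fit$gamma["mass", s] * (fit$a[, s] + delta_a)
    if (fit$use_snow) {
      eta0 <- eta0 + fit$gamma["days", s] * days +
        fit$gamma["mass_x_days", s] * fit$a[, s] * days
      etad <- etad + fit$gamma["days", s] * days +
        fit$gamma["mass_x_days", s] * (fit$a[, s] + delta_a) * days
    }
    delta[s] <- mean(stats::plogis(etad)) - mean(stats::plogis(eta0))
  }
  list(samples = delta, mode = posterior_mode(delta), hpd = hpd(delta))
}

#' Posterior predictive checks for the growth/survival model
#'
#' Mass check: the sum of squared standardized mass residuals for observed
#' vs replicated data. Survival check: the Bernoulli deviance for observed
#' vs replicated outcomes. Tail probabilities near 0 or 1 indicate misfit;
#' a well-specified model gives values near 0.5.
#'
#' @param fit A `qg_growth`.
#' @return List: `ppp_mass`, `ppp_survival`.
#' @export
posterior_predictive_check <- function(fit) {
  stopifnot(inherits(fit, "qg_growth"))
  cap <- fit$captures
  jix <- match(cap$id, fit$juveniles$id)
  S <- ncol(fit$a)
  snow_i <- stats::setNames(fit$snow$first_snowfall_day, fit$snow$year)
  fsn <- unname(snow_i[as.character(fit$juveniles$year)])
  sexm <- as.numeric(fit$juveniles$sex == "M")
  surv <- fit$juveniles$survived
  exc_mass <- exc_surv <- logical(S)
  for (s in seq_len(S)) {
    mu <- fit$a[jix, s] * (1 - exp(-fit$k[jix, s] *
                                     (cap$julian_day - fit$t0[jix, s])))
    T_obs <- sum(((cap$mass - mu) / fit$meas_sd)^2)
    rep_mass <- mu + stats::rnorm(length(mu), 0, fit$meas_sd)
    T_rep <- sum(((rep_mass - mu) / fit$meas_sd)^2)
    exc_mass[s] <- T_rep >= T_obs
    days <- fsn - fit$t0[, s]
    eta <- fit$gamma["intercept", s] + fit$gamma["sexM", s] * sexm +
      fit$gamma["mass", s] * fit$a[, s]
    if (fit$use_snow) {
      eta <- eta + fit$gamma["days", s] * days +
        fit$gamma["mass_x_days", s] * fit$a[, s] * days
    }
    p <- stats::plogis(eta)
    dev_obs <- -2 * sum(ifelse(surv == 1, log(p), log1p(-p)))
    rep_surv <- stats::rbinom(length(p), 1, p)
    dev_rep <- -2 * sum(ifelse(rep_surv == 1, log(p), log1p(-p)))
    exc_surv[s] <- dev_rep >= dev_obs
  }
  list(ppp_mass = mean(exc_mass), ppp_survival = mean(exc_surv))
}
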
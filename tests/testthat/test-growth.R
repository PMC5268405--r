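# small growth fit reused across tests in this file
growth_fixture <- function() {
  if (!is.null(.growth_cache$fit)) return(.growth_cache)
  cfg <- sim_config(seed = 51, n_founders = 30, n_years = 6,
                    breeding_females = 16)
  sim <- simulate_study(cfg)
  juv <- sim$juveniles[sim$juveniles$n_captures > 0, ]
  surv <- data.frame(id = juv$id, sex = juv$sex, survived = juv$survived)
  fit <- fit_growth_survival(sim$captures, sim$snow, surv,
                             mcmc = growth_mcmc_settings(
                               n_iter = 6000, burnin = 2500, thin = 10,
                               n_chains = 1, seed = 2))
  .growth_cache$fit <- fit
  .growth_cache$sim <- sim
  .growth_cache$juv <- juv
  .growth_cache
}
.growth_cache <- new.env()

test_that("stored posterior states always satisfy the litter constraints", {
  gc_ <- growth_fixture()
  fit <- gc_$fit
  S <- dim(fit$tau)[3]
  for (s in seq_len(S)) {
    taus <- fit$tau[, , s]
    expect_true(all(diff(t(taus)) >= 20 - 1e-9))
  }
  # litter assignments are valid indices and each juvenile's t0 matches its
  # assigned litter's date
  expect_true(all(fit$litter >= 1 & fit$litter <= 5))
  for (s in seq_len(min(S, 25))) {
    t0s <- fit$tau[cbind(fit$juveniles$group, fit$litter[, s], s)]
    expect_equal(unname(fit$t0[, s]), unname(t0s))
  }
  # birth dates precede first captures
  min_day <- tapply(gc_$sim$captures$julian_day, gc_$sim$captures$id, min)
  min_day <- min_day[rownames(fit$t0)]
  expect_true(all(sweep(fit$t0, 1, min_day, `-`) < 0))
})

test_that("monomolecular curve is increasing with the asymptote as limit", {
  a <- 40; k <- 0.02; t0 <- 150
  t <- seq(151, 1500, by = 1)
  m <- a * (1 - exp(-k * (t - t0)))
  expect_true(all(diff(m) > 0))
  expect_lt(abs(m[length(m)] - a), 1e-8)
})

test_that("a single late capture with fast growth pins the asymptote", {
  # two juveniles observed essentially at their asymptote
  cap <- data.frame(id = c("j1", "j1", "j2", "j2"),
                    mother = c("m1", "m1", "m2", "m2"),
                    year = 2006,
                    julian_day = c(230, 250, 235, 255),
                    mass = c(38.2, 38.3, 45.0, 44.8))
  snow <- data.frame(year = 2006, snowmelt_day = 120,
                     first_snowfall_day = 280)
  surv <- data.frame(id = c("j1", "j2"), sex = c("F", "M"),
                     survived = c(1, 0))
  fit <- fit_growth_survival(cap, snow, surv, use_snow = FALSE,
                             hyper = c(42, 25, log(0.1), 0.01),
                             mcmc = growth_mcmc_settings(
                               n_iter = 4000, burnin = 1500, thin = 5,
                               n_chains = 1, seed = 4))
  expect_lt(abs(mean(fit$a["j1", ]) - 38.25), 3)
  expect_lt(abs(mean(fit$a["j2", ]) - 44.9), 3)
})

test_that("capture data inconsistent with the snow table is rejected", {
  cap <- data.frame(id = "j1", mother = "m1", year = 2006,
                    julian_day = 100, mass = 20)
  snow <- data.frame(year = 2006, snowmelt_day = 120,
                     first_snowfall_day = 280)
  surv <- data.frame(id = "j1", sex = "F", survived = 1)
  expect_error(fit_growth_survival(cap, snow, surv), "predate snowmelt")
  cap2 <- transform(cap, julian_day = 150, year = 2007)
  expect_error(fit_growth_survival(cap2, snow, surv), "does not cover")
})

test_that("growth parameters and survival selection are recovered", {
  gc_ <- growth_fixture()
  fit <- gc_$fit
  tr <- gc_$juv[match(rownames(fit$a), gc_$juv$id), ]
  # per-individual asymptote and birth-date coverage
  cov_a <- mean(vapply(seq_len(nrow(fit$a)), function(i) {
    h <- hpd(fit$a[i, ]); tr$a[i] >= h[1] && tr$a[i] <= h[2]
  }, TRUE))
  cov_t0 <- mean(vapply(seq_len(nrow(fit$t0)), function(i) {
    h <- hpd(fit$t0[i, ]); tr$t0[i] >= h[1] && tr$t0[i] <= h[2]
  }, TRUE))
  expect_gt(cov_a, 0.8)
  expect_gt(cov_t0, 0.75)
  # population scale
  expect_lt(abs(posterior_mode(fit$mu["mu_a", ]) - 41.7), 3)
  # survival regression: negative mass effect, positive interaction
  g <- gc_$sim$truth$config$growth
  hm <- hpd(fit$gamma["mass", ])
  expect_true(g$s_mass >= hm[1] - 0.15 && g$s_mass <= hm[2] + 0.15)
  expect_gt(posterior_mode(fit$gamma["mass_x_days", ]), 0)
})

test_that("year-group selection and phenology summaries work end to end", {
  gc_ <- growth_fixture()
  fit <- gc_$fit
  yrs <- sort(unique(gc_$sim$snow$year))
  sel <- selection_on_adult_mass(fit, list(long = yrs[1:2], short = yrs[-(1:2)]))
  expect_named(sel, c("long", "short"))
  expect_lt(sel$short$summary$mode, sel$long$summary$mode)
  expect_true(all(sel$long$curve$survival >= 0 & sel$long$curve$survival <= 1))
  expect_error(selection_on_adult_mass(fit, list(none = 1900)), "no juveniles")

  ph <- phenology_regression(fit)
  expect_true(is.finite(ph$lag_mean) && is.finite(ph$lag_se))
  expect_equal(nrow(ph$per_year), length(unique(gc_$juv$year)))
})

test_that("degenerate phenology design falls back to the mean lag", {
  gc_ <- growth_fixture()
  fit <- gc_$fit
  fit$snow$snowmelt_day <- 150  # no variation
  expect_warning(ph <- phenology_regression(fit), "slope undefined")
  expect_true(is.na(ph$slope))
  expect_true(is.finite(ph$lag_mean))
})

test_that("population survival shift is null when nothing shifts", {
  gc_ <- growth_fixture()
  fit <- gc_$fit
  expect_equal(population_survival_shift(fit, 0)$samples,
               rep(0, ncol(fit$a)))
  # mass-blind survival model: any shift changes nothing
  flat <- fit
  flat$gamma["mass", ] <- 0
  flat$gamma["mass_x_days", ] <- 0
  expect_equal(population_survival_shift(flat, -2)$samples,
               rep(0, ncol(fit$a)))
  expect_warning(population_survival_shift(fit, -1000), "outside")
})

test_that("posterior predictive checks flag gross misfit", {
  gc_ <- growth_fixture()
  fit <- gc_$fit
  ppc <- posterior_predictive_check(fit)
  expect_gt(ppc$ppp_mass, 0.01)
  expect_gt(ppc$ppp_survival, 0.01)
  shifted <- fit
  shifted$captures$mass <- shifted$captures$mass + 10
  ppc2 <- posterior_predictive_check(shifted)
  expect_lt(ppc2$ppp_mass, 0.01)
})

test_that("fits are invariant to capture row order", {
  gc_ <- growth_fixture()
  sim <- gc_$sim
  juv <- gc_$juv
  surv <- data.frame(id = juv$id, sex = juv$sex, survived = juv$survived)
  set.seed(123)
  cap_shuffled <- sim$captures[sample(nrow(sim$captures)), ]
  fit2 <- fit_growth_survival(cap_shuffled, sim$snow, surv,
                              mcmc = growth_mcmc_settings(
                                n_iter = 6000, burnin = 2500, thin = 10,
                                n_chains = 1, seed = 2))
  expect_equal(gc_$fit$t0, fit2$t0)
  expect_equal(gc_$fit$gamma, fit2$gamma)
})
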
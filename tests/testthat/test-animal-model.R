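# Conjugate oracle: one-way balanced random-effects model (unrelated
# individuals, repeated records). The marginal posterior of (V_A, V_R)
# after integrating the individual effects and a flat mean has a closed
# form evaluable on a grid; the Gibbs sampler must reproduce its moments.
grid_posterior_means <- function(y, ind, Vprior, nu) {
  ybar_i <- tapply(y, ind, mean)
  m <- as.integer(table(ind)[1])
  n <- length(ybar_i)
  SSW <- sum((y - ybar_i[ind])^2)
  SSB <- sum((ybar_i - mean(ybar_i))^2)
  va_grid <- seq(0.02, 12, length.out = 260)
  vr_grid <- seq(0.02, 12, length.out = 260)
  # log inverse-Wishart (1-D: scaled inverse chi-square) prior
  liw <- function(v) -(nu / 2 + 1) * log(v) - nu * Vprior / (2 * v)
  lp <- outer(va_grid, vr_grid, function(va, vr) {
    tau <- va + vr / m
    -(n * (m - 1)) / 2 * log(vr) - SSW / (2 * vr) -
      (n - 1) / 2 * log(tau) - SSB / (2 * tau) +
      liw(va) + liw(vr)
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  c(va = sum(outer(va_grid, rep(1, length(vr_grid))) * w),
    vr = sum(outer(rep(1, length(va_grid)), vr_grid) * w))
}

test_that("Gibbs sampler matches the conjugate grid posterior", {
  set.seed(31)
  n <- 60; m <- 3
  ids <- sprintf("i%02d", seq_len(n))
  a_true <- stats::rnorm(n, 0, sqrt(2))
  ped <- validate_pedigree(data.frame(
    id = ids, sire = NA, dam = NA,
    sex = rep(c("M", "F"), length.out = n), cohort = 2000))
  ph <- data.frame(
    id = rep(ids, each = m), year = 2001,
    julian_day = rep(c(150, 180, 210), n),
    age_class = "adult", sex = rep(rep(c("M", "F"), length.out = n), each = m),
    mass = 10 + rep(a_true, each = m) + stats::rnorm(n * m, 0, 1))
  pr <- default_prior(c(mass = 3), n_terms = 3, px = FALSE)
  pr$G$V <- matrix(1, 1, 1); pr$G$nu <- 1
  pr$R$V <- matrix(1, 1, 1); pr$R$nu <- 1
  fit <- fit_animal_model(ph, ped, traits = "mass", random = character(0),
                          fixed_formula = ~1, prior = pr,
                          mcmc = mcmc_settings(30000, 5000, 10, seed = 3))
  oracle <- grid_posterior_means(ph$mass, ph$id, Vprior = 1, nu = 1)
  va <- fit$G[1, 1, ]
  vr <- fit$R[1, 1, ]
  mcse_va <- stats::sd(va) / sqrt(unname(coda::effectiveSize(coda::mcmc(va))))
  mcse_vr <- stats::sd(vr) / sqrt(unname(coda::effectiveSize(coda::mcmc(vr))))
  expect_lt(abs(mean(va) - oracle["va"]), 4 * mcse_va + 0.05)
  expect_lt(abs(mean(vr) - oracle["vr"]), 4 * mcse_vr + 0.05)
})

test_that("posterior summaries are invariant to input row order", {
  sim <- simulate_study(tiny_config(seed = 21))
  ph <- sim$phenotypes
  fit1 <- fit_animal_model(ph, sim$pedigree, traits = "mass",
                           mcmc = fast_mcmc(seed = 5))
  set.seed(99)
  fit2 <- fit_animal_model(ph[sample(nrow(ph)), ], sim$pedigree,
                           traits = "mass", mcmc = fast_mcmc(seed = 5))
  expect_equal(fit1$G, fit2$G)
  expect_equal(fit1$bv, fit2$bv)
})

test_that("posterior_mode behaves on reference shapes", {
  set.seed(1)
  x <- stats::rnorm(5000)
  expect_lt(abs(posterior_mode(x) - mean(x)), 0.15)
  expect_equal(posterior_mode(rep(3.7, 200)), 3.7)
  g <- stats::rgamma(10000, shape = 2, rate = 1)
  # analytic mode (k-1)/rate = 1; KDE smoothing shifts skewed modes a bit
  expect_lt(abs(posterior_mode(g) - 1), 0.2)
  expect_warning(posterior_mode(stats::rnorm(50)), "imprecise")
  expect_error(posterior_mode(stats::rnorm(50), strict = TRUE), "imprecise")
})

test_that("heritability and genetic correlation identities hold", {
  k <- 2
  S <- 200
  G <- array(0, c(k, k, S), dimnames = list(c("m", "w"), c("m", "w"), NULL))
  R <- G
  G[1, 1, ] <- 1; G[2, 2, ] <- 1
  R[1, 1, ] <- 1; R[2, 2, ] <- 1
  f <- fake_fit(G, R = R, random = character(0))
  h <- heritability(f, "m")
  expect_true(all(h$samples == 0.5))

  rho <- genetic_correlation(f, c("m", "w"))
  expect_true(all(rho$samples == 0))
  expect_equal(rho$n_skipped, 0)
  expect_error(heritability(f, "zz"), "not in model")
})

test_that("null additive variance is recovered as a boundary posterior", {
  cfg <- tiny_config(seed = 23)
  cfg$G[] <- 0  # no genetic variance in any trait
  sim <- simulate_study(cfg)
  fit <- fit_animal_model(sim$phenotypes, sim$pedigree, traits = "mass",
                          mcmc = fast_mcmc(seed = 7, n_iter = 10000,
                                           burnin = 3000))
  h2 <- heritability(fit, "mass")
  expect_lt(h2$mode, 0.05)
  expect_lt(h2$hpd[1], 0.01)
})

test_that("variance components are recovered on a synthetic study", {
  sim <- simulate_study(sim_config(seed = 5, n_founders = 40,
                                   breeding_females = 22, n_sessions = 3,
                                   selection = FALSE))
  fit <- fit_animal_model(sim$phenotypes, sim$pedigree, traits = "mass",
                          mcmc = mcmc_settings(16000, 4000, 12, seed = 2))
  va <- fit$G[1, 1, ]
  expect_gt(4.34, hpd(va)[1])
  expect_lt(4.34, hpd(va)[2])
  expect_lt(abs(posterior_mode(fit$R[1, 1, ]) - 13.5), 4)
  # founder breeding values have variance near the sampled V_A
  founders <- sim$pedigree$id[is.na(sim$pedigree$sire)]
  vf <- mean(apply(fit$bv[founders, 1, ], 2, stats::var))
  expect_lt(abs(vf - mean(va)) / mean(va), 0.5)
  # chain diagnostics are reported
  expect_true(all(is.finite(fit$diagnostics$lag1_autocorrelation)))
})

test_that("aliased fixed-effect designs raise an identifiability error", {
  sim <- simulate_study(tiny_config(seed = 25))
  ph <- sim$phenotypes
  ph$dup <- ph$julian_day  # alias of the date covariate
  expect_error(
    fit_animal_model(ph, sim$pedigree, traits = "mass",
                     fixed_formula = ~ date_s + I(date_s * 1.0),
                     mcmc = fast_mcmc()),
    "aliased")
})

test_that("individuals missing from the pedigree are reported", {
  sim <- simulate_study(tiny_config(seed = 26))
  ph <- sim$phenotypes
  ph$id[1] <- "stranger"
  expect_error(fit_animal_model(ph, sim$pedigree, traits = "mass",
                                mcmc = fast_mcmc()),
               "absent from pedigree")
})
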
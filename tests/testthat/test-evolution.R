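test_that("Price genetic change is the scaled genetic differential", {
  tr <- c("mass", "omega")
  S <- 120
  G <- array(0, c(2, 2, S), dimnames = list(tr, tr, NULL))
  G[1, 1, ] <- 4; G[2, 2, ] <- 0.1
  G[1, 2, ] <- G[2, 1, ] <- -0.35
  f <- fake_fit(G, random = character(0))
  pc <- price_genetic_change(f, "mass", T_gen = 1.2)
  expect_equal(pc$per_year, pc$per_generation / 1.2, tolerance = 1e-15)
  expect_equal(unique(pc$per_generation), -0.35)
  expect_equal(pc$mode, -0.35 / 1.2, tolerance = 1e-6)
  expect_error(price_genetic_change(f, "mass", T_gen = -1), "positive")
})

test_that("breeding-value trend equals the truth-ledger trend exactly", {
  sim <- simulate_study(tiny_config(seed = 41))
  ped <- sim$pedigree
  bv_true <- sim$truth$bv[, "mass"]
  # direct least squares on cohort means of the true breeding values
  cm <- tapply(bv_true, ped$cohort, mean)
  yrs <- as.numeric(names(cm))
  direct <- unname(stats::coef(stats::lm(cm ~ yrs))[2])
  # a posterior that is a point mass at the truth must return that slope
  S <- 120
  bv_arr <- array(rep(cbind(bv_true, 0), S),
                  dim = c(nrow(ped), 2, S),
                  dimnames = list(ped$id, c("mass", "omega"), NULL))
  G <- array(1, c(2, 2, S),
             dimnames = list(c("mass", "omega"), c("mass", "omega"), NULL))
  f <- fake_fit(G, bv = bv_arr,
                cohorts = stats::setNames(ped$cohort, ped$id))
  tr <- blup_trend(f, "mass")
  expect_equal(unique(round(tr$slopes, 12)), round(direct, 12))
  expect_equal(tr$p_mcmc, 1 / S)  # every sample on one side of zero

  # all-zero breeding values give a zero slope
  f0 <- fake_fit(G, bv = 0 * bv_arr,
                 cohorts = stats::setNames(ped$cohort, ped$id))
  expect_equal(unique(blup_trend(f0, "mass")$slopes), 0)

  # fewer than three cohorts is an error
  few <- stats::setNames(rep(c(2000, 2001), length.out = nrow(ped)), ped$id)
  ff <- fake_fit(G, bv = bv_arr, cohorts = few)
  expect_error(blup_trend(ff, "mass"), "3 cohorts")
})

test_that("gene dropping with zero variance yields exactly zero slopes", {
  ped <- random_pedigree(n_founders = 12, n_gen = 4, per_gen = 15, seed = 4)
  dn <- gene_drop_drift(ped, va_samples = rep(0, 50), n_sims = 50, seed = 1)
  expect_true(all(dn$drift_slopes == 0))
  expect_error(gene_drop_drift(ped, numeric(0)), "empty")
})

test_that("drift null is mean zero with the closed-form founder variance", {
  # founders spread over cohorts: independent N(0, va/n_c) cohort means
  n_per <- 40
  yrs <- 2000:2004
  fo <- validate_pedigree(data.frame(
    id = sprintf("f%03d", seq_len(n_per * length(yrs))),
    sire = NA, dam = NA,
    sex = rep(c("M", "F"), length.out = n_per * length(yrs)),
    cohort = rep(yrs, each = n_per)))
  va <- 4
  n_sims <- 1000
  dn <- gene_drop_drift(fo, va_samples = rep(va, n_sims), n_sims = n_sims,
                        seed = 2)
  # slope = w' m with w from the regression design, m ~ N(0, va/n_per)
  X <- cbind(1, yrs)
  w <- (solve(crossprod(X)) %*% t(X))[2, ]
  var_slope <- sum(w^2) * va / n_per
  expect_lt(abs(mean(dn$drift_slopes)), 3 * sqrt(var_slope / n_sims))
  # chi-square bounds on the realized variance
  rel_se <- sqrt(2 / (n_sims - 1))
  expect_lt(abs(stats::var(dn$drift_slopes) - var_slope),
            4 * rel_se * var_slope)
})

test_that("paired drift comparison orients its tail to the observed sign", {
  ped <- random_pedigree(n_founders = 12, n_gen = 4, per_gen = 15, seed = 6)
  obs <- rep(-0.5, 400)  # strong negative observed change
  dn <- gene_drop_drift(ped, va_samples = rep(1, 400),
                        observed_slopes = obs, n_sims = 400, seed = 3)
  expect_equal(dn$direction, -1)
  expect_lt(dn$p_drift, 0.05)
  dn2 <- gene_drop_drift(ped, va_samples = rep(1, 400),
                         observed_slopes = rep(0, 400), n_sims = 400,
                         seed = 3, tail = "two")
  expect_gt(dn2$p_drift, 0.5)
})

test_that("Darwin conversion follows its definition", {
  expect_equal(to_darwins(0, 41.7)$darwins, 0)
  d <- to_darwins(-0.29, 41.7)
  expect_equal(d$darwins, abs(log((41.7 - 0.29) / 41.7)) * 1e6)
  expect_true(d$darwins > 6.5e3 && d$darwins < 7.5e3)
  expect_match(d$formula, "1e6")
  expect_error(to_darwins(0.1, -1), "positive")
})

test_that("realized genetic change equals the Robertson covariance identity", {
  # one generation of reproduction with fitness-weighted mating: the
  # offspring mean breeding value must equal the parental mean plus the
  # sex-averaged covariance between breeding value and relative realized
  # reproductive success, up to Mendelian sampling noise
  cfg <- sim_config(seed = 47, n_founders = 300, n_years = 1,
                    breeding_females = 1000, young_breeding_prob = 0,
                    selection = TRUE)
  sim <- simulate_pedigree(cfg)
  ped <- sim$pedigree
  bv <- sim$truth$bv[, "mass"]
  founders <- is.na(ped$sire) & is.na(ped$dam)
  kids <- !founders
  expect_gt(sum(kids), 100)
  counts <- table(c(ped$sire[kids], ped$dam[kids]))
  cnt <- stats::setNames(rep(0, sum(founders)), ped$id[founders])
  cnt[names(counts)] <- as.numeric(counts)
  sexf <- ped$sex[founders]
  idsf <- ped$id[founders]
  terms <- vapply(c("F", "M"), function(sx) {
    sel <- sexf == sx
    w <- cnt[idsf[sel]] / mean(cnt[idsf[sel]])
    mean(bv[idsf[sel]] * w) - mean(bv[idsf[sel]])
  }, 0)
  predicted_delta <- mean(bv[ped$id[founders]]) + sum(terms) / 2
  observed <- mean(bv[ped$id[kids]])
  mend_se <- sqrt(cfg$G[1, 1] / 2 / sum(kids))
  expect_lt(abs(observed - predicted_delta), 4 * mend_se)
  # and selection did act: the covariance term is materially negative
  expect_lt(sum(terms) / 2, -0.05)
})
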
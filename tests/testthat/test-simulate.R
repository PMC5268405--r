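test_that("simulation is fully deterministic under a fixed seed", {
  s1 <- simulate_study(tiny_config(seed = 11))
  s2 <- simulate_study(tiny_config(seed = 11))
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$captures, s2$captures)
  expect_identical(s1$fitness, s2$fitness)
  expect_identical(s1$truth$bv, s2$truth$bv)
  s3 <- simulate_study(tiny_config(seed = 12))
  expect_false(identical(s1$phenotypes, s3$phenotypes))
})

test_that("no recruitment and full survival leaves founders only", {
  cfg <- tiny_config(seed = 1, breeding_females = 0, adult_survival = 1,
                     young_breeding_prob = 0)
  sim <- simulate_pedigree(cfg)
  expect_equal(nrow(sim$pedigree), cfg$n_founders)
  expect_true(all(is.na(sim$pedigree$sire)))
})

test_that("generated litters always respect spacing and count constraints", {
  sim <- simulate_study(sim_config(seed = 2))
  lt <- sim$truth$litters
  for (key in unique(paste(lt$mother, lt$year))) {
    g <- lt[paste(lt$mother, lt$year) == key, ]
    expect_lte(nrow(g), 5)
    if (nrow(g) > 1) expect_true(all(diff(sort(g$t0)) >= 20))
  }
  # conceptions fall inside the snow-free season with the configured lag
  snow <- sim$snow
  for (i in seq_len(nrow(lt))) {
    sm <- snow$snowmelt_day[snow$year == lt$year[i]]
    fs <- snow$first_snowfall_day[snow$year == lt$year[i]]
    expect_gte(lt$t0[i], sm + sim$truth$config$snow$birth_lag - 1e-9)
    expect_lte(lt$t0[i], fs - 10 + 1e-9)
  }
})

test_that("pedigree link counts equal the generator's litter ledger", {
  sim <- simulate_study(tiny_config(seed = 3))
  ped <- sim$pedigree
  expect_equal(attr(ped, "n_maternities"), sum(sim$truth$litters$size))
  expect_equal(attr(ped, "n_paternities"), sum(sim$truth$litters$size))
  # every generated table passes its reader schema
  expect_s3_class(validate_pedigree(as.data.frame(ped)), "qg_pedigree")
})

test_that("breeding-value dropping has the right moments", {
  fo <- validate_pedigree(data.frame(
    id = sprintf("f%04d", 1:2000),
    sire = NA, dam = NA,
    sex = rep(c("M", "F"), 1000), cohort = 2000))
  bv <- simulate_breeding_values(fo, matrix(4, 1, 1), seed = 1)
  # founder variance: chi-square sampling bounds, 3 SE
  se <- 4 * sqrt(2 / (2000 - 1))
  expect_lt(abs(stats::var(bv[, 1]) - 4), 3 * se)

  # zero G gives exactly zero breeding values
  bv0 <- simulate_breeding_values(fo, matrix(0, 1, 1), seed = 1)
  expect_true(all(bv0 == 0))

  # parent-offspring covariance = A_po * V_A over 5000 replicate trios
  n <- 5000
  trios <- data.frame(
    id = c(sprintf("s%d", 1:n), sprintf("d%d", 1:n), sprintf("o%d", 1:n)),
    sire = c(rep(NA, 2 * n), sprintf("s%d", 1:n)),
    dam = c(rep(NA, 2 * n), sprintf("d%d", 1:n)),
    sex = c(rep("M", n), rep("F", n), rep("F", n)),
    cohort = c(rep(2000, 2 * n), rep(2001, n)))
  tp <- validate_pedigree(trios)
  bvt <- simulate_breeding_values(tp, matrix(4, 1, 1), seed = 2)
  sires <- bvt[sprintf("s%d", 1:n), 1]
  offs <- bvt[sprintf("o%d", 1:n), 1]
  # cov = 0.5 * 4 = 2; MC SE of a covariance of bivariate normals
  se_cov <- sqrt((4 * 4 + 2^2) / n)
  expect_lt(abs(stats::cov(sires, offs) - 2), 3 * se_cov)
  # offspring variance also V_A
  expect_lt(abs(stats::var(offs) - 4), 3 * 4 * sqrt(2 / n))

  # non-PSD G is refused
  badG <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulate_breeding_values(fo, badG), "positive semi-definite")
})

test_that("phenotypes collapse to fixed effects when all variances vanish", {
  k <- 4
  zero <- matrix(0, k, k)
  fx <- c(intercept_mass = 40, intercept_length = 100, intercept_tail = 60,
          intercept_fitness = 1,
          sexM_mass = 0, sexM_length = 0, sexM_tail = 0,
          age_juv_mass = 0, age_juv_length = 0, age_juv_tail = 0,
          date_mass = 0, date2_mass = 0, date_length = 0, date2_length = 0,
          date_tail = 0, date2_tail = 0)
  cfg <- tiny_config(seed = 4, G = zero, M_cov = zero, P_cov = zero,
                     Y_cov = zero, R_cov = zero, fixed = fx)
  sim <- simulate_phenotypes_fitness(simulate_pedigree(cfg))
  expect_true(all(sim$phenotypes$mass == 40))
  expect_true(all(sim$phenotypes$body_length == 100))

  # additive sex effect appears exactly when it is the only term
  fx2 <- fx
  fx2["sexM_mass"] <- 4
  cfg2 <- tiny_config(seed = 4, G = zero, M_cov = zero, P_cov = zero,
                      Y_cov = zero, R_cov = zero, fixed = fx2)
  sim2 <- simulate_phenotypes_fitness(simulate_pedigree(cfg2))
  m <- tapply(sim2$phenotypes$mass, sim2$phenotypes$sex, mean)
  expect_equal(unname(m["M"] - m["F"]), 4)
})

test_that("generating trait-fitness covariances are realized in the truth", {
  cfg <- sim_config(seed = 6, n_founders = 400, n_years = 1,
                    breeding_females = 0)
  sim <- simulate_pedigree(cfg)
  bv <- sim$truth$bv
  # founders: cov(BV_mass, BV_fitness) targets G[mass, fitness] = -0.35
  se <- sqrt((cfg$G[1, 1] * cfg$G[4, 4] + cfg$G[1, 4]^2) / 400)
  expect_lt(abs(stats::cov(bv[, "mass"], bv[, "fitness"]) -
                  cfg$G["mass", "fitness"]), 3 * se)
  # total latent fitness covariance adds the permanent-environment part
  w <- sim$truth$w
  var_w <- cfg$G[4, 4] + cfg$P_cov[4, 4]
  se_w <- sqrt((cfg$G[1, 1] * var_w + cfg$G[1, 4]^2) / 400)
  expect_lt(abs(stats::cov(bv[, "mass"], w) - cfg$G["mass", "fitness"]),
            3 * se_w)
})

test_that("growth histories hit the asymptote when noise vanishes", {
  g <- list(a_mean = 41.7, a_sd = 5.2, logk_mean = log(1), logk_sd = 0,
            corr_a_logk = 0, measurement_sd = 0, emergence_lag = 25,
            s_intercept = 0, s_sex = 0, s_mass = 0, s_days = 0,
            s_interaction = 0)
  sim <- simulate_study(tiny_config(seed = 8, growth = g))
  juv <- sim$juveniles
  cap <- sim$captures
  a_of <- stats::setNames(juv$a, juv$id)
  # masses are stored to 0.01 g
  expect_lt(max(abs(cap$mass - a_of[cap$id])), 0.0051)
  # neutral survival coefficients: survival independent of a
  fitglm <- stats::glm(survived ~ a, family = stats::binomial(),
                       data = juv)
  ci <- suppressMessages(stats::confint(fitglm, "a"))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("infeasible snow seasons are rejected at configuration", {
  expect_error(tiny_config(snow = list(snowmelt_long = 200,
                                       snowmelt_short = 200,
                                       first_snow_long = 150,
                                       first_snow_short = 260,
                                       n_long_years = 2, birth_lag = 40,
                                       litter_spread = 30)),
               "snowfall")
  expect_error(tiny_config(snow = list(snowmelt_long = 120,
                                       snowmelt_short = 150,
                                       first_snow_long = 285,
                                       first_snow_short = 185,
                                       n_long_years = 2, birth_lag = 40,
                                       litter_spread = 30)),
               "season too short")
})

test_that("written study files round-trip", {
  sim <- simulate_study(tiny_config(seed = 9))
  dir <- tempfile()
  write_sim_data(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("pedigree.csv", "phenotypes.csv", "fitness.csv",
           "captures.csv", "snow.csv", "truth.json")))))
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(nrow(ped), nrow(sim$pedigree))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$seed, 9)
})
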
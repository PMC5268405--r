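test_that("relativize_fitness divides by sex-by-group cell means", {
  df <- data.frame(id = c("a", "b"), sex = "F", cohort = 2000,
                   lrs = c(0, 2))
  out <- relativize_fitness(df, "lrs", by = "cohort")
  expect_equal(out$relative, c(0, 2))

  df2 <- data.frame(id = letters[1:6], sex = rep(c("F", "M"), 3),
                    cohort = rep(2000:2002, each = 2), lrs = 5)
  expect_true(all(relativize_fitness(df2, "lrs")$relative == 1))

  # per-cell mean is exactly 1 on a generated fitness table
  sim <- simulate_study(tiny_config(seed = 31))
  lr <- sim$lrs
  lr <- lr[ave(lr$lrs, paste(lr$sex, lr$cohort), FUN = mean) > 0, ]
  rel <- relativize_fitness(lr, "lrs", by = "cohort")
  cellmeans <- tapply(rel$relative, paste(rel$sex, rel$cohort), mean)
  expect_true(all(abs(cellmeans - 1) < 1e-12))

  # idempotence
  rel2 <- relativize_fitness(transform(rel, lrs = relative), "lrs")
  expect_equal(rel2$relative, rel$relative)

  # all-zero cell is an explicit error
  dead <- data.frame(id = c("x", "y"), sex = "M", cohort = 1999, lrs = 0)
  expect_error(relativize_fitness(rbind(df, dead), "lrs"), "all-zero")
})

# fabricated posterior arrays with known structure
make_sel_fit <- function(S = 150, seed = 7) {
  set.seed(seed)
  tr <- c("mass", "body_length", "tail_length", "omega")
  k <- 4
  G <- array(0, c(k, k, S), dimnames = list(tr, tr, NULL))
  M <- G; P <- G; Y <- G; R <- G
  for (s in seq_len(S)) {
    G[, , s] <- diag(c(4, 10, 6, 0.1))
    P[, , s] <- diag(c(6, 8, 5, 1.5))
    R[, , s] <- diag(c(13, 15, 9, 0))
    M[, , s] <- diag(c(1.5, 2, 1, 0.02))
    Y[, , s] <- diag(c(2, 2, 1, 0))
    G["mass", "omega", s] <- G["omega", "mass", s] <- -0.3 + 0.02 * stats::rnorm(1)
    P["mass", "omega", s] <- P["omega", "mass", s] <- 1.2 + 0.02 * stats::rnorm(1)
  }
  fake_fit(G, M = M, P = P, Y = Y, R = R)
}

test_that("selection differential decomposes exactly per sample", {
  f <- make_sel_fit()
  sd_ <- selection_differential(f, "mass")
  expect_equal(sd_$sigma_P, sd_$sigma_A + sd_$sigma_E, tolerance = 1e-15)
  expect_equal(sd_$sigma_A, f$G["mass", "omega", ])
  # year-level covariance is excluded by construction
  f2 <- make_sel_fit()
  f2$Y["mass", "omega", ] <- 5
  sd2 <- selection_differential(f2, "mass")
  expect_equal(sd2$sigma_P, sd_$sigma_P, tolerance = 1e-12)
})

test_that("selection gradients reduce to S/VP for diagonal covariances", {
  f <- make_sel_fit()
  sg <- selection_gradients(f)
  s <- 1
  vp_mass <- 4 + 6 + 13  # G' + P' + R' diagonal entry
  expect_equal(unname(sg$samples["mass", s]),
               unname(sg$S["mass", s] / vp_mass), tolerance = 1e-12)
  expect_equal(sg$n_skipped, 0)
  # identity covariances and S = (1, 0, 0) give beta = S
  tr <- c("m", "l", "t", "w")
  S <- 120
  G <- array(0, c(4, 4, S), dimnames = list(tr, tr, NULL))
  for (s in seq_len(S)) G[, , s] <- diag(c(1, 1, 1, 1) / 3)
  G[1, 4, ] <- G[4, 1, ] <- 1 / 3
  f2 <- fake_fit(G, P = G, R = G, random = c("pe"))
  sg2 <- selection_gradients(f2, fitness_trait = "w")
  expect_equal(unname(sg2$samples[, 1]), c(1, 0, 0), tolerance = 1e-12)
})

test_that("response predictions agree across forms when correlations vanish", {
  f <- make_sel_fit()
  T_gen <- 1.2
  ube <- predict_response(f, "UBE", T_gen = T_gen)
  mbe <- predict_response(f, "MBE", T_gen = T_gen)
  mbe0 <- predict_response(f, "MBE_rho0", T_gen = T_gen)
  price <- predict_response(f, "Price", T_gen = T_gen)
  # diagonal G': MBE and MBE_rho0 identical sample by sample
  expect_equal(mbe$per_generation, mbe0$per_generation, tolerance = 1e-12)
  # trait-wise MBE = V_A * beta
  sg <- selection_gradients(f)
  expect_equal(mbe$per_generation["mass", 1],
               4 * sg$samples["mass", 1], tolerance = 1e-12)
  # Price = sigma_A(z, omega)
  expect_equal(price$per_generation["mass", ], f$G["mass", "omega", ])
  # per-year = per-generation / T for every sample of every estimator
  for (r in list(ube, mbe, mbe0, price)) {
    expect_equal(r$per_year, r$per_generation / T_gen, tolerance = 1e-15)
  }
  expect_error(predict_response(f, "UBE", T_gen = 0), "positive")
})

test_that("UBE equals h2 * S sample by sample", {
  f <- make_sel_fit()
  ube <- predict_response(f, "UBE", T_gen = 1)
  h2 <- heritability(f, "mass")$samples
  sd_ <- selection_differential(f, "mass")
  expect_equal(ube$per_generation["mass", ], h2 * sd_$sigma_P,
               tolerance = 1e-12)
})

test_that("component decomposition recovers the juvenile viability signal", {
  # strong genetic viability selection against heavy juveniles, none in
  # adults; expect a negative genetic covariance for the juvenile component
  cfg <- sim_config(seed = 33, n_founders = 40, breeding_females = 22,
                    n_sessions = 3,
                    viability = list(juv_slope = -0.25, adult_slope = 0))
  sim <- simulate_study(cfg)
  dec <- decompose_by_component(sim$phenotypes, sim$fitness, sim$pedigree,
                                component = "phi_juv",
                                mcmc = fast_mcmc(seed = 3, n_iter = 9000,
                                                 burnin = 3000))
  expect_lt(dec$summary$mode[dec$summary$component == "sigma_A"], 0.02)
  expect_equal(dec$sigma_P, dec$sigma_A + dec$sigma_E, tolerance = 1e-12)

  # constant survival: nothing to covary with
  fa <- sim$fitness
  fa$survived <- 1L
  dec0 <- decompose_by_component(sim$phenotypes, fa, sim$pedigree,
                                 component = "phi_juv",
                                 mcmc = fast_mcmc(seed = 4))
  expect_lt(abs(dec0$summary$mode[dec0$summary$component == "sigma_P"]),
            0.25)
  hp <- hpd(dec0$sigma_P)
  expect_true(hp[1] < 0 && hp[2] > 0)

  # data-sufficiency floor
  expect_error(
    decompose_by_component(sim$phenotypes, sim$fitness, sim$pedigree,
                           component = "ARS_M", min_n = 1e6),
    "fewer than")
})
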
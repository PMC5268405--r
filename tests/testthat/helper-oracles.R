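# Test helpers: small fixtures and independent oracles.

# minimal sire/dam/offspring trio
trio_table <- function() {
  data.frame(id = c("s1", "d1", "o1"),
             sire = c(NA, NA, "s1"), dam = c(NA, NA, "d1"),
             sex = c("M", "F", "F"), cohort = c(2000, 2000, 2001))
}

# random pedigree with n_founders founders and n_gen discrete generations;
# parents drawn within the previous generation (inbreeding arises naturally)
random_pedigree <- function(n_founders = 10, n_gen = 4, per_gen = 12,
                            seed = 1) {
  set.seed(seed)
  id <- paste0("f", seq_len(n_founders))
  sex <- rep(c("M", "F"), length.out = n_founders)
  sire <- dam <- rep(NA_character_, n_founders)
  cohort <- rep(2000L, n_founders)
  prev <- data.frame(id = id, sex = sex, stringsAsFactors = FALSE)
  for (g in seq_len(n_gen)) {
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (!length(males) || !length(females)) break
    nid <- paste0("g", g, "_", seq_len(per_gen))
    nsex <- sample(c("M", "F"), per_gen, replace = TRUE)
    id <- c(id, nid)
    sex <- c(sex, nsex)
    sire <- c(sire, sample(males, per_gen, replace = TRUE))
    dam <- c(dam, sample(females, per_gen, replace = TRUE))
    cohort <- c(cohort, rep(2000L + g, per_gen))
    prev <- data.frame(id = nid, sex = nsex, stringsAsFactors = FALSE)
  }
  validate_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                               cohort = cohort, stringsAsFactors = FALSE))
}

# independent oracle: expected relatedness from discrete gene dropping
# (allele-sharing probabilities over n_rep replicate transmissions)
gene_drop_relatedness <- function(ped, n_rep = 50000, seed = 42) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- attr(ped, "index")
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  # allele ids per individual x replicate (two gametes)
  A1 <- matrix(0L, n, n_rep)
  A2 <- matrix(0L, n, n_rep)
  next_allele <- 0L
  for (i in seq_len(n)) {
    if (si[i] == 0L) {
      A1[i, ] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      A1[i, ] <- ifelse(pick, A1[si[i], ], A2[si[i], ])
    }
    if (di[i] == 0L) {
      A2[i, ] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      A2[i, ] <- ifelse(pick, A1[di[i], ], A2[di[i], ])
    }
  }
  kin <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      sh <- (A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
        (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])
      if (i == j) {
        # kinship with self: (1 + F)/2, F = P(the two own alleles IBD)
        f <- mean(A1[i, ] == A2[i, ])
        kin[i, i] <- (1 + f) / 2
      } else {
        kin[i, j] <- kin[j, i] <- mean(sh) / 4
      }
    }
  }
  2 * kin  # numerator relationship
}

# independent oracle: kinship coefficients by the recursive definition
# f(i,j) = (f(sire_i, j) + f(dam_i, j)) / 2 for i later than j
kinship_recursive <- function(ped) {
  n <- nrow(ped)
  idx <- attr(ped, "index")
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      v <- 0
      if (si[i] > 0L) v <- v + 0.5 * f[si[i], j]
      if (di[i] > 0L) v <- v + 0.5 * f[di[i], j]
      f[i, j] <- f[j, i] <- v
    }
    fij <- if (si[i] > 0L && di[i] > 0L) f[si[i], di[i]] else 0
    f[i, i] <- 0.5 * (1 + fij)
  }
  f
}

# fabricate a qg_animal_model-shaped object with given covariance arrays
fake_fit <- function(G, M = NULL, P = NULL, Y = NULL, R = NULL,
                     traits = dimnames(G)[[1]], bv = NULL, cohorts = NULL,
                     random = c("maternal", "pe", "year")) {
  k <- dim(G)[1]
  S <- dim(G)[3]
  zero <- array(0, dim = c(k, k, S), dimnames = dimnames(G))
  out <- list(G = G, M = M %||% zero, P = P %||% zero, Y = Y %||% zero,
              R = R %||% zero, traits = traits, random = random,
              bv = bv, cohorts = cohorts,
              year_levels = NULL, n_records = 0)
  class(out) <- "qg_animal_model"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared fits across acceptance blocks (computed once, reused)
.acc_cache <- new.env()

# small, fast simulation config for tests (dots override the tiny defaults)
tiny_config <- function(seed = 1, ...) {
  args <- list(n_founders = 24, n_years = 5, breeding_females = 14,
               n_sessions = 3, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

fast_mcmc <- function(seed = 1, n_iter = 6000, burnin = 2000, thin = 8) {
  mcmc_settings(n_iter = n_iter, burnin = burnin, thin = thin, seed = seed)
}
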
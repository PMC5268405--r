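#' Configuration for the synthetic snow-vole-style study generator
#'
#' Builds the parameter set for a complete simulated monitoring study:
#' an overlapping-generations pedigree, multi-level trait/fitness
#' (co)variances, monomolecular juvenile growth with litter structure, and
#' snowfall-dependent overwinter viability selection. Defaults target the
#' scale and the published point estimates of a nine-year alpine rodent
#' study (~900 individuals, mean adult mass 41.7 g, additive variance
#' 4.34 g^2, genetic mass-fitness covariance -0.35 g, phenotypic selection
#' differential +0.86 g, measurement error SD 2.05 g, 40-day lag between
#' snowmelt and first conception, survival interaction 0.0025 per g per day).
#' Where the study system gives no number (litter-size and litters-per-year
#' distributions, adult survival), defaults are the package's own choices of
#' realistic rodent demography and are documented as such.
#'
#' All covariance matrices are over the trait vector
#' `c("mass", "length", "tail", "fitness")`, in that order. The
#' environmental mass-fitness covariance is injected at the
#' permanent-environment level and fitness has zero residual and
#' (essentially) zero year variance, matching the modelling convention that
#' relative fitness is measured once per individual with its nonadditive
#' variance carried by the permanent-environment term.
#'
#' @param n_founders Number of founders (half of each sex).
#' @param n_years Number of monitored breeding seasons (cohorts).
#' @param start_year Calendar year of the first cohort.
#' @param seed Integer seed; fully determines every generated dataset.
#' @param G,M_cov,P_cov,Y_cov,R_cov 4x4 (co)variance matrices for the
#'   additive-genetic, maternal, permanent-environment, year and residual
#'   levels.
#' @param fixed Named fixed-effect coefficients (intercepts per trait, sex
#'   and age contrasts, linear/quadratic Julian-date terms on the scaled
#'   date).
#' @param adult_survival,juv_survival Annual survival probabilities used by
#'   the neutral demography (the growth module has its own survival model).
#' @param mean_extra_litters Poisson mean of litters beyond the first per
#'   dam-year (total capped at `max_litters`).
#' @param max_litters Maximum litters per dam-year.
#' @param litter_size_mean Mean of the (1 + Poisson) litter-size law.
#' @param young_breeding_prob Probability that a female breeds in her birth
#'   year (rare but documented in snow voles).
#' @param breeding_females Ceiling on the number of breeding females per
#'   year (simple density regulation keeping the population near the
#'   study's scale).
#' @param viability Named list `juv_slope`, `adult_slope`: logit-scale
#'   effect (per gram of mass latent, breeding value plus permanent
#'   environment) on overwinter survival, by age class. The default makes
#'   juvenile viability selection act against genetically heavy individuals
#'   while adult survival is mass-neutral, the study system's pattern.
#' @param selection If `TRUE`, reproductive allocation (dam litter numbers
#'   and sire sampling) is weighted by the latent fitness trait, so the
#'   pedigree realizes genetic change predicted by the Robertson-Price
#'   identity.
#' @param growth Named list of growth/survival parameters: `a_mean`, `a_sd`
#'   (asymptotic mass, g), `logk_mean`, `logk_sd` (log growth rate per day),
#'   `corr_a_logk`, `measurement_sd` (g), `emergence_lag` (days from
#'   conception-scale birth date to first possible capture), `s_intercept`,
#'   `s_sex`, `s_mass`, `s_days`, `s_interaction` (survival logit
#'   coefficients on raw scales).
#' @param snow Named list: `snowmelt_long`, `snowmelt_short`,
#'   `first_snow_long`, `first_snow_short` (Julian days), `n_long_years`
#'   (initial years with a long snow-free season), `birth_lag` (days from
#'   snowmelt to first conception), `litter_spread` (days over which first
#'   litters are staggered among dams).
#' @param n_sessions Trapping sessions per season.
#' @return A `sim_config` list, validated (PSD covariances, feasible season).
#' @export
sim_config <- function(n_founders = 50,
                       n_years = 9,
                       start_year = 2006,
                       seed = 1,
                       G = NULL, M_cov = NULL, P_cov = NULL,
                       Y_cov = NULL, R_cov = NULL,
                       fixed = NULL,
                       adult_survival = 0.22,
                       juv_survival = 0.35,
                       mean_extra_litters = 0.2,
                       max_litters = 5,
                       litter_size_mean = 3.8,
                       young_breeding_prob = 0.03,
                       breeding_females = 28,
                       viability = list(juv_slope = -0.08, adult_slope = 0),
                       selection = TRUE,
                       growth = NULL,
                       snow = NULL,
                       n_sessions = 5) {
  traits <- c("mass", "length", "tail", "fitness")
  mk <- function(d, rho = NULL) {
    m <- diag(d)
    dimnames(m) <- list(traits, traits)
    if (!is.null(rho)) for (r in rho) m[r[[1]], r[[2]]] <- m[r[[2]], r[[1]]] <- r[[3]]
    m
  }
  cor2cov <- function(C, v) diag(sqrt(v)) %*% C %*% diag(sqrt(v))
  if (is.null(G)) {
    Gc <- mk(rep(1, 4), list(
      list("mass", "length", 0.79), list("mass", "tail", 0.40),
      list("length", "tail", 0.56),
      list("mass", "fitness", -0.35 / sqrt(4.34 * 0.10)),
      list("length", "fitness", -0.25), list("tail", "fitness", -0.12)))
    G <- cor2cov(Gc, c(4.34, 12, 8, 0.10))
    dimnames(G) <- list(traits, traits)
  }
  if (is.null(M_cov)) M_cov <- mk(c(1.5, 2, 1, 0.02))
  if (is.null(P_cov)) {
    Pc <- mk(rep(1, 4), list(list("mass", "fitness", 1.21 / sqrt(6 * 1.45))))
    P_cov <- cor2cov(Pc, c(6, 8, 5, 1.45))
    dimnames(P_cov) <- list(traits, traits)
  }
  if (is.null(Y_cov)) Y_cov <- mk(c(2, 2, 1, 1e-6))
  if (is.null(R_cov)) {
    Rc <- mk(c(1, 1, 1, 0), list(
      list("mass", "length", 0.45), list("mass", "tail", 0.30),
      list("length", "tail", 0.35)))
    R_cov <- cor2cov(Rc, c(13.5, 15, 9, 0))
    dimnames(R_cov) <- list(traits, traits)
  }
  if (is.null(fixed)) {
    fixed <- c(intercept_mass = 41.7, intercept_length = 128,
               intercept_tail = 62, intercept_fitness = 1,
               sexM_mass = 4, sexM_length = 4, sexM_tail = 1.5,
               age_juv_mass = -12, age_juv_length = -14, age_juv_tail = -6,
               date_mass = 1.5, date2_mass = -1.2,
               date_length = 0.5, date2_length = -0.3,
               date_tail = 0.2, date2_tail = -0.1)
  }
  if (is.null(growth)) {
    growth <- list(a_mean = 41.7, a_sd = 5.2,
                   logk_mean = log(0.02), logk_sd = 0.2,
                   corr_a_logk = -0.077, measurement_sd = 2.05,
                   emergence_lag = 25,
                   s_intercept = 8.56, s_sex = -0.2, s_mass = -0.215,
                   s_days = -0.104, s_interaction = 0.0025)
  }
  if (is.null(snow)) {
    snow <- list(snowmelt_long = 120, snowmelt_short = 150,
                 first_snow_long = 285, first_snow_short = 265,
                 n_long_years = 2, birth_lag = 40, litter_spread = 30)
  }
  cfg <- list(n_founders = n_founders, n_years = n_years,
              start_year = start_year, seed = as.integer(seed),
              traits = traits, G = G, M_cov = M_cov, P_cov = P_cov,
              Y_cov = Y_cov, R_cov = R_cov, fixed = fixed,
              adult_survival = adult_survival, juv_survival = juv_survival,
              mean_extra_litters = mean_extra_litters,
              max_litters = max_litters,
              litter_size_mean = litter_size_mean,
              young_breeding_prob = young_breeding_prob,
              breeding_females = breeding_females,
              viability = viability,
              selection = isTRUE(selection),
              growth = growth, snow = snow, n_sessions = n_sessions)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` to validate.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  for (nm in c("G", "M_cov", "P_cov", "Y_cov", "R_cov")) {
    m <- cfg[[nm]]
    if (!isSymmetric(unname(m), tol = 1e-8)) {
      stop("covariance matrix ", nm, " is not symmetric")
    }
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("covariance matrix ", nm, " is not positive semi-definite")
    }
  }
  sn <- cfg$snow
  if (sn$first_snow_long <= sn$snowmelt_long ||
      sn$first_snow_short <= sn$snowmelt_short) {
    stop("first snowfall must fall after snowmelt in every year")
  }
  if (sn$snowmelt_short + sn$birth_lag >= sn$first_snow_short) {
    stop("season too short: no room for births between snowmelt + lag and ",
         "first snowfall")
  }
  if (cfg$n_founders < 4) stop("need at least 2 founders of each sex")
  cfg
}

# Named RNG substream: stage streams are independent of how many draws
# earlier stages consumed, so adding a stage never perturbs another.
.substream <- function(seed, stage) {
  off <- c(pedigree = 1L, values = 2L, phenotypes = 3L, growth = 4L,
           drift = 5L, accept = 6L)[[stage]]
  set.seed(seed + 97L * off)
}

.snow_table <- function(cfg) {
  sn <- cfg$snow
  yrs <- cfg$start_year + seq_len(cfg$n_years) - 1L
  long <- seq_along(yrs) <= sn$n_long_years
  data.frame(
    year = yrs,
    snowmelt_day = ifelse(long, sn$snowmelt_long, sn$snowmelt_short),
    first_snowfall_day = ifelse(long, sn$first_snow_long, sn$first_snow_short)
  )
}

.session_days <- function(cfg, snow_row) {
  lo <- snow_row$snowmelt_day + 25
  hi <- snow_row$first_snowfall_day - 5
  round(seq(lo, hi, length.out = cfg$n_sessions))
}

#' Simulate an overlapping-generations pedigree (with latent trait values)
#'
#' Runs the yearly demography: founders enter in the year before monitoring,
#' dams produce 1-5 litters at least 20 days apart starting `birth_lag` days
#' after snowmelt, sires are drawn polygamously, and survival removes
#' individuals between years. Breeding values for all four traits are drawn
#' along the way (founders from `N(0, G)`, offspring from the midparent with
#' Mendelian-sampling covariance `G(1 - (F_s + F_d)/2)/2`), together with
#' permanent-environment and maternal deviations, so that when
#' `cfg$selection` is `TRUE` reproductive allocation can be weighted by the
#' latent fitness trait and the pedigree realizes genuine selection.
#'
#' @param cfg A [sim_config()].
#' @return A list: `pedigree` (a validated `qg_pedigree`), `truth` (per
#'   individual: breeding values `bv`, permanent-environment `pe`, maternal
#'   deviations, inbreeding, latent fitness `w`; per litter: mother, year,
#'   conception-scale date `t0`, size; plus the config), `snow` table.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .substream(cfg$seed, "pedigree")
  traits <- cfg$traits
  k <- length(traits)
  cG <- chol(cfg$G + diag(1e-10, k))
  cP <- chol(cfg$P_cov + diag(1e-10, k))
  cM <- chol(cfg$M_cov + diag(1e-10, k))
  snow <- .snow_table(cfg)

  cap <- max(2500L, 25L * cfg$n_founders)
  id <- character(cap); sire <- character(cap); dam <- character(cap)
  sex <- character(cap); cohort <- integer(cap)
  bv <- matrix(0, cap, k); pe <- matrix(0, cap, k); mat <- matrix(0, cap, k)
  f_coef <- numeric(cap)
  death_year <- rep(NA_integer_, cap)
  A <- matrix(0, cap, cap)  # incremental relationship matrix
  n <- 0L

  new_ind <- function(iid, s, d, sx, coh) {
    n <<- n + 1L
    if (n > cap) stop("simulated population exceeded capacity; raise cap")
    id[n] <<- iid; sire[n] <<- s; dam[n] <<- d; sex[n] <<- sx
    cohort[n] <<- coh
    si <- if (is.na(s)) 0L else match(s, id[seq_len(n - 1L)])
    di <- if (is.na(d)) 0L else match(d, id[seq_len(n - 1L)])
    prev <- seq_len(n - 1L)
    row <- numeric(n - 1L)
    if (si > 0L) row <- row + 0.5 * A[si, prev]
    if (di > 0L) row <- row + 0.5 * A[di, prev]
    if (n > 1L) { A[n, prev] <<- row; A[prev, n] <<- row }
    fo <- if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
    A[n, n] <<- 1 + fo
    f_coef[n] <<- fo
    fs <- if (si > 0L) f_coef[si] else 0
    fd <- if (di > 0L) f_coef[di] else 0
    mid <- numeric(k)
    ms_scale <- 0.5 * (1 - 0.5 * (fs + fd))
    if (si > 0L) mid <- mid + 0.5 * bv[si, ] else ms_scale <- ms_scale + 0.25
    if (di > 0L) mid <- mid + 0.5 * bv[di, ] else ms_scale <- ms_scale + 0.25
    bv[n, ] <<- (mid + sqrt(ms_scale) * drop(stats::rnorm(k) %*% cG)) *
      (diag(cfg$G) > 0)
    pe[n, ] <<- drop(stats::rnorm(k) %*% cP) * (diag(cfg$P_cov) > 0)
    mat[n, ] <<- drop(stats::rnorm(k) %*% cM) * (diag(cfg$M_cov) > 0)
    n
  }

  # latent Gaussian relative-fitness trait, mean 1 (intercept) + genetic +
  # permanent-environment components; drives reproduction when selection on
  w_of <- function(i) 1 + bv[i, k] + pe[i, k]

  nf <- cfg$n_founders
  for (i in seq_len(nf)) {
    new_ind(sprintf("F%03d", i), NA_character_, NA_character_,
            if (i <= nf / 2) "F" else "M", cfg$start_year - 1L)
  }
  alive <- rep(TRUE, nf)

  litters <- list()
  for (yi in seq_len(cfg$n_years)) {
    yr <- snow$year[yi]
    cur <- seq_len(n)
    adults <- cur[alive[cur] & cohort[cur] < yr]
    dams_pool <- adults[sex[adults] == "F"]
    sires_pool <- adults[sex[adults] == "M"]
    if (!length(dams_pool) || !length(sires_pool)) {
      stop("simulation went extinct in year ", yr,
           " (no breeding adults of one sex)")
    }
    wts <- function(ix) {
      if (!cfg$selection) return(rep(1, length(ix)))
      pmax(vapply(ix, w_of, 0), 0.05)
    }
    # density regulation: cap the number of breeding females so the
    # population fluctuates around the study's scale
    if (length(dams_pool) > cfg$breeding_females) {
      dams_pool <- sort(dams_pool[sample.int(length(dams_pool),
                                             cfg$breeding_females)])
    }
    # same-year breeders join late
    n_lit <- stats::setNames(
      pmin(1L + stats::rpois(length(dams_pool), cfg$mean_extra_litters),
           cfg$max_litters), NULL)
    if (cfg$selection) {
      # fitness raises the chance of extra litters
      ww <- wts(dams_pool)
      extra <- stats::rpois(length(dams_pool),
                            cfg$mean_extra_litters * ww / mean(ww))
      n_lit <- pmin(1L + extra, cfg$max_litters)
    }
    sm <- snow$snowmelt_day[yi]; fs <- snow$first_snowfall_day[yi]
    first_day <- sm + cfg$snow$birth_lag
    young_pool <- integer(0)
    born_this_year <- integer(0)
    for (j in seq_along(dams_pool)) {
      dmi <- dams_pool[j]
      t0 <- first_day + stats::runif(1, 0, cfg$snow$litter_spread)
      for (l in seq_len(n_lit[j])) {
        if (l > 1L) t0 <- t0 + 20 + stats::rexp(1, 1 / 5)
        if (t0 > fs - 10) break  # conception after snowfall forbidden
        size <- 1L + stats::rpois(1L, cfg$litter_size_mean - 1)
        sw <- wts(sires_pool)
        sirx <- sires_pool[sample.int(length(sires_pool), 1L,
                                      prob = sw / sum(sw))]
        kids <- integer(size)
        for (m in seq_len(size)) {
          kid_id <- sprintf("Y%02dI%04d", yi, n + 1L)
          kids[m] <- new_ind(kid_id, id[sirx], id[dmi],
                             sample(c("F", "M"), 1L), yr)
        }
        alive <- c(alive, rep(TRUE, size))
        born_this_year <- c(born_this_year, kids)
        litters[[length(litters) + 1L]] <- data.frame(
          litter = length(litters) + 1L, mother = id[dmi], sire = id[sirx],
          year = yr, t0 = round(t0, 1), size = size)
      }
    }
    # rare same-year breeding: one extra small late litter
    yf <- born_this_year[sex[born_this_year] == "F"]
    yf <- yf[stats::runif(length(yf)) < cfg$young_breeding_prob]
    for (dmi in yf) {
      t0 <- fs - 12 - stats::runif(1, 0, 5)
      if (t0 < first_day + 20) next
      size <- 1L + stats::rpois(1L, max(cfg$litter_size_mean - 2, 0.5))
      sw <- wts(sires_pool)
      sirx <- sires_pool[sample.int(length(sires_pool), 1L,
                                    prob = sw / sum(sw))]
      for (m in seq_len(size)) {
        new_ind(sprintf("Y%02dI%04d", yi, n + 1L), id[sirx], id[dmi],
                sample(c("F", "M"), 1L), yr)
        alive <- c(alive, TRUE)
      }
      litters[[length(litters) + 1L]] <- data.frame(
        litter = length(litters) + 1L, mother = id[dmi], sire = id[sirx],
        year = yr, t0 = round(t0, 1), size = size)
    }
    # overwinter survival; viability selection acts on the mass latent
    # (breeding value + permanent environment) at the configured logit slope
    cur <- seq_len(n)
    juv <- cohort[cur] == yr
    slope <- ifelse(juv, cfg$viability$juv_slope, cfg$viability$adult_slope)
    base <- ifelse(juv, cfg$juv_survival, cfg$adult_survival)
    mass_dev <- bv[cur, 1] + pe[cur, 1]
    p_surv <- stats::plogis(stats::qlogis(base) + slope * mass_dev)
    died <- alive[cur] & (stats::runif(n) > p_surv)
    alive[cur][died] <- FALSE
    death_year[cur][died] <- yr
    if (yi < cfg$n_years && !any(alive[cur])) {
      stop("simulation went extinct in year ", yr, " (no survivors)")
    }
  }
  death_year[seq_len(n)][is.na(death_year[seq_len(n)])] <- max(snow$year)

  keep <- seq_len(n)
  ped_df <- data.frame(id = id[keep], sire = sire[keep], dam = dam[keep],
                       sex = sex[keep], cohort = cohort[keep],
                       stringsAsFactors = FALSE)
  ped <- validate_pedigree(ped_df)
  ord <- match(ped$id, ped_df$id)
  litter_df <- if (length(litters)) do.call(rbind, litters) else
    data.frame(litter = integer(), mother = character(), sire = character(),
               year = integer(), t0 = numeric(), size = integer())
  truth <- list(
    config = cfg,
    ids = ped$id,
    bv = structure(bv[keep, , drop = FALSE][ord, , drop = FALSE],
                   dimnames = list(ped$id, traits)),
    pe = structure(pe[keep, , drop = FALSE][ord, , drop = FALSE],
                   dimnames = list(ped$id, traits)),
    maternal = structure(mat[keep, , drop = FALSE][ord, , drop = FALSE],
                         dimnames = list(ped$id, traits)),
    f = stats::setNames(f_coef[keep][ord], ped$id),
    w = stats::setNames((1 + bv[keep, k] + pe[keep, k])[ord], ped$id),
    death_year = stats::setNames(death_year[keep][ord], ped$id),
    litters = litter_df
  )
  list(pedigree = ped, truth = truth, snow = snow)
}

#' Drop breeding values down a fixed pedigree
#'
#' Simulates multivariate breeding values under pure transmission (no
#' selection): founders from `N(0, G)`, offspring from the midparent plus
#' Mendelian sampling with covariance `G (1 - (F_s + F_d)/2) / 2`. An
#' unknown parent contributes an independent founder draw on its side. This
#' is both the generative model of the synthetic world and the engine of the
#' gene-dropping drift null.
#'
#' @param ped A `qg_pedigree`.
#' @param G Trait covariance matrix (a scalar is taken as a 1x1 matrix).
#' @param seed Optional integer seed.
#' @param f Optional precomputed inbreeding coefficients (pedigree order).
#' @return Matrix of breeding values (individuals x traits, pedigree order).
#' @export
simulate_breeding_values <- function(ped, G, seed = NULL, f = NULL) {
  stopifnot(inherits(ped, "qg_pedigree"))
  if (!is.matrix(G)) G <- matrix(G, 1, 1)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) stop("G is not positive semi-definite")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped); k <- ncol(G)
  if (is.null(f)) f <- unname(inbreeding(ped))
  pp <- .ped_parent_idx(ped)
  cG <- chol(G + diag(1e-12, k))
  bv <- matrix(0, n, k, dimnames = list(ped$id, colnames(G)))
  z <- matrix(stats::rnorm(n * k), n, k) %*% cG
  z[, diag(G) == 0] <- 0  # zero-variance traits carry exactly zero
  for (i in seq_len(n)) {
    s <- pp$si[i]; d <- pp$di[i]
    fs <- if (s > 0L) f[s] else 0
    fd <- if (d > 0L) f[d] else 0
    ms <- 0.5 * (1 - 0.5 * (fs + fd))
    mid <- numeric(k)
    if (s > 0L) mid <- mid + 0.5 * bv[s, ] else ms <- ms + 0.25
    if (d > 0L) mid <- mid + 0.5 * bv[d, ] else ms <- ms + 0.25
    bv[i, ] <- mid + sqrt(ms) * z[i, ]
  }
  bv
}

#' Simulate phenotype and fitness tables from a pedigree and its truth
#'
#' Builds long-format capture records for mass, body length and tail length
#' as fixed effects + breeding value + maternal + permanent-environment +
#' year + correlated residual draws at every scheduled trapping session an
#' individual is alive for, and a fitness table carrying the latent Gaussian
#' relative-fitness trait (`omega`), realized lifetime reproductive success
#' from the pedigree, and annual reproductive success / survival rows.
#'
#' @param sim Output of [simulate_pedigree()].
#' @return `sim` extended with `phenotypes`, `fitness` (one row per
#'   individual-year), `lrs` (one row per individual) and date-scaling
#'   constants in `truth$date_scale`.
#' @export
simulate_phenotypes_fitness <- function(sim) {
  cfg <- sim$truth$config
  .substream(cfg$seed, "phenotypes")
  ped <- sim$pedigree
  truth <- sim$truth
  snow <- sim$snow
  traits <- cfg$traits
  k <- length(traits)
  ktr <- k - 1L  # observed morphological traits
  yr_eff <- matrix(stats::rnorm(nrow(snow) * k), nrow(snow), k) %*%
    chol(cfg$Y_cov + diag(1e-10, k))
  rownames(yr_eff) <- snow$year
  cR <- chol(cfg$R_cov[seq_len(ktr), seq_len(ktr)] + diag(1e-10, ktr))

  # presence: from the first monitored year (or birth) through the death
  # year recorded by the demography stage
  idx <- attr(ped, "index")
  first_year <- pmax(ped$cohort, snow$year[1])
  lit <- truth$litters
  death_after <- unname(truth$death_year[ped$id])

  recs <- vector("list", nrow(snow))
  date_center <- mean(vapply(seq_len(nrow(snow)),
                             function(yi) mean(.session_days(cfg, snow[yi, ])),
                             0))
  date_sd <- 30
  for (yi in seq_len(nrow(snow))) {
    yr <- snow$year[yi]
    days <- .session_days(cfg, snow[yi, ])
    present <- which(first_year <= yr & death_after >= yr)
    if (!length(present)) next
    out <- vector("list", length(days))
    for (si in seq_along(days)) {
      d <- days[si]
      juv <- ped$cohort[present] == yr
      ds <- (d - date_center) / date_sd
      mu <- matrix(0, length(present), ktr)
      fx <- cfg$fixed
      for (ti in seq_len(ktr)) {
        tn <- traits[ti]
        mu[, ti] <- fx[[paste0("intercept_", tn)]] +
          fx[[paste0("sexM_", tn)]] * (ped$sex[present] == "M") +
          fx[[paste0("age_juv_", tn)]] * juv +
          fx[[paste0("date_", tn)]] * ds +
          fx[[paste0("date2_", tn)]] * ds^2 +
          truth$bv[present, ti] + truth$pe[present, ti] +
          yr_eff[as.character(yr), ti]
      }
      # maternal deviation of the *mother* applies; unknown mother gets an
      # independent deviate (drawn once per individual at birth, stored as
      # own-row maternal effect for orphans)
      mom <- ped$dam[present]
      mref <- ifelse(is.na(mom), ped$id[present], mom)
      mu <- mu + truth$maternal[mref, seq_len(ktr), drop = FALSE]
      err <- matrix(stats::rnorm(length(present) * ktr),
                    length(present), ktr) %*% cR
      vals <- mu + err
      out[[si]] <- data.frame(
        id = ped$id[present], year = yr, julian_day = d,
        age_class = ifelse(juv, "juvenile", "adult"),
        sex = ped$sex[present],
        mass = round(vals[, 1], 1), body_length = round(vals[, 2], 1),
        tail_length = round(vals[, 3], 1))
    }
    recs[[yi]] <- do.call(rbind, out)
  }
  phen <- do.call(rbind, recs)
  rownames(phen) <- NULL

  # lifetime reproductive success from the pedigree link ledger
  lrs_n <- table(c(ped$sire, ped$dam))
  lrs <- stats::setNames(rep(0L, nrow(ped)), ped$id)
  lrs[names(lrs_n)] <- as.integer(lrs_n)
  lrs_df <- data.frame(id = ped$id, sex = ped$sex, cohort = ped$cohort,
                       lrs = unname(lrs), omega = unname(truth$w))

  # annual rows: ARS = offspring attributed in that year, survived =
  # present next year
  fit_rows <- list()
  for (yi in seq_len(nrow(snow))) {
    yr <- snow$year[yi]
    present <- which(first_year <= yr & death_after >= yr)
    if (!length(present)) next
    ars <- stats::setNames(rep(0L, length(present)), ped$id[present])
    if (nrow(lit)) {
      ly <- lit[lit$year == yr, ]
      for (col in c("mother", "sire")) {
        tab <- tapply(ly$size, ly[[col]], sum)
        hit <- intersect(names(tab), names(ars))
        ars[hit] <- ars[hit] + as.integer(tab[hit])
      }
    }
    fit_rows[[yi]] <- data.frame(
      id = ped$id[present], sex = ped$sex[present],
      cohort = ped$cohort[present], year = yr,
      lrs = unname(lrs[present]), omega = unname(truth$w[present]),
      ars = unname(ars),
      # survival out of the final monitored year is right-censored
      survived = if (yr < max(snow$year)) {
        as.integer(death_after[present] > yr)
      } else NA_integer_)
  }
  fitness <- do.call(rbind, fit_rows)
  rownames(fitness) <- NULL

  sim$phenotypes <- phen
  sim$fitness <- fitness
  sim$lrs <- lrs_df
  sim$truth$date_scale <- c(center = date_center, sd = date_sd)
  sim$truth$year_effects <- structure(yr_eff,
                                      dimnames = list(snow$year, traits))
  sim
}

#' Simulate juvenile capture histories under monomolecular growth
#'
#' Litters (from the pedigree stage) give every juvenile a conception-scale
#' birth date `t0`; individual asymptotic mass `a_i` and growth rate `k_i`
#' come from a bivariate (a, log k) population distribution; observed masses
#' follow `m(t) = a_i (1 - exp(-k_i (t - t0)))` plus `N(0, sd^2)` measurement
#' error at each trapping session at least `emergence_lag` days after `t0`;
#' overwinter survival is Bernoulli on the logit scale in sex, `a_i`,
#' days-to-first-snowfall (`first_snowfall_day - t0`) and the
#' `a_i x days` interaction.
#'
#' @param sim Output of [simulate_pedigree()] (phenotype stage optional).
#' @return `sim` extended with `captures` (id, mother, year, julian_day,
#'   mass), `juveniles` (truth: a, k, t0, days, survival probability and
#'   outcome) and the snow table unchanged.
#' @export
simulate_growth_histories <- function(sim) {
  cfg <- sim$truth$config
  .substream(cfg$seed, "growth")
  g <- cfg$growth
  snow <- sim$snow
  lit <- sim$truth$litters
  ped <- sim$pedigree
  if (!nrow(lit)) stop("no litters in truth ledger; nothing to grow")
  kids <- ped[!is.na(ped$dam), , drop = FALSE]
  # attach each offspring to its mother-year litter; litters within a
  # mother-year are assigned round-robin by the ledger sizes
  caps <- list(); juv_truth <- list()
  # predicted adult mass is adult mass: it inherits the individual's mass
  # breeding value, so genetic trends in mass show up as cohort-level
  # trends in the asymptote; the environmental remainder keeps the total
  # SD at a_sd and carries the (weak) correlation with growth rate
  va_mass <- cfg$G["mass", "mass"]
  var_e <- max(g$a_sd^2 - va_mass, 0.25)
  cov_e <- g$corr_a_logk * g$a_sd * g$logk_sd
  Sg <- matrix(c(var_e, cov_e, cov_e, g$logk_sd^2), 2, 2)
  cS <- chol(Sg + diag(1e-12, 2))
  for (li in seq_len(nrow(lit))) {
    L <- lit[li, ]
    snr <- snow[snow$year == L$year, ]
    members <- kids$id[kids$dam == L$mother & kids$cohort == L$year &
                         kids$sire == L$sire]
    # ledger litters of the same pair/year are consumed in order
    prior_lit <- lit[seq_len(li - 1L), , drop = FALSE]
    used <- sum(prior_lit$size[prior_lit$mother == L$mother &
                                 prior_lit$year == L$year &
                                 prior_lit$sire == L$sire])
    members <- members[seq_len(min(L$size, max(length(members) - used, 0))) +
                         used]
    members <- members[!is.na(members)]
    if (!length(members)) next
    days <- .session_days(cfg, snr)
    for (m_id in members) {
      zz <- drop(stats::rnorm(2) %*% cS)
      a_i <- g$a_mean + sim$truth$bv[m_id, "mass"] + zz[1]
      k_i <- exp(g$logk_mean + zz[2])
      obs_days <- days[days >= L$t0 + g$emergence_lag]
      d2s <- snr$first_snowfall_day - L$t0
      sexm <- ped$sex[attr(ped, "index")[m_id]] == "M"
      eta <- g$s_intercept + g$s_sex * sexm + g$s_mass * a_i +
        g$s_days * d2s + g$s_interaction * a_i * d2s
      p_surv <- stats::plogis(eta)
      surv <- stats::rbinom(1L, 1L, p_surv)
      if (length(obs_days)) {
        mass <- a_i * (1 - exp(-k_i * (obs_days - L$t0))) +
          stats::rnorm(length(obs_days), 0, g$measurement_sd)
        caps[[length(caps) + 1L]] <- data.frame(
          id = m_id, mother = L$mother, year = L$year,
          julian_day = obs_days, mass = round(mass, 2))
      }
      juv_truth[[length(juv_truth) + 1L]] <- data.frame(
        id = m_id, mother = L$mother, year = L$year, litter = L$litter,
        sex = if (sexm) "M" else "F", a = a_i, k = k_i, t0 = L$t0,
        days_to_snowfall = d2s, p_surv = p_surv, survived = surv,
        n_captures = length(obs_days))
    }
  }
  sim$captures <- if (length(caps)) do.call(rbind, caps) else
    data.frame(id = character(), mother = character(), year = integer(),
               julian_day = numeric(), mass = numeric())
  rownames(sim$captures) <- NULL
  sim$juveniles <- do.call(rbind, juv_truth)
  rownames(sim$juveniles) <- NULL
  sim
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [simulate_pedigree()],
#' [simulate_phenotypes_fitness()] and [simulate_growth_histories()] under
#' the config's seed. The result contains every table a real study would
#' provide plus the full generating truth for parameter-recovery tests.
#'
#' @param cfg A [sim_config()].
#' @return A `qg_sim` list: `pedigree`, `phenotypes`, `fitness`, `lrs`,
#'   `captures`, `juveniles`, `snow`, `truth`.
#' @export
simulate_study <- function(cfg) {
  sim <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes_fitness(sim)
  sim <- simulate_growth_histories(sim)
  class(sim) <- "qg_sim"
  sim
}

#' @export
print.qg_sim <- function(x, ...) {
  cat("qg_sim:", nrow(x$pedigree), "individuals,",
      nrow(x$truth$litters), "litters,", nrow(x$phenotypes),
      "phenotype records,", nrow(x$captures), "juvenile captures\n")
  invisible(x)
}

#' Write a synthetic study to disk as plain-text tables
#'
#' @param sim A `qg_sim` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE, na = "")
  ped <- as.data.frame(sim$pedigree)[, c("id", "sire", "dam", "sex", "cohort")]
  w(ped, "pedigree.csv")
  w(sim$phenotypes, "phenotypes.csv")
  w(sim$fitness, "fitness.csv")
  w(sim$captures, "captures.csv")
  w(sim$snow, "snow.csv")
  tr <- sim$truth
  jsonlite::write_json(
    list(seed = tr$config$seed,
         n_individuals = nrow(sim$pedigree),
         traits = tr$config$traits,
         G = tr$config$G, P = tr$config$P_cov, M = tr$config$M_cov,
         Y = tr$config$Y_cov, R = tr$config$R_cov,
         date_scale = tr$date_scale,
         growth = tr$config$growth, snow = tr$config$snow),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
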
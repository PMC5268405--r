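#' MCMC settings for the model samplers
#'
#' The default is a scaled-down chain suitable for tests and desk-scale
#' analyses. `mcmc_long()` is the long preset (the kind of chain used for
#' publication-grade variance-component estimates: 1.3M iterations, 300k
#' burn-in, thinning 1,000).
#'
#' @param n_iter,burnin,thin Chain length, burn-in and thinning interval.
#' @param seed Integer seed for the sampler.
#' @param store_bv Store thinned breeding-value samples (needed for
#'   breeding-value trends and the drift null).
#' @return A list of settings.
#' @export
mcmc_settings <- function(n_iter = 60000, burnin = 10000, thin = 50,
                          seed = 1, store_bv = TRUE) {
  stopifnot(n_iter > burnin, thin >= 1)
  list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
       thin = as.integer(thin), seed = as.integer(seed),
       store_bv = isTRUE(store_bv))
}

#' @rdname mcmc_settings
#' @export
mcmc_long <- function(seed = 1, store_bv = TRUE) {
  mcmc_settings(1300000, 300000, 1000, seed = seed, store_bv = store_bv)
}

#' Default inverse-Wishart priors for the variance components
#'
#' Per random term, an inverse-Wishart with scale `V` and degree of belief
#' `nu`. The default follows the usual weakly-informative convention for
#' animal models: the scale splits the observed phenotypic (co)variance
#' evenly across the fitted components and the degree of belief is small
#' (`k - 1 + 0.002` for `k` traits, the multivariate analogue of the
#' univariate variance-1, belief-0.002 prior).
#'
#' Parameter expansion (`px = TRUE`, the default) gives every random term a
#' scalar working parameter with a `N(0, 1000)` prior; the effective
#' covariance is the working covariance times the squared working
#' parameter. Without it the sampler has an absorbing state near zero
#' variance and components close to zero mix very poorly.
#'
#' @param vp Named vector of observed per-trait variances.
#' @param n_terms Number of random terms (including the residual).
#' @param nu Degree of belief.
#' @param px Use parameter expansion.
#' @return A `qg_prior` list with elements `G`, `M`, `P`, `Y`, `R`, `px`.
#' @export
default_prior <- function(vp, n_terms = 5, nu = NULL, px = TRUE) {
  k <- length(vp)
  if (is.null(nu)) nu <- k - 1 + 0.002
  V <- diag(pmax(vp, 1e-6) / n_terms, k)
  pr <- list(G = list(V = V, nu = nu), M = list(V = V, nu = nu),
             P = list(V = V, nu = nu), Y = list(V = V, nu = nu),
             R = list(V = V, nu = nu), px = isTRUE(px))
  class(pr) <- "qg_prior"
  pr
}

# Build the per-trait fixed-effect design matrix, failing loudly on aliasing
.design <- function(form, df, label) {
  mm <- stats::model.matrix(form, df)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    aliased <- colnames(mm)[setdiff(seq_len(ncol(mm)), qr_$pivot[seq_len(qr_$rank)])]
    stop("singular fixed-effect design for ", label,
         "; aliased columns: ", paste(aliased, collapse = ", "))
  }
  mm
}

#' Fit a Bayesian animal model by Gibbs sampling
#'
#' Uni- or multivariate Gaussian mixed model with a pedigree-structured
#' additive genetic effect and optional maternal, permanent-environment and
#' year random effects. Trait records enter in long format (one capture per
#' row); relative fitness, if modelled, enters as one record per individual
#' with its residual variance fixed at `fix_frac` times its observed
#' variance (near zero), so the permanent-environment term carries its
#' nonadditive variance and the additive covariance `sigma_A(z, omega)` is
#' the Robertson-Price genetic differential.
#'
#' Fixed effects for morphological traits default to the standard capture
#' correction: age class, sex, their interaction, scaled Julian date and its
#' square plus interactions with age and sex, and the pedigree inbreeding
#' coefficient as a covariate. Relative fitness gets an intercept only.
#'
#' @param phenotypes Long-format capture table with columns `id`, `year`,
#'   `julian_day`, `age_class` (`"juvenile"`/`"adult"`), `sex`, and one
#'   column per morphological trait.
#' @param ped A `qg_pedigree`; every measured individual must appear.
#' @param traits Character vector of phenotype columns to model (e.g.
#'   `"mass"` or `c("mass", "body_length", "tail_length")`).
#' @param fitness Optional data.frame `id`, `value` (one row per individual)
#'   with the relative-fitness trait `omega`; when supplied, `"omega"` is
#'   appended to the modelled traits.
#' @param random Random terms to include besides the additive effect:
#'   subset of `c("maternal", "pe", "year")`.
#' @param fixed_formula RHS formula for morphological traits, evaluated in
#'   the record table which carries `age_class`, `sex`, `date_s`, `date_s2`
#'   and `f_ped`.
#' @param fitness_formula RHS formula for the fitness trait.
#' @param prior A [default_prior()]-shaped list; built from the data when
#'   `NULL`.
#' @param mcmc [mcmc_settings()].
#' @param fix_frac Fraction of the observed variance at which a fixed-trait
#'   residual is pinned.
#' @param date_scale Optional `c(center, sd)` for Julian-date scaling; the
#'   constants are estimated from the data and stored with the fit when
#'   `NULL`, so predictions reuse identical scaling.
#' @return A `qg_animal_model`: thinned posterior arrays `G`, `M`, `P`, `Y`,
#'   `R` (trait x trait x sample), fixed effects `b`, breeding values `bv`
#'   (individual x trait x sample, pedigree order), plus metadata
#'   (`traits`, `ids`, `prior`, `mcmc`, `date_scale`, `diagnostics`).
#' @export
fit_animal_model <- function(phenotypes, ped, traits = "mass",
                             fitness = NULL,
                             random = c("maternal", "pe", "year"),
                             fixed_formula = ~ age_class * sex *
                               (date_s + date_s2) + f_ped,
                             fitness_formula = ~ 1,
                             prior = NULL,
                             mcmc = mcmc_settings(),
                             fix_frac = 1e-8,
                             date_scale = NULL) {
  stopifnot(inherits(ped, "qg_pedigree"))
  random <- if (length(random)) {
    match.arg(random, c("maternal", "pe", "year"), several.ok = TRUE)
  } else character(0)
  ph <- phenotypes
  miss <- setdiff(unique(ph$id), ped$id)
  if (length(miss)) {
    stop("phenotyped individuals absent from pedigree: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  # canonical ordering makes the fit invariant to input row order
  ph <- ph[order(ph$id, ph$year, ph$julian_day), , drop = FALSE]

  if (is.null(date_scale)) {
    date_scale <- c(center = mean(ph$julian_day), sd = stats::sd(ph$julian_day))
  }
  f_all <- inbreeding(ped)
  rec <- data.frame(
    id = ph$id,
    year = ph$year,
    age_class = factor(ph$age_class, levels = c("adult", "juvenile")),
    sex = factor(ph$sex, levels = c("F", "M")),
    date_s = (ph$julian_day - date_scale["center"]) / date_scale["sd"],
    f_ped = unname(f_all[ph$id]))
  rec$date_s2 <- rec$date_s^2

  model_traits <- traits
  Y <- as.matrix(ph[, traits, drop = FALSE])
  rowgroup <- rep(0L, nrow(Y))
  has_fitness <- !is.null(fitness)
  if (has_fitness) {
    stopifnot(all(c("id", "value") %in% names(fitness)))
    if (anyDuplicated(fitness$id)) stop("fitness must have one row per individual")
    fmiss <- setdiff(fitness$id, ped$id)
    if (length(fmiss)) stop("fitness individuals absent from pedigree: ",
                            paste(utils::head(fmiss, 5), collapse = ", "))
    fitness <- fitness[order(fitness$id), , drop = FALSE]
    model_traits <- c(traits, "omega")
    kf0 <- length(traits)
    Y <- cbind(Y, matrix(NA_real_, nrow(Y), 1))
    fY <- matrix(NA_real_, nrow(fitness), kf0 + 1L)
    fY[, kf0 + 1L] <- fitness$value
    Y <- rbind(Y, fY)
    coh <- stats::setNames(ped$cohort, ped$id)
    sex_of <- stats::setNames(ped$sex, ped$id)
    frec <- data.frame(
      id = fitness$id, year = unname(coh[fitness$id]),
      age_class = factor("adult", levels = c("adult", "juvenile")),
      sex = factor(sex_of[fitness$id], levels = c("F", "M")),
      date_s = 0, f_ped = unname(f_all[fitness$id]))
    frec$date_s2 <- 0
    rec <- rbind(rec, frec)
    rowgroup <- c(rowgroup, rep(length(model_traits), nrow(fitness)))
  }
  colnames(Y) <- model_traits
  k <- length(model_traits)
  free_tr <- seq_along(traits) - 1L
  fix_res <- rep(-1, k)
  if (has_fitness) {
    fix_res[k] <- fix_frac * stats::var(fitness$value)
    if (fix_res[k] <= 0) fix_res[k] <- fix_frac
  }

  obs <- !is.na(Y)
  if (any(rowSums(obs[rowgroup == 0L, seq_along(traits), drop = FALSE]) == 0)) {
    stop("every capture record must observe at least one trait")
  }
  # start missing entries at trait means
  for (t in seq_len(k)) {
    if (anyNA(Y[, t])) Y[is.na(Y[, t]), t] <- mean(Y[, t], na.rm = TRUE)
  }

  idx <- attr(ped, "index")
  ind <- unname(idx[rec$id])
  dam_of <- stats::setNames(ped$dam, ped$id)
  momid <- dam_of[rec$id]
  momid[is.na(momid)] <- paste0(".orphan.", rec$id[is.na(momid)])
  mom_lev <- sort(unique(momid))
  mom <- if ("maternal" %in% random) match(momid, mom_lev) else rep(0L, nrow(rec))
  yr_lev <- sort(unique(rec$year))
  year <- if ("year" %in% random) match(rec$year, yr_lev) else rep(0L, nrow(rec))

  Xlist <- vector("list", k)
  for (t in seq_len(k)) {
    form <- if (has_fitness && t == k) fitness_formula else fixed_formula
    Xlist[[t]] <- .design(form, rec, model_traits[t])
  }

  if (is.null(prior)) {
    vp <- vapply(seq_len(k), function(t) stats::var(Y[obs[, t], t]), 0)
    prior <- default_prior(vp, n_terms = 2 + length(random))
  }
  # the residual prior acts on the free block only
  prior_cpp <- prior
  prior_cpp$R$V <- prior$R$V[free_tr + 1L, free_tr + 1L, drop = FALSE]
  if (!is.matrix(prior_cpp$R$V)) prior_cpp$R$V <- matrix(prior_cpp$R$V, 1, 1)

  Ainv <- a_inverse(ped)

  set.seed(mcmc$seed)
  res <- animal_gibbs_cpp(
    Y = Y, obs = obs * 1L, Xlist = Xlist,
    ind = as.integer(ind), mom = as.integer(mom), year = as.integer(year),
    rowgroup = as.integer(rowgroup),
    free_tr = as.integer(free_tr), fix_res = fix_res,
    Ai_i = Ainv@i, Ai_p = Ainv@p, Ai_x = Ainv@x,
    n_ind = nrow(ped), n_mom = length(mom_lev), n_year = length(yr_lev),
    use_mat = "maternal" %in% random, use_pe = "pe" %in% random,
    use_year = "year" %in% random,
    prior = prior_cpp, n_iter = mcmc$n_iter, burnin = mcmc$burnin,
    thin = mcmc$thin, store_bv = mcmc$store_bv)

  dn <- list(model_traits, model_traits, NULL)
  out <- list(
    G = structure(res$G, dimnames = dn),
    M = structure(res$M, dimnames = dn),
    P = structure(res$P, dimnames = dn),
    Y = structure(res$Y, dimnames = dn),
    R = structure(res$R, dimnames = dn),
    b = stats::setNames(lapply(seq_len(k), function(t) {
      m <- res$b[[t]]; colnames(m) <- colnames(Xlist[[t]]); m
    }), model_traits),
    bv = if (mcmc$store_bv)
      structure(res$bv, dimnames = list(ped$id, model_traits, NULL)),
    year_eff = if ("year" %in% random)
      structure(res$year_effects,
                dimnames = list(yr_lev, model_traits, NULL)),
    traits = model_traits,
    free_traits = traits,
    fixed_residual = if (has_fitness) stats::setNames(fix_res[k], "omega"),
    ids = ped$id,
    cohorts = stats::setNames(ped$cohort, ped$id),
    random = random,
    prior = prior,
    mcmc = mcmc,
    date_scale = date_scale,
    year_levels = yr_lev,
    n_records = nrow(Y))
  class(out) <- "qg_animal_model"
  out$diagnostics <- .chain_diagnostics(out)
  out
}

# lag-1 autocorrelation and effective size of the main variance chains
.chain_diagnostics <- function(fit) {
  k <- length(fit$traits)
  chains <- list()
  for (nm in c("G", "P", "R")) {
    arr <- fit[[nm]]
    for (t in seq_len(k)) {
      chains[[paste0(nm, "_", fit$traits[t])]] <- arr[t, t, ]
    }
  }
  lag1 <- vapply(chains, function(x) {
    if (stats::sd(x) == 0) return(0)
    stats::cor(x[-length(x)], x[-1])
  }, 0)
  ess <- vapply(chains, function(x) {
    as.numeric(coda::effectiveSize(coda::mcmc(x)))
  }, 0)
  list(lag1_autocorrelation = lag1, effective_size = ess)
}

#' @export
print.qg_animal_model <- function(x, ...) {
  k <- length(x$traits)
  S <- dim(x$G)[3]
  cat("qg_animal_model:", paste(x$traits, collapse = ", "), "|",
      x$n_records, "records |", S, "posterior samples\n")
  cat("posterior mode V_A:",
      paste(sprintf("%s=%.3g", x$traits,
                    vapply(seq_len(k), function(t) posterior_mode(x$G[t, t, ]), 0)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Posterior mode of a sample by kernel density estimation
#'
#' The mode of a Gaussian-kernel density estimate (bandwidth: Silverman's
#' rule, `stats::bw.nrd0`) over the draws; the convention used for all
#' point estimates reported by this package.
#'
#' @param x Numeric vector of posterior draws.
#' @param strict Error (rather than warn) when fewer than 100 draws.
#' @return Scalar mode. Kernel smoothing biases the mode of skewed
#'   densities slightly toward the bulk; this is the usual price of the
#'   estimator.
#' @export
posterior_mode <- function(x, strict = FALSE) {
  x <- x[is.finite(x)]
  if (length(x) < 100) {
    msg <- sprintf("only %d draws: posterior mode is imprecise", length(x))
    if (strict) stop(msg) else warning(msg)
  }
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' 95% highest-posterior-density interval
#' @param x Numeric vector of posterior draws.
#' @param prob Target probability mass.
#' @return Length-2 vector `c(lower, upper)`.
#' @export
hpd <- function(x, prob = 0.95) {
  iv <- coda::HPDinterval(coda::mcmc(as.numeric(x)), prob = prob)
  c(lower = iv[1, "lower"], upper = iv[1, "upper"])
}

#' Posterior tail probability against a reference value
#'
#' The MCMC analogue of a two-sided p-value: twice the smaller tail mass of
#' the posterior relative to `ref` (bounded below by `1/n_draws`).
#' @param x Posterior draws.
#' @param ref Reference value (default 0).
#' @return Scalar in (0, 1].
#' @export
p_mcmc <- function(x, ref = 0) {
  x <- x[is.finite(x)]
  p <- min(mean(x <= ref), mean(x >= ref)) * 2
  max(p, 1 / length(x))
}

#' Posterior of heritability
#'
#' Per posterior sample, \eqn{h^2 = V_A / V_P} with the phenotypic variance
#' summing every fitted random component plus the residual. The composition
#' of the denominator is debatable for year effects (variance among years is
#' not variance among individuals within a year); `exclude_year = TRUE`
#' drops the year variance and both versions can be reported.
#'
#' @param fit A `qg_animal_model`.
#' @param trait Trait name.
#' @param exclude_year Drop the year variance from the denominator.
#' @return List: `samples`, `mode`, `hpd`.
#' @export
heritability <- function(fit, trait = fit$traits[1], exclude_year = FALSE) {
  t <- .trait_index(fit, trait)
  va <- fit$G[t, t, ]
  vp <- va + fit$R[t, t, ]
  if ("pe" %in% fit$random) vp <- vp + fit$P[t, t, ]
  if ("maternal" %in% fit$random) vp <- vp + fit$M[t, t, ]
  if ("year" %in% fit$random && !exclude_year) vp <- vp + fit$Y[t, t, ]
  h2 <- va / vp
  list(samples = h2, mode = posterior_mode(h2), hpd = hpd(h2))
}

#' Posterior of a genetic correlation
#'
#' Per sample, \eqn{\rho_A = \sigma_A(z, y) / \sqrt{\sigma_A^2(z)\,
#' \sigma_A^2(y)}}. Samples with a non-positive variance draw are skipped
#' and counted. Tail probabilities against 0 and 1 are reported.
#'
#' @param fit A `qg_animal_model`.
#' @param trait_pair Character vector of two trait names.
#' @return List: `samples`, `mode`, `hpd`, `p_vs_0`, `p_vs_1`, `n_skipped`.
#' @export
genetic_correlation <- function(fit, trait_pair) {
  stopifnot(length(trait_pair) == 2)
  i <- .trait_index(fit, trait_pair[1])
  j <- .trait_index(fit, trait_pair[2])
  vi <- fit$G[i, i, ]; vj <- fit$G[j, j, ]; cij <- fit$G[i, j, ]
  ok <- vi > 0 & vj > 0
  rho <- cij[ok] / sqrt(vi[ok] * vj[ok])
  list(samples = rho, mode = posterior_mode(rho), hpd = hpd(rho),
       p_vs_0 = p_mcmc(rho, 0), p_vs_1 = p_mcmc(rho, 1),
       n_skipped = sum(!ok))
}

.trait_index <- function(fit, trait) {
  t <- match(trait, fit$traits)
  if (is.na(t)) {
    stop("trait '", trait, "' not in model (has: ",
         paste(fit$traits, collapse = ", "), ")")
  }
  t
}
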
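#' Relativize fitness by group means
#'
#' Divides a fitness measure by its group-specific mean so that mean
#' relative fitness is 1 within each cell. Total selection uses lifetime
#' reproductive success standardized within sex-by-cohort cells (cohort
#' standardization absorbs variation in population growth rate; sex
#' standardization absorbs the unequal sampling of paternities and
#' maternities); fertility and viability components use annual measures
#' standardized within sex-by-year cells.
#'
#' @param df Data.frame with columns `sex`, the `value` column, and the
#'   grouping column (`cohort` or `year`).
#' @param value Name of the fitness column (e.g. `"lrs"`, `"ars"`,
#'   `"survived"`).
#' @param by Grouping: `"cohort"` or `"year"` (always crossed with sex).
#' @return The input with a new column `relative` and attribute
#'   `cell_sizes`. Cells whose members are all zero raise an error naming
#'   the cells.
#' @export
relativize_fitness <- function(df, value = "lrs", by = c("cohort", "year")) {
  by <- match.arg(by)
  stopifnot(all(c("sex", by, value) %in% names(df)))
  cell <- interaction(df$sex, df[[by]], drop = TRUE, sep = ":")
  mu <- tapply(df[[value]], cell, mean)
  bad <- names(mu)[mu == 0]
  if (length(bad)) {
    stop("relative fitness undefined: all-zero ", value,
         " in cell(s) ", paste(bad, collapse = ", "))
  }
  df$relative <- as.numeric(df[[value]] / mu[as.character(cell)])
  attr(df, "cell_sizes") <- table(cell)
  df
}

#' Posterior of a selection differential and its decomposition
#'
#' The selection differential on trait `z` is the phenotypic covariance
#' with relative fitness, obtained per posterior sample as the sum of the
#' trait-fitness covariances at the additive-genetic, maternal,
#' permanent-environment and residual levels. The among-year covariance is
#' excluded: covariation between trait and fitness at the year level does
#' not act among individuals and is not selection. The environmental
#' differential is the maternal + permanent-environment + residual part, so
#' that per sample `sigma_P = sigma_A + sigma_E` exactly.
#'
#' @param fit A `qg_animal_model` containing both `trait` and the fitness
#'   trait.
#' @param trait Trait name (e.g. `"mass"`).
#' @param fitness_trait Name of the fitness trait in the model.
#' @return A `qg_selection` list: per-sample vectors `sigma_P`, `sigma_A`,
#'   `sigma_E` (and its parts), with modes, 95% HPDs and `p_mcmc`.
#' @export
selection_differential <- function(fit, trait = "mass",
                                   fitness_trait = "omega") {
  i <- .trait_index(fit, trait)
  j <- .trait_index(fit, fitness_trait)
  sA <- fit$G[i, j, ]
  sM <- if ("maternal" %in% fit$random) fit$M[i, j, ] else 0 * sA
  sPE <- if ("pe" %in% fit$random) fit$P[i, j, ] else 0 * sA
  sR <- fit$R[i, j, ]
  sE <- sM + sPE + sR
  out <- list(trait = trait, fitness_trait = fitness_trait,
              sigma_A = sA, sigma_E = sE, sigma_P = sA + sE,
              parts = list(maternal = sM, perm_env = sPE, residual = sR))
  out$summary <- do.call(rbind, lapply(
    c("sigma_P", "sigma_A", "sigma_E"), function(nm) {
      x <- out[[nm]]
      data.frame(component = nm, mode = posterior_mode(x),
                 lower = hpd(x)[1], upper = hpd(x)[2], p_mcmc = p_mcmc(x))
    }))
  class(out) <- "qg_selection"
  out
}

#' @export
print.qg_selection <- function(x, ...) {
  cat("Selection on", x$trait, "via", x$fitness_trait, "\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Posterior of selection gradients
#'
#' Per posterior sample, \eqn{\beta = (G' + P' + R')^{-1} S}, where the
#' primed matrices drop the fitness row/column and `S` stacks the
#' per-trait selection differentials (year level excluded). The maternal
#' covariance is excluded from the phenotypic denominator by default,
#' following the estimator's standard form; `include_maternal = TRUE` adds
#' `M'`, and both can be reported when they differ.
#'
#' @param fit A `qg_animal_model` with >= 1 morphological trait + fitness.
#' @param fitness_trait Fitness trait name.
#' @param include_maternal Add the maternal covariance to the denominator.
#' @return List: `samples` (traits x samples matrix of gradients), `S`
#'   (differential samples), `summary`, `n_skipped` (singular draws).
#' @export
selection_gradients <- function(fit, fitness_trait = "omega",
                                include_maternal = FALSE) {
  j <- .trait_index(fit, fitness_trait)
  tr <- setdiff(seq_along(fit$traits), j)
  S <- dim(fit$G)[3]
  has_m <- "maternal" %in% fit$random
  has_p <- "pe" %in% fit$random
  beta <- matrix(NA_real_, length(tr), S,
                 dimnames = list(fit$traits[tr], NULL))
  Sdiff <- matrix(0, length(tr), S, dimnames = list(fit$traits[tr], NULL))
  skipped <- 0L
  for (s in seq_len(S)) {
    Gp <- fit$G[tr, tr, s, drop = FALSE][, , 1]
    Pp <- if (has_p) fit$P[tr, tr, s, drop = FALSE][, , 1] else 0 * Gp
    Rp <- fit$R[tr, tr, s, drop = FALSE][, , 1]
    den <- Gp + Pp + Rp
    if (include_maternal && has_m)
      den <- den + fit$M[tr, tr, s, drop = FALSE][, , 1]
    sv <- fit$G[tr, j, s] + fit$R[tr, j, s] +
      (if (has_p) fit$P[tr, j, s] else 0) +
      (if (has_m) fit$M[tr, j, s] else 0)
    Sdiff[, s] <- sv
    b <- tryCatch(solve(den, sv), error = function(e) NULL)
    if (is.null(b)) { skipped <- skipped + 1L; next }
    beta[, s] <- b
  }
  ok <- !is.na(beta[1, ])
  summ <- do.call(rbind, lapply(seq_along(tr), function(t) {
    x <- beta[t, ok]
    data.frame(trait = fit$traits[tr][t], mode = posterior_mode(x),
               lower = hpd(x)[1], upper = hpd(x)[2], p_mcmc = p_mcmc(x))
  }))
  list(samples = beta[, ok, drop = FALSE], S = Sdiff[, ok, drop = FALSE],
       kept = which(ok), summary = summ, n_skipped = skipped)
}

#' Predicted evolutionary response per generation and per year
#'
#' Four estimators of the rate of evolutionary change of the focal traits:
#' * `UBE`: univariate breeder's equation \eqn{R = h^2 S} per trait;
#' * `MBE`: multivariate breeder's equation \eqn{\Delta\bar{Z}' = G'\beta};
#' * `MBE_rho0`: the same with genetic correlations constrained to zero
#'   (`G'` times the identity, i.e. off-diagonals zeroed) before
#'   multiplying \eqn{\beta};
#' * `Price`: the Robertson-Price genetic differential
#'   \eqn{\sigma_A(z, \omega)}, the predicted (here: realized) rate of
#'   genetic change per generation.
#'
#' All computed per posterior sample; per-year rates divide by the mean
#' generation time `T` sample-wise, so per-year = per-generation / T holds
#' exactly for every draw.
#'
#' @param fit A `qg_animal_model` with fitness.
#' @param mode One of `"UBE"`, `"MBE"`, `"MBE_rho0"`, `"Price"`.
#' @param T_gen Mean generation time in years (see [generation_time()]).
#' @param fitness_trait Fitness trait name.
#' @return A `qg_response` list: `per_generation` and `per_year` (traits x
#'   samples matrices), `mode`, `T_gen`, `summary` (per-year scale).
#' @export
predict_response <- function(fit, mode = c("UBE", "MBE", "MBE_rho0", "Price"),
                             T_gen, fitness_trait = "omega") {
  mode <- match.arg(mode)
  if (T_gen <= 0) stop("generation time must be positive")
  j <- .trait_index(fit, fitness_trait)
  tr <- setdiff(seq_along(fit$traits), j)
  S <- dim(fit$G)[3]
  has_m <- "maternal" %in% fit$random
  has_p <- "pe" %in% fit$random
  pred <- matrix(NA_real_, length(tr), S,
                 dimnames = list(fit$traits[tr], NULL))
  if (mode == "Price") {
    pred[] <- t(sapply(tr, function(t) fit$G[t, j, ]))
  } else if (mode == "UBE") {
    for (ti in seq_along(tr)) {
      t <- tr[ti]
      h2 <- heritability(fit, fit$traits[t])$samples
      sdiff <- fit$G[t, j, ] + fit$R[t, j, ] +
        (if (has_p) fit$P[t, j, ] else 0) +
        (if (has_m) fit$M[t, j, ] else 0)
      pred[ti, ] <- h2 * sdiff
    }
  } else {
    sg <- selection_gradients(fit, fitness_trait)
    pred <- matrix(NA_real_, length(tr), ncol(sg$samples),
                   dimnames = list(fit$traits[tr], NULL))
    for (s in seq_len(ncol(sg$samples))) {
      orig <- sg$kept[s]
      Gp <- fit$G[tr, tr, orig, drop = FALSE][, , 1]
      if (mode == "MBE_rho0") Gp <- Gp * diag(nrow(Gp))
      pred[, s] <- Gp %*% sg$samples[, s]
    }
  }
  ok <- stats::complete.cases(t(pred))
  pred <- pred[, ok, drop = FALSE]
  out <- list(mode = mode, T_gen = T_gen,
              per_generation = pred, per_year = pred / T_gen)
  out$summary <- do.call(rbind, lapply(seq_len(nrow(pred)), function(t) {
    x <- out$per_year[t, ]
    data.frame(estimator = mode, trait = rownames(pred)[t], scale = "per_year",
               mode = posterior_mode(x), lower = hpd(x)[1],
               upper = hpd(x)[2], p_mcmc = p_mcmc(x))
  }))
  class(out) <- "qg_response"
  out
}

#' @export
print.qg_response <- function(x, ...) {
  cat("Predicted response (", x$mode, "), per year (T = ",
      x$T_gen, " y):\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Genetic/environmental decomposition of a fitness-component covariance
#'
#' Refits a bivariate animal model of the focal trait and one fitness
#' component on the appropriate data subset: relative annual reproductive
#' success of adult males (`ARS_M`) or females (`ARS_F`), or relative
#' overwinter survival of juveniles (`phi_juv`) or adults (`phi_ad`).
#' Annual measures are first relativized within sex-by-year cells and then
#' averaged per individual, so the component enters (like total fitness) as
#' one Gaussian record per individual with near-zero residual variance.
#'
#' @param phenotypes Capture table (see [fit_animal_model()]).
#' @param fitness_annual Per individual-year table with columns `id`,
#'   `sex`, `year`, `ars`, `survived`, and `cohort`.
#' @param ped A `qg_pedigree`.
#' @param component One of `"ARS_M"`, `"ARS_F"`, `"phi_juv"`, `"phi_ad"`.
#' @param trait Focal trait column, default `"mass"`.
#' @param min_n Data-sufficiency floor for the subset.
#' @param ... Passed to [fit_animal_model()] (e.g. `mcmc`).
#' @return A `qg_selection` from [selection_differential()], with the fit
#'   attached as attribute `fit`.
#' @export
decompose_by_component <- function(phenotypes, fitness_annual, ped,
                                   component = c("ARS_M", "ARS_F",
                                                 "phi_juv", "phi_ad"),
                                   trait = "mass", min_n = 30,
                                   fixed_formula = ~ sex *
                                     (date_s + date_s2) + f_ped, ...) {
  component <- match.arg(component)
  fa <- fitness_annual
  juv <- fa$year == fa$cohort
  sub <- switch(component,
    ARS_M = fa[!juv & fa$sex == "M", ],
    ARS_F = fa[!juv & fa$sex == "F", ],
    phi_juv = fa[juv, ],
    phi_ad = fa[!juv, ])
  value <- if (component %in% c("ARS_M", "ARS_F")) "ars" else "survived"
  if (value == "survived") {
    # overwinter survival out of the final monitored year is unobservable
    sub <- sub[!is.na(sub[[value]]) & sub$year < max(fa$year), , drop = FALSE]
  }
  if (length(unique(sub$id)) < min_n) {
    stop("subset for ", component, " has fewer than ", min_n, " individuals")
  }
  sub <- relativize_fitness(sub, value = value, by = "year")
  per_ind <- stats::aggregate(relative ~ id, data = sub, FUN = mean)
  names(per_ind)[2] <- "value"

  ph <- phenotypes
  keep_age <- if (component == "phi_juv") "juvenile" else "adult"
  ph <- ph[ph$age_class == keep_age & ph$id %in% sub$id, , drop = FALSE]
  if (component == "ARS_M") ph <- ph[ph$sex == "M", , drop = FALSE]
  if (component == "ARS_F") ph <- ph[ph$sex == "F", , drop = FALSE]
  per_ind <- per_ind[per_ind$id %in% ph$id, , drop = FALSE]

  # subsets hold a single age class, so the age terms of the default
  # capture correction would be aliased
  fit <- fit_animal_model(ph, ped, traits = trait, fitness = per_ind,
                          fixed_formula = fixed_formula, ...)
  out <- selection_differential(fit, trait = trait)
  out$component <- component
  attr(out, "fit") <- fit
  out
}
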
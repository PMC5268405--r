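#' Demography-corrected phenotypic trend
#'
#' The per-year slope of the population mean trait corrected for
#' demographic structure (sex, age, measurement date): per posterior sample
#' of the animal model, the least-squares slope of the year effects on
#' year. This is the "phenotypic trend" panel of the estimator comparison:
#' fixed effects absorb composition changes, so what remains in the year
#' term is the corrected year-specific mean.
#'
#' @param fit A `qg_animal_model` fitted with a `year` random term.
#' @param trait Trait name.
#' @return A `qg_trend`-shaped list: `slopes`, `mode`, `hpd`, `p_mcmc`,
#'   `year_means` (year x sample deviations from the model intercept).
#' @export
phenotypic_trend <- function(fit, trait = "mass") {
  if (is.null(fit$year_eff)) stop("model has no year random term")
  t <- .trait_index(fit, trait)
  ye <- fit$year_eff[, t, , drop = FALSE]
  yrs <- as.numeric(fit$year_levels)
  if (length(yrs) < 3) stop("need >= 3 years for a trend")
  S <- dim(ye)[3]
  X <- cbind(1, yrs)
  XtXi_Xt <- solve(crossprod(X)) %*% t(X)
  slopes <- vapply(seq_len(S), function(s) (XtXi_Xt %*% ye[, 1, s])[2], 0)
  out <- list(slopes = slopes, mode = posterior_mode(slopes),
              hpd = hpd(slopes), p_mcmc = p_mcmc(slopes),
              year_means = ye[, 1, ], cohort_years = yrs)
  class(out) <- "qg_trend"
  out
}

#' Run the full analysis pipeline on a synthetic or supplied study
#'
#' Stages: `simulate` (or load), `amatrix`, `fit_animal` (multivariate
#' mass/length/tail/fitness), `selection` (differential, gradients,
#' UBE/MBE/MBE_rho0/Price responses, component decomposition),
#' `evolution` (breeding-value trend, gene-drop drift null, Darwins),
#' `growth` (joint growth/survival model, year-group selection, phenology,
#' posterior predictive checks), `report`. Every stage writes tidy CSV/JSON
#' under `out_dir` and the manifest records seeds, input checksums and
#' timings.
#'
#' @param config A [sim_config()] (the generating world; its seed drives
#'   every stage).
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run (in canonical order).
#' @param animal_mcmc,growth_mcmc MCMC presets for the two samplers.
#' @param drift_sims Gene-dropping replicates.
#' @return The run manifest (list), invisibly; all artefacts on disk.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir,
                         stages = c("simulate", "amatrix", "fit_animal",
                                    "selection", "evolution", "growth",
                                    "report"),
                         animal_mcmc = mcmc_settings(seed = config$seed),
                         growth_mcmc = growth_mcmc_settings(
                           n_chains = 2, seed = config$seed),
                         drift_sims = 1000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("qgwild")),
                   seed = config$seed, stages = list())
  t_all <- Sys.time()
  env <- new.env()
  stage <- function(name, f) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- Sys.time()
    f()
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    message("[qgwild] stage ", name, " done (",
            manifest$stages[[name]]$seconds, " s)")
  }

  stage("simulate", function() {
    env$sim <- simulate_study(config)
    inp <- file.path(out_dir, "inputs")
    write_sim_data(env$sim, inp)
    manifest$input_checksums <<- as.list(tools::md5sum(
      list.files(inp, full.names = TRUE)))
  })

  stage("amatrix", function() {
    ped <- env$sim$pedigree
    Ainv <- a_inverse(ped)
    write_matrix_coo(Ainv, file.path(out_dir, "inputs", "a_inverse.csv"))
    env$T_gen <- generation_time(ped)
  })

  stage("fit_animal", function() {
    sim <- env$sim
    fitn <- data.frame(id = sim$lrs$id, value = sim$lrs$omega)
    env$fit <- fit_animal_model(
      sim$phenotypes, sim$pedigree,
      traits = c("mass", "body_length", "tail_length"),
      fitness = fitn, mcmc = animal_mcmc)
    dir.create(file.path(out_dir, "posteriors"), showWarnings = FALSE)
    .write_vc_samples(env$fit, file.path(out_dir, "posteriors",
                                         "animal_model_samples.csv"))
  })

  stage("selection", function() {
    fit <- env$fit
    T_gen <- env$T_gen %||% generation_time(env$sim$pedigree)
    env$sel <- selection_differential(fit, "mass")
    env$grad <- selection_gradients(fit)
    env$resp <- lapply(c("UBE", "MBE", "MBE_rho0", "Price"), function(m) {
      predict_response(fit, m, T_gen = T_gen)
    })
    names(env$resp) <- c("UBE", "MBE", "MBE_rho0", "Price")
    tabs <- do.call(rbind, lapply(env$resp, `[[`, "summary"))
    dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
    utils::write.csv(tabs, file.path(out_dir, "tables", "responses.csv"),
                     row.names = FALSE)
    utils::write.csv(env$sel$summary,
                     file.path(out_dir, "tables", "selection_mass.csv"),
                     row.names = FALSE)
  })

  stage("evolution", function() {
    fit <- env$fit
    sim <- env$sim
    T_gen <- env$T_gen %||% generation_time(sim$pedigree)
    env$price <- price_genetic_change(fit, "mass", T_gen = T_gen)
    env$trend <- blup_trend(fit, "mass")
    env$drift <- gene_drop_drift(sim$pedigree,
                                 va_samples = fit$G["mass", "mass", ],
                                 observed_slopes = env$price$per_year,
                                 n_sims = drift_sims, seed = config$seed + 7)
    env$pt <- phenotypic_trend(fit, "mass")
    mean_mass <- mean(sim$phenotypes$mass[sim$phenotypes$age_class == "adult"])
    env$darwins <- to_darwins(env$price$mode, mean_mass)
    ev <- data.frame(
      estimator = c("price_per_year", "blup_trend", "phenotypic_trend"),
      mode = c(env$price$mode, env$trend$mode, env$pt$mode),
      lower = c(env$price$hpd[1], env$trend$hpd[1], env$pt$hpd[1]),
      upper = c(env$price$hpd[2], env$trend$hpd[2], env$pt$hpd[2]),
      p_mcmc = c(env$price$p_mcmc, env$trend$p_mcmc, env$pt$p_mcmc))
    dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
    utils::write.csv(ev, file.path(out_dir, "tables", "evolution.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(drift_p = env$drift$p_drift, n_sims = drift_sims,
           darwins = env$darwins$darwins,
           darwins_formula = env$darwins$formula),
      file.path(out_dir, "tables", "drift_darwins.json"),
      auto_unbox = TRUE, digits = NA)
  })

  stage("growth", function() {
    sim <- env$sim
    juv <- sim$juveniles[sim$juveniles$n_captures > 0, ]
    surv_tab <- data.frame(id = juv$id, sex = juv$sex,
                           survived = juv$survived)
    env$gfit <- fit_growth_survival(sim$captures, sim$snow, surv_tab,
                                    mcmc = growth_mcmc)
    n_long <- config$snow$n_long_years
    yrs <- sort(unique(sim$snow$year))
    env$gsel <- selection_on_adult_mass(
      env$gfit, list(long = yrs[seq_len(n_long)],
                     short = yrs[-seq_len(n_long)]))
    env$phen <- phenology_regression(env$gfit)
    env$ppc <- posterior_predictive_check(env$gfit)
    gs <- do.call(rbind, lapply(env$gsel, `[[`, "summary"))
    dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
    utils::write.csv(gs, file.path(out_dir, "tables",
                                   "growth_selection.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(lag_mean = env$phen$lag_mean, lag_se = env$phen$lag_se,
           ppp_mass = env$ppc$ppp_mass, ppp_survival = env$ppc$ppp_survival,
           corr_a_logk = posterior_mode(env$gfit$corr_a_logk),
           max_rhat = max(env$gfit$diagnostics$rhat)),
      file.path(out_dir, "tables", "growth_summary.json"),
      auto_unbox = TRUE, digits = NA)
  })

  stage("report", function() {
    env$report <- make_report(env, out_dir)
  })

  manifest$total_seconds <- round(as.numeric(
    difftime(Sys.time(), t_all, units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(manifest, as.list(env)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flat CSV of the thinned covariance samples of a fit
.write_vc_samples <- function(fit, path) {
  k <- length(fit$traits)
  S <- dim(fit$G)[3]
  cols <- list()
  for (nm in c("G", "M", "P", "Y", "R")) {
    arr <- fit[[nm]]
    for (i in seq_len(k)) for (j in i:k) {
      cols[[paste0(nm, "_", fit$traits[i], "_", fit$traits[j])]] <- arr[i, j, ]
    }
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}

#' Build the summary report of a pipeline run
#'
#' Writes the six-estimator comparison (MBE, MBE with genetic correlations
#' constrained to zero, UBE, phenotypic trend, breeding-value trend,
#' Robertson-Price), the cohort breeding-value trajectory, the
#' fitness-component decomposition summary and growth/selection panels as
#' CSV tables plus base-graphics PDF figures.
#'
#' @param env Environment or list holding pipeline stage outputs (`fit`,
#'   `resp`, `price`, `trend`, `pt`, `gsel`, ...).
#' @param out_dir Run directory.
#' @return Data frame of the estimator comparison.
#' @export
make_report <- function(env, out_dir) {
  if (is.environment(env)) env <- as.list(env)
  need <- c("resp", "price", "trend", "pt")
  miss <- setdiff(need, names(env))
  if (length(miss)) {
    stop("report requires stage outputs: ", paste(miss, collapse = ", "))
  }
  pick <- function(r) r$summary[r$summary$trait == "mass",
                                c("mode", "lower", "upper")]
  six <- rbind(
    cbind(estimator = "MBE", pick(env$resp$MBE)),
    cbind(estimator = "MBE_rho0", pick(env$resp$MBE_rho0)),
    cbind(estimator = "UBE", pick(env$resp$UBE)),
    data.frame(estimator = "PT", mode = env$pt$mode,
               lower = env$pt$hpd[1], upper = env$pt$hpd[2]),
    data.frame(estimator = "TPBV", mode = env$trend$mode,
               lower = env$trend$hpd[1], upper = env$trend$hpd[2]),
    data.frame(estimator = "GCPE", mode = env$price$mode,
               lower = env$price$hpd[1], upper = env$price$hpd[2]))
  rownames(six) <- NULL
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  utils::write.csv(six, file.path(out_dir, "tables",
                                  "estimator_comparison.csv"),
                   row.names = FALSE)
  figdir <- file.path(out_dir, "figures")
  dir.create(figdir, showWarnings = FALSE)

  grDevices::pdf(file.path(figdir, "estimator_comparison.pdf"), 7, 5)
  bp <- graphics::barplot(six$mode, names.arg = six$estimator,
                          ylab = "rate of change in mass (g/year)",
                          ylim = range(c(six$lower, six$upper, 0)) * 1.1)
  graphics::arrows(bp, six$lower, bp, six$upper, angle = 90, code = 3,
                   length = 0.05)
  graphics::abline(h = 0, lty = 2)
  grDevices::dev.off()

  if (!is.null(env$trend)) {
    cm <- env$trend$cohort_means
    grDevices::pdf(file.path(figdir, "cohort_breeding_values.pdf"), 7, 5)
    yrs <- env$trend$cohort_years
    mid <- apply(cm, 1, stats::median)
    lo <- apply(cm, 1, function(x) hpd(x)[1])
    hi <- apply(cm, 1, function(x) hpd(x)[2])
    plot(yrs, mid, type = "b", pch = 19, ylim = range(c(lo, hi)),
         xlab = "cohort", ylab = "mean breeding value, mass (g)")
    graphics::arrows(yrs, lo, yrs, hi, angle = 90, code = 3, length = 0.04)
    graphics::abline(h = 0, lty = 3)
    grDevices::dev.off()
  }
  if (!is.null(env$gsel)) {
    grDevices::pdf(file.path(figdir, "survival_vs_mass.pdf"), 7, 5)
    cols <- c("brown", "red", "blue", "darkgreen")
    first <- TRUE
    i <- 0
    for (nm in names(env$gsel)) {
      i <- i + 1
      cv <- env$gsel[[nm]]$curve
      if (first) {
        plot(cv$a, cv$survival, type = "l", col = cols[i], ylim = c(0, 1),
             xlab = "predicted adult mass (g)",
             ylab = "overwinter survival probability")
        first <- FALSE
      } else graphics::lines(cv$a, cv$survival, col = cols[i])
    }
    graphics::legend("topright", legend = names(env$gsel),
                     col = cols[seq_along(env$gsel)], lty = 1)
    grDevices::dev.off()
  }
  six
}
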
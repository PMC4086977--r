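#' Configuration of the synthetic grazing-experiment generator
#'
#' Collects every parameter of the generator: design size (experiments,
#' plots, a per-experiment year count drawn from `years_range`), species-pool
#' size, the true fixed coefficients of the productivity model
#' (`productivity = beta0 + beta1 * exp(-k * CWM_LDMC) + beta_rain * rain +
#' u_exp + u_plot + eps`), the random-intercept standard deviations, the
#' residual dispersion model `sd(eps) = sigma0 * exp(-gamma * RaoQ_LDMC)`
#' (`gamma > 0` makes productivity more predictable at high functional
#' diversity), the fertility-diversity coupling of community assembly, and
#' the weather marginals.
#'
#' Defaults put the fixed coefficients at the values typical of long-term
#' grazing experiments on mesotrophic grassland (intercept -0.687, decay
#' amplitude 95.31 with rate k = 0.0170 per mg g^-1, rainfall slope 0.0018
#' LU ha^-1 yr^-1 per mm), with 9 experiments of 3 plots observed for 4-15
#' years.
#'
#' @param n_experiments Number of experiments (default 9).
#' @param plots_per_experiment Plots per experiment (default 3; one block per
#'   plot, so the full `experiment/block/plot` ladder is exercisable).
#' @param years_range Inclusive range the per-experiment year count is drawn
#'   from (default `c(4, 15)`).
#' @param n_species Species-pool size (default 40).
#' @param beta0,beta1,k,beta_rain True fixed coefficients (see above).
#' @param sigma_exp,sigma_plot Random-intercept SDs (LU ha^-1 yr^-1).
#' @param sigma0 Baseline residual SD at RaoQ_LDMC = 0.
#' @param gamma Resilience coupling (per unit RaoQ_LDMC); 0 = homoscedastic.
#' @param coupling Fertility-diversity coupling strength in `[0, 1]`: high
#'   fertility concentrates abundance on low-LDMC species, raising
#'   productivity while lowering RaoQ_LDMC (0 decouples them).
#' @param fd_effect Optional true fixed effect of an FD metric on mean
#'   productivity, as `c(<metric column> = slope)` computed on the
#'   generator's own metric values; default none (FD affects dispersion
#'   only).
#' @param rain_mean_range Range the per-experiment mean growing-season
#'   rainfall (mm) is drawn from (default `c(350, 750)`).
#' @param rain_sd Year-to-year rainfall SD within an experiment (mm).
#' @param temp_mean,temp_sd Growing-season mean temperature marginals
#'   (degrees C); temperature is generated but carries no true effect, so
#'   fixed-model simplification has a true-negative term to drop.
#' @param dirichlet_conc Dirichlet concentration of plot-year compositions
#'   (point-quadrat-like sampling noise; larger = less noisy).
#' @param year_fluct_sd SD of the lognormal yearly fluctuation multipliers on
#'   species weights.
#' @param fertility_year_sd SD of the yearly jitter on the plot fertility
#'   score (weather-driven shifts in which species are favoured; moves both
#'   CWM LDMC and RaoQ between years within a plot).
#' @param conc_log_sd Log-scale SD of the per-plot-year Dirichlet
#'   concentration (year-to-year shifts in dominance).
#' @param plot_lognormal_sd SD of the plot-level lognormal base-abundance
#'   profile across species.
#' @param fertility_jitter_sd SD of plot-level jitter around the experiment
#'   fertility score.
#' @param selection_strength LDMC-selection exponent scale at `coupling = 1`.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return Validated list of class `generator_config`.
#' @export
generatorConfig <- function(n_experiments = 9, plots_per_experiment = 3,
                            years_range = c(4, 15), n_species = 40,
                            beta0 = -0.687, beta1 = 95.31, k = 0.0170,
                            beta_rain = 0.0018,
                            sigma_exp = 0.06, sigma_plot = 0.08,
                            sigma0 = 0.10, gamma = 2.7, coupling = 1,
                            fd_effect = NULL,
                            rain_mean_range = c(450, 650), rain_sd = 90,
                            temp_mean = 12.5, temp_sd = 1.2,
                            dirichlet_conc = 60, year_fluct_sd = 0.7,
                            fertility_year_sd = 0.25, conc_log_sd = 1.2,
                            plot_lognormal_sd = 1,
                            fertility_jitter_sd = 0.18,
                            selection_strength = 2.5,
                            seed = 1L) {
  cfg <- list(n_experiments = n_experiments,
              plots_per_experiment = plots_per_experiment,
              years_range = years_range, n_species = n_species,
              beta0 = beta0, beta1 = beta1, k = k, beta_rain = beta_rain,
              sigma_exp = sigma_exp, sigma_plot = sigma_plot,
              sigma0 = sigma0, gamma = gamma, coupling = coupling,
              fd_effect = fd_effect,
              rain_mean_range = rain_mean_range, rain_sd = rain_sd,
              temp_mean = temp_mean, temp_sd = temp_sd,
              dirichlet_conc = dirichlet_conc, year_fluct_sd = year_fluct_sd,
              fertility_year_sd = fertility_year_sd, conc_log_sd = conc_log_sd,
              plot_lognormal_sd = plot_lognormal_sd,
              fertility_jitter_sd = fertility_jitter_sd,
              selection_strength = selection_strength,
              seed = as.integer(seed))
  validateGeneratorConfig(cfg)
  structure(cfg, class = "generator_config")
}

validateGeneratorConfig <- function(cfg) {
  stopifnot(cfg$n_experiments >= 1, cfg$plots_per_experiment >= 1,
            cfg$n_species >= 5)
  if (cfg$k <= 0) stop("decay rate k must be positive")
  for (nm in c("sigma_exp", "sigma_plot", "sigma0"))
    if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
  yr <- cfg$years_range
  if (length(yr) != 2L || yr[1] < 4 || yr[2] > 15 || yr[1] > yr[2])
    stop("years_range must lie within [4, 15]")
  if (cfg$coupling < 0 || cfg$coupling > 1) stop("coupling must lie in [0, 1]")
  invisible(cfg)
}

#' Generate a synthetic species pool with coded traits
#'
#' Draws grassland-plausible trait marginals for a species pool and builds
#' the coded trait table through the standard coding pipeline (raw long-form
#' entries with replication counts, scheme coding, replication-weighted
#' averaging): LDMC truncated-normal (mean 250, SD 60 mg g^-1, truncated to
#' [80, 500]); log SLA negatively correlated with LDMC; lognormal canopy
#' height and leaf size (stored logged); categorical coded traits drawn with
#' hemicryptophyte-dominated, mostly perennial frequencies.
#'
#' @param config A [generator_config][generatorConfig].
#' @param seed Optional seed; by default the current RNG state is used (the
#'   top-level [simulateGrazingData()] seeds once for the whole dataset).
#' @return A [trait_table][buildTraitTable]; the raw entries are attached as
#'   attribute `entries`.
#' @export
generateSpeciesPool <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- config$n_species
  sp <- sprintf("sp%03d", seq_len(S))

  ldmc <- numeric(S)
  for (i in seq_len(S)) {
    repeat { v <- stats::rnorm(1, 250, 60); if (v >= 80 && v <= 500) break }
    ldmc[i] <- v
  }
  z <- (ldmc - 250) / 60
  sla <- exp(3.1 - 0.3 * z + stats::rnorm(S, 0, 0.25))
  height <- exp(stats::rnorm(S, log(0.3), 0.6))
  leaf_size <- exp(stats::rnorm(S, log(400), 1))

  cat_draw <- function(labels, prob) sample(labels, S, replace = TRUE, prob = prob)
  life_form <- cat_draw(c("Hemicryptophyte", "Chamaephyte", "Geophyte", "Therophyte"),
                        c(0.70, 0.10, 0.10, 0.10))
  canopy_structure <- cat_draw(c("Rosette", "Hemirosette", "Erosulate"),
                               c(0.30, 0.40, 0.30))
  flowering <- month.name[sample(4:8, S, replace = TRUE,
                                 prob = c(0.15, 0.3, 0.3, 0.15, 0.1))]
  leafing <- cat_draw(c("Evergreen", "Summer green"), c(0.4, 0.6))
  life_span <- cat_draw(c("Annual", "Biennial", "Perennial"), c(0.1, 0.1, 0.8))
  rhizome <- cat_draw(c("Not rhizomatous", "Rhizomatous"), c(0.6, 0.4))
  stolon <- cat_draw(c("Not stoloniferous", "Stoloniferous"), c(0.7, 0.3))

  vals <- list(life_form = life_form, canopy_height = height,
               canopy_structure = canopy_structure, flowering_start = flowering,
               ldmc = ldmc, leaf_size = leaf_size, leafing_period = leafing,
               life_span = life_span, sla = sla, rhizome = rhizome,
               stolon = stolon)
  entries <- do.call(rbind, lapply(names(vals), function(tr) {
    data.frame(species_id = sp, trait_name = tr,
               value = as.character(vals[[tr]]),
               replication = sample(1:10, S, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  tab <- buildTraitTable(entries, defaultTraitSchemes())
  attr(tab, "entries") <- entries
  tab
}

#' Generate plot-year community compositions
#'
#' Dirichlet compositions per plot-year over the species pool. Each
#' experiment carries a fertility score (evenly spread over experiments,
#' jittered per plot); fertility tilts species weights toward low-LDMC
#' species with exponent `selection_strength * coupling * fertility`, which
#' both raises expected productivity (through CWM LDMC) and concentrates
#' abundance on functionally similar species, lowering RaoQ of LDMC — the
#' classic fertility-diversity trade-off. Yearly lognormal fluctuation
#' multipliers and finite Dirichlet concentration supply between-year and
#' sampling variation.
#'
#' @param pool A [trait_table][buildTraitTable] from [generateSpeciesPool()].
#' @param config A [generator_config][generatorConfig].
#' @param seed Optional seed (see [generateSpeciesPool()]).
#' @return A [community_matrix][communityMatrix]; per-plot fertility scores
#'   are attached as attribute `fertility`.
#' @export
generateCommunities <- function(pool, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(pool$values)
  sp <- traitSpecies(pool)
  z <- as.numeric(scale(pool$values[, "ldmc"]))

  n_exp <- config$n_experiments
  fert_exp <- if (n_exp == 1L) 0.5 else seq(0.1, 0.9, length.out = n_exp)
  sel <- config$selection_strength * config$coupling

  rows <- list(); keys <- list(); fert_plot <- list()
  ri <- 0L
  for (e in seq_len(n_exp)) {
    yr_choices <- seq(config$years_range[1], config$years_range[2])
    n_years <- if (length(yr_choices) == 1L) yr_choices else sample(yr_choices, 1L)
    years <- seq(2001L, length.out = n_years)
    for (pl in seq_len(config$plots_per_experiment)) {
      f <- min(1, max(0, fert_exp[e] + stats::rnorm(1, 0, config$fertility_jitter_sd)))
      base <- stats::rnorm(S, 0, config$plot_lognormal_sd)
      for (y in years) {
        f_y <- min(1, max(0, f + stats::rnorm(1, 0, config$fertility_year_sd)))
        w <- exp(base - sel * f_y * z + stats::rnorm(S, 0, config$year_fluct_sd))
        conc <- config$dirichlet_conc * exp(stats::rnorm(1, 0, config$conc_log_sd))
        shape <- conc * w / sum(w)
        g <- stats::rgamma(S, shape = shape)
        if (sum(g) <= 0) g[which.max(shape)] <- 1
        ri <- ri + 1L
        rows[[ri]] <- g / sum(g)
        keys[[ri]] <- data.frame(experiment = sprintf("exp%02d", e),
                                 block = sprintf("b%d", pl),
                                 plot = sprintf("p%d", pl), year = y)
        fert_plot[[ri]] <- f
      }
    }
  }
  abund <- do.call(rbind, rows)
  colnames(abund) <- sp
  cm <- communityMatrix(abund, do.call(rbind, keys))
  attr(cm, "fertility") <- unlist(fert_plot)
  cm
}

#' Generate plot-year productivity records with ground truth
#'
#' Builds the plot-year record table from generated communities: weather
#' (per-experiment rainfall regime, shared across plots within an
#' experiment-year; temperature generated with no true effect), and
#' productivity from the true mean structure
#' `beta0 + beta1 * exp(-k * CWM_LDMC) + beta_rain * rain` plus Gaussian
#' experiment and plot random intercepts and a residual whose SD follows
#' `sigma0 * exp(-gamma * RaoQ_LDMC)`. Negative productivity draws are
#' truncated at 0 and counted (defaults keep the truncation rate below 1%).
#'
#' @param communities A [community_matrix][communityMatrix].
#' @param pool The [trait_table][buildTraitTable] used to build it.
#' @param config A [generator_config][generatorConfig].
#' @param seed Optional seed (see [generateSpeciesPool()]).
#' @return List of class `synthetic_records`: `records` (data frame with
#'   `experiment`, `block`, `plot`, `year`, `productivity`, `rain`, `temp`)
#'   and `truth` (true coefficients and variance parameters, per-row
#'   `cwm_ldmc`, `rao_ldmc`, residual SD and residual draw, random
#'   intercepts, truncation count).
#' @export
generateRecords <- function(communities, pool, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keys <- communities$keys
  n <- nrow(keys)
  d_ldmc <- gowerDist(pool, subset = "ldmc")
  cwm_ldmc <- unname(apply(communities$abund, 1L, cwm, traits = pool, trait = "ldmc"))
  rao_ldmc <- unname(apply(communities$abund, 1L, raoQ, d = d_ldmc))

  exps <- unique(keys$experiment)
  rain_mean <- stats::setNames(
    stats::runif(length(exps), config$rain_mean_range[1], config$rain_mean_range[2]),
    exps)
  ey <- unique(keys[c("experiment", "year")])
  ey$rain <- pmax(50, stats::rnorm(nrow(ey), rain_mean[ey$experiment], config$rain_sd))
  ey$temp <- stats::rnorm(nrow(ey), config$temp_mean, config$temp_sd)
  wx <- merge(keys, ey, by = c("experiment", "year"), sort = FALSE)
  # merge keeps key order within experiment/year groups; realign to keys
  idx <- match(plotYearId(keys), plotYearId(wx))
  wx <- wx[idx, ]

  u_exp <- stats::setNames(stats::rnorm(length(exps), 0, config$sigma_exp), exps)
  plots <- unique(keys[c("experiment", "block", "plot")])
  plot_id <- function(k) paste(k$experiment, k$block, k$plot, sep = ".")
  u_plot <- stats::setNames(stats::rnorm(nrow(plots), 0, config$sigma_plot),
                            plot_id(plots))

  mu <- config$beta0 + config$beta1 * expDecay(cwm_ldmc, config$k) +
    config$beta_rain * wx$rain
  if (!is.null(config$fd_effect)) {
    met <- names(config$fd_effect)
    if (!identical(met, "rao_ldmc"))
      stop("fd_effect currently supports the 'rao_ldmc' metric only")
    mu <- mu + config$fd_effect[[1]] * rao_ldmc
  }
  sd_eps <- config$sigma0 * exp(-config$gamma * rao_ldmc)
  eps <- stats::rnorm(n, 0, sd_eps)
  prod_raw <- mu + u_exp[keys$experiment] + u_plot[plot_id(keys)] + eps
  truncated <- prod_raw < 0
  productivity <- pmax(0, prod_raw)

  records <- data.frame(keys,
                        productivity = productivity,
                        rain = wx$rain, temp = wx$temp)
  truth <- list(beta0 = config$beta0, beta1 = config$beta1, k = config$k,
                beta_rain = config$beta_rain,
                sigma_exp = config$sigma_exp, sigma_plot = config$sigma_plot,
                sigma0 = config$sigma0, gamma = config$gamma,
                cwm_ldmc = cwm_ldmc, rao_ldmc = rao_ldmc,
                sd_eps = sd_eps, eps = eps,
                u_exp = u_exp, u_plot = u_plot,
                n_truncated = sum(truncated))
  structure(list(records = records, truth = truth), class = "synthetic_records")
}

#' Generate a complete synthetic grazing-experiment dataset
#'
#' Seeds the RNG once from `config$seed` and runs the three generator stages
#' (species pool, communities, records), returning every component plus the
#' ground-truth sidecar. Identical configurations yield identical datasets.
#'
#' @param config A [generator_config][generatorConfig] (default
#'   `generatorConfig()`).
#' @return List of class `synthetic_dataset`: `traits`, `community`,
#'   `records`, `truth`, `config`.
#' @export
simulateGrazingData <- function(config = generatorConfig()) {
  validateGeneratorConfig(config)
  set.seed(config$seed)
  pool <- generateSpeciesPool(config)
  comm <- generateCommunities(pool, config)
  rec <- generateRecords(comm, pool, config)
  structure(list(traits = pool, community = comm,
                 records = rec$records, truth = rec$truth, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", length(unique(x$records$experiment)),
      " experiments, ", nrow(unique(x$records[c("experiment", "block", "plot")])),
      " plots, ", nrow(x$records), " plot-years, ",
      nrow(x$traits$values), " species\n", sep = "")
  cat("  true model: ", x$config$beta0, " + ", x$config$beta1,
      "*exp(-", x$config$k, "*LDMC) + ", x$config$beta_rain, "*rain",
      "; gamma = ", x$config$gamma, "\n", sep = "")
  if (x$truth$n_truncated > 0)
    cat("  ", x$truth$n_truncated, " productivity draw(s) truncated at 0\n")
  invisible(x)
}
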
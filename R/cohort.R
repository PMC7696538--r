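#' Specification for a synthetic cohort seizure log
#'
#' Describes the before/during-stimulation cohort design: 10 baseline days
#' followed by 10 stimulation days per animal, daily seizure counts Poisson
#' with a rate multiplier during stimulation, lognormal seizure durations
#' with a duration multiplier during stimulation, and a latent per-animal
#' coupling (PAC) level linearly linked to the animal's realized seizure-rate
#' change. Defaults reflect the study condition being emulated: baseline 1
#' seizure/day, a 23% rate decrease (multiplier 0.77), mean duration 60.84 s
#' falling to 44.67 s (multiplier 0.734), and a negative PAC-outcome link.
#'
#' @param n_animals Number of animals (>= 2).
#' @param baseline_seizure_rate Baseline rate in seizures/day.
#' @param dbs_rate_multiplier Rate multiplier during stimulation days (> 0).
#' @param mean_duration_s Mean seizure duration before stimulation (s).
#' @param dbs_duration_multiplier Duration multiplier during stimulation (> 0).
#' @param duration_cv Coefficient of variation of individual durations.
#' @param pac_outcome_slope Slope of the latent PAC level on the realized
#'   rate change (PAC units per seizure/day); negative means animals that
#'   improve more carry weaker coupling.
#' @param pac_mean,pac_noise_sd Location and residual SD of the latent PAC
#'   level (unitless coupling, 1e-2 decade).
#' @param n_days Days per phase (default 10).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 10, baseline_seizure_rate = 1.0,
                        dbs_rate_multiplier = 0.77,
                        mean_duration_s = 60.84,
                        dbs_duration_multiplier = 44.67 / 60.84,
                        duration_cv = 0.5, pac_outcome_slope = -0.01,
                        pac_mean = 0.02, pac_noise_sd = 0.004,
                        n_days = 10, seed = 1L) {
  if (n_animals < 2) stop("`n_animals` must be >= 2", call. = FALSE)
  if (dbs_rate_multiplier <= 0 || dbs_duration_multiplier <= 0)
    stop("multipliers must be > 0", call. = FALSE)
  if (baseline_seizure_rate < 0 || mean_duration_s <= 0 || duration_cv < 0)
    stop("invalid cohort parameters", call. = FALSE)
  structure(list(
    n_animals = as.integer(n_animals),
    baseline_seizure_rate = baseline_seizure_rate,
    dbs_rate_multiplier = dbs_rate_multiplier,
    mean_duration_s = mean_duration_s,
    dbs_duration_multiplier = dbs_duration_multiplier,
    duration_cv = duration_cv, pac_outcome_slope = pac_outcome_slope,
    pac_mean = pac_mean, pac_noise_sd = pac_noise_sd,
    n_days = as.integer(n_days), seed = seed
  ), class = "cohort_spec")
}

#' Generate a cohort-level behavioral seizure log
#'
#' Per animal: daily seizure counts are Poisson(baseline) for the "before"
#' days and Poisson(baseline * dbs_rate_multiplier) for the stimulation days;
#' each seizure receives a Racine grade in 3-6, a time of day, and a
#' lognormal duration with the specified mean and coefficient of variation,
#' multiplied by `dbs_duration_multiplier` during stimulation. Each animal
#' also carries a latent PAC level `pac_mean + pac_outcome_slope *
#' rate_change + noise`, where `rate_change = rate_before - rate_dbs`
#' (positive = fewer seizures during stimulation).
#'
#' @param spec A [cohort_spec].
#' @return An object of class `seizure_cohort`: list with `log` (data frame
#'   `animal_id`, `day`, `phase`, `seizure_time_s`, `racine_grade`,
#'   `duration_s`; one row per seizure) and `animals` (data frame
#'   `animal_id`, `pac_level`, `rate_before`, `rate_dbs`, `rate_change`).
#' @export
generate_seizure_log <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sdlog <- sqrt(log(1 + spec$duration_cv^2))
  meanlog_before <- log(spec$mean_duration_s) - sdlog^2 / 2
  with_seed(spec$seed, {
    rows <- list(); animals <- list()
    for (a in seq_len(spec$n_animals)) {
      id <- sprintf("rat%02d", a)
      counts_before <- stats::rpois(spec$n_days, spec$baseline_seizure_rate)
      counts_dbs <- stats::rpois(spec$n_days,
                                 spec$baseline_seizure_rate * spec$dbs_rate_multiplier)
      for (phase in c("before", "dbs")) {
        counts <- if (phase == "before") counts_before else counts_dbs
        mlog <- meanlog_before +
          if (phase == "dbs") log(spec$dbs_duration_multiplier) else 0
        for (d in seq_len(spec$n_days)) {
          k <- counts[d]
          if (k == 0L) next
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = id, day = d, phase = phase,
            seizure_time_s = sort(stats::runif(k, 0, 86400)),
            racine_grade = sample(3:6, k, replace = TRUE,
                                  prob = c(0.4, 0.3, 0.2, 0.1)),
            duration_s = stats::rlnorm(k, mlog, sdlog))
        }
      }
      rate_before <- sum(counts_before) / spec$n_days
      rate_dbs <- sum(counts_dbs) / spec$n_days
      rate_change <- rate_before - rate_dbs
      animals[[a]] <- data.frame(
        animal_id = id,
        pac_level = spec$pac_mean + spec$pac_outcome_slope * rate_change +
          stats::rnorm(1, 0, spec$pac_noise_sd),
        rate_before = rate_before, rate_dbs = rate_dbs,
        rate_change = rate_change)
    }
    log_df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(animal_id = character(), day = integer(), phase = character(),
                 seizure_time_s = numeric(), racine_grade = integer(),
                 duration_s = numeric())
    rownames(log_df) <- NULL
    structure(list(log = log_df, animals = do.call(rbind, animals)),
              class = "seizure_cohort")
  })
}

#' @export
print.seizure_cohort <- function(x, ...) {
  cat(sprintf("<seizure_cohort> %d animals, %d seizures logged\n",
              nrow(x$animals), nrow(x$log)))
  cat(sprintf("  mean rate before %.2f/day, during stimulation %.2f/day\n",
              mean(x$animals$rate_before), mean(x$animals$rate_dbs)))
  invisible(x)
}
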
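#' Percent change between two values
#'
#' `mode = "reduction"` gives `100 * (before - after) / before` (positive
#' when the quantity decreased); `mode = "increase"` gives
#' `100 * (after - before) / before`. The two modes are exact negatives of
#' each other.
#'
#' @param before,after Values before and after (before must be > 0).
#' @param mode `"reduction"` or `"increase"`.
#' @return Percent change (same length as the inputs).
#' @examples
#' percent_change(5.17, 3.37)                 # IED-rate reduction, ~34.8
#' percent_change(25.9, 30.3, "increase")     # theta amplification, ~17
#' @export
percent_change <- function(before, after, mode = c("reduction", "increase")) {
  mode <- match.arg(mode)
  if (any(!is.finite(before)) || any(before <= 0))
    stop("`before` must be positive and finite", call. = FALSE)
  if (mode == "reduction") 100 * (before - after) / before
  else 100 * (after - before) / before
}

#' Compare two samples (paired, unpaired or one-way ANOVA)
#'
#' Standard two-sided tests as used for the group-level comparisons: paired
#' t-test for pre/post designs, Welch t-test for unpaired group contrasts
#' (configurable to pooled variance), and one-way ANOVA when `values_a` is a
#' list of three or more groups. Identical paired samples return `t = 0`,
#' `p = 1` rather than an error. No multiplicity correction is applied.
#'
#' @param values_a Numeric vector, or a list of numeric vectors for
#'   `design = "anova"`.
#' @param values_b Numeric vector (ignored for ANOVA on a list).
#' @param design `"paired"`, `"unpaired"` or `"anova"`.
#' @param var_equal Pool variances for the unpaired test / ANOVA
#'   (default `FALSE` for the t-test, classic pooled ANOVA otherwise).
#' @return An object of class `group_comparison`: list with `statistic`,
#'   `p_value`, `df`, `method`.
#' @export
compare_groups <- function(values_a, values_b = NULL,
                           design = c("paired", "unpaired", "anova"),
                           var_equal = FALSE) {
  design <- match.arg(design)
  if (design == "anova") {
    groups <- if (is.list(values_a)) values_a else list(values_a, values_b)
    groups <- Filter(Negate(is.null), groups)
    if (length(groups) < 2L || any(lengths(groups) < 2L))
      stop("ANOVA needs >= 2 groups with >= 2 values each", call. = FALSE)
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
    out <- list(statistic = unname(ft$statistic), p_value = ft$p.value,
                df = unname(ft$parameter), method = "one-way ANOVA")
  } else {
    if (length(values_a) < 2L || length(values_b) < 2L)
      stop("need at least 2 values per group", call. = FALSE)
    if (design == "paired") {
      if (length(values_a) != length(values_b))
        stop("paired design requires equal lengths", call. = FALSE)
      d <- values_a - values_b
      if (all(d == 0)) {
        out <- list(statistic = 0, p_value = 1, df = length(d) - 1,
                    method = "paired t-test")
      } else {
        tt <- stats::t.test(values_a, values_b, paired = TRUE)
        out <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                    df = unname(tt$parameter), method = "paired t-test")
      }
    } else {
      tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
      out <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                  df = unname(tt$parameter),
                  method = if (var_equal) "pooled t-test" else "Welch t-test")
    }
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic=%.3f, df=%.3g, p=%.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pearson correlation between an outcome and a predictor
#'
#' @param outcome,predictor Numeric vectors (>= 3 complete pairs).
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate_outcome <- function(outcome, predictor) {
  ok <- stats::complete.cases(outcome, predictor)
  x <- outcome[ok]; y <- predictor[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Assemble the per-animal outcome table
#'
#' Joins the behavioral seizure log with discharge-rate and PAC tables into
#' one row per animal: seizure rates before and during stimulation and their
#' difference `rate_change = rate_before - rate_dbs` (positive = fewer
#' seizures during stimulation), mean seizure durations per phase, mean
#' discharge rates (total and per subtype), and mean MaxPAC per epoch, side
#' and fA band. Animals absent from a predictor table get explicit `NA`s;
#' predictor rows for unknown animals raise a join error naming them.
#'
#' @param seizure_logs A `seizure_cohort` from [generate_seizure_log()] or a
#'   seizure-log data frame (`animal_id`, `day`, `phase`, `duration_s`).
#' @param ied_tables Optional data frame with `animal_id` and columns
#'   `rate`, `spike_rate`, `polyspike_rate`, `sharp_wave_rate` (one or more
#'   rows per animal; averaged).
#' @param pac_tables Optional data frame as returned by [epoch_pac()]
#'   (rows averaged per animal x epoch x channel x fA band, then spread to
#'   columns `pac_<epoch>_<side>_<band>`).
#' @param n_days Days per phase used to convert counts to rates (default 10).
#' @return Data frame of class `outcome_table`, one row per animal.
#' @export
summarize_outcomes <- function(seizure_logs, ied_tables = NULL,
                               pac_tables = NULL, n_days = 10) {
  if (inherits(seizure_logs, "seizure_cohort")) {
    log_df <- seizure_logs$log
    ids <- sort(unique(seizure_logs$animals$animal_id))  # keeps seizure-free animals
  } else {
    log_df <- as.data.frame(seizure_logs)
    ids <- sort(unique(log_df$animal_id))
  }
  if (!length(ids)) stop("empty seizure log", call. = FALSE)
  base <- do.call(rbind, lapply(ids, function(id) {
    sub <- log_df[log_df$animal_id == id, ]
    nb <- sum(sub$phase == "before"); nd <- sum(sub$phase == "dbs")
    data.frame(
      animal_id = id,
      rate_before = nb / n_days, rate_dbs = nd / n_days,
      rate_change = (nb - nd) / n_days,
      mean_duration_before_s = if (nb) mean(sub$duration_s[sub$phase == "before"]) else NA_real_,
      mean_duration_dbs_s = if (nd) mean(sub$duration_s[sub$phase == "dbs"]) else NA_real_)
  }))

  check_ids <- function(tab, what) {
    extra <- setdiff(unique(tab$animal_id), ids)
    if (length(extra))
      stop(sprintf("join error: %s table has unmatched animals: %s", what,
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(ied_tables)) {
    ied_tables <- as.data.frame(ied_tables)
    check_ids(ied_tables, "IED")
    for (col in c("rate", "spike_rate", "polyspike_rate", "sharp_wave_rate")) {
      if (!col %in% names(ied_tables)) next
      agg <- tapply(ied_tables[[col]], ied_tables$animal_id, mean)
      base[[paste0("mean_ied_", col)]] <- unname(agg[base$animal_id])
    }
  }
  if (!is.null(pac_tables)) {
    pac_tables <- as.data.frame(pac_tables)
    check_ids(pac_tables, "PAC")
    key <- interaction(pac_tables$epoch, pac_tables$channel,
                       pac_tables$fa_band, drop = TRUE)
    for (k in levels(key)) {
      sub <- pac_tables[key == k, ]
      col <- paste0("pac_", gsub("\\.", "_", k))
      agg <- tapply(sub$max_pac, sub$animal_id, mean)
      base[[col]] <- unname(agg[base$animal_id])
    }
  }
  rownames(base) <- NULL
  class(base) <- c("outcome_table", "data.frame")
  base
}

#' Correlations between seizure-rate change and PAC strength
#'
#' Emits the epoch x side x fA band correlation grid: Pearson r and p of
#' `rate_change` against each `pac_*` column of the outcome table.
#'
#' @param outcomes An `outcome_table` from [summarize_outcomes()].
#' @return Data frame with `epoch`, `channel`, `fa_band`, `r`, `p_value`, `n`.
#' @export
pac_outcome_correlations <- function(outcomes) {
  cols <- grep("^pac_", names(outcomes), value = TRUE)
  if (!length(cols)) stop("outcome table has no PAC columns", call. = FALSE)
  rows <- lapply(cols, function(col) {
    parts <- strsplit(sub("^pac_", "", col), "_")[[1]]
    ct <- correlate_outcome(outcomes$rate_change, outcomes[[col]])
    data.frame(epoch = parts[1],
               channel = paste(parts[2:3], collapse = "_"),
               fa_band = paste(parts[-(1:3)], collapse = "_"),
               r = ct$r, p_value = ct$p_value, n = ct$n)
  })
  do.call(rbind, rows)
}

#' Day-course of discharge rates and first/last-day comparison
#'
#' @param ied_tables Data frame with `animal_id`, `group`, `day_index` and
#'   `rate` (bilateral events/min).
#' @return List with `day_means` (mean rate per group x day) and
#'   `day1_vs_day10` (paired comparison per group over animals present on
#'   both the first and the last day; `NULL` when fewer than 2).
#' @export
day_course <- function(ied_tables) {
  tab <- as.data.frame(ied_tables)
  if (!nrow(tab)) return(list(day_means = tab, day1_vs_day10 = NULL))
  if (!"group" %in% names(tab)) tab$group <- "all"
  day_means <- stats::aggregate(rate ~ group + day_index, data = tab, FUN = mean)
  day_means <- day_means[order(day_means$group, day_means$day_index), ]
  rownames(day_means) <- NULL
  d1 <- min(tab$day_index); d10 <- max(tab$day_index)
  tests <- list()
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, ]
    a <- sub$rate[sub$day_index == d1][match(
      intersect(sub$animal_id[sub$day_index == d1],
                sub$animal_id[sub$day_index == d10]),
      sub$animal_id[sub$day_index == d1])]
    b <- sub$rate[sub$day_index == d10][match(
      intersect(sub$animal_id[sub$day_index == d1],
                sub$animal_id[sub$day_index == d10]),
      sub$animal_id[sub$day_index == d10])]
    if (length(a) >= 2L && d10 > d1)
      tests[[g]] <- compare_groups(a, b, "paired")
  }
  list(day_means = day_means,
       day1_vs_day10 = if (length(tests)) tests else NULL)
}
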
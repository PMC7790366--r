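#' Per-item chosen frequency
#'
#' Number of trials in which each item was chosen; the counts sum to the
#' number of trials.
#'
#' @inheritParams log_likelihood
#' @return Integer vector of length `n_items`.
#' @export
chosen_frequency <- function(data) {
  n_items <- .check_data(data)
  tabulate(data$chosen, nbins = n_items)
}

#' Conflict annotation of trials from chosen-frequency differences
#'
#' Decision conflict is operationalized per trial as the absolute
#' difference in the two on-screen items' overall chosen frequencies:
#' similar frequencies mean similarly preferred items, hence high
#' conflict. Trials whose difference is strictly below the participant's
#' mean difference are labelled `large` conflict; all others (including
#' those exactly at the threshold) `small`.
#'
#' @inheritParams log_likelihood
#' @return Data frame with per-trial `freq_diff` and `conflict`
#'   (`"large"`/`"small"`), plus attributes `threshold` (the mean
#'   difference) and `all_at_threshold` (flag for the degenerate case of
#'   identical differences, when every trial falls at the threshold and
#'   is labelled `small`).
#' @export
conflict_split <- function(data) {
  freq <- chosen_frequency(data)
  d <- abs(freq[data$left] - freq[data$right])
  thr <- mean(d)
  out <- data.frame(trial = data$trial, freq_diff = d,
                    conflict = ifelse(d < thr, "large", "small"))
  attr(out, "threshold") <- thr
  attr(out, "all_at_threshold") <- all(d == thr)
  out
}

# Participant-level RT trimming: keep trials with RT inside mean +/- 3 SD,
# the threshold computed once over all of the participant's trials.
.rt_keep <- function(rt) {
  m <- mean(rt); s <- stats::sd(rt)
  if (is.na(s) || s == 0) return(rep(TRUE, length(rt)))
  rt >= m - 3 * s & rt <= m + 3 * s
}

.fisher_z <- function(r) atanh(r)

#' Reaction-time conflict analysis over a cohort
#'
#' Per participant: trials with RT outside that participant's mean +/- 3
#' SD (computed once over all their trials) are excluded; mean RT is
#' computed per conflict condition of [conflict_split()]; and the Pearson
#' correlation between RT and chosen-frequency difference is computed on
#' the same trimmed trials and Fisher-Z transformed. Cohort level: a
#' paired t-test of large- vs small-conflict mean RTs and a one-sample
#' t-test of the Fisher Z values against 0. Participants lacking two
#' trials in a condition are dropped from the paired test with a note;
#' participants with undefined correlation are dropped from the Z test.
#'
#' @param cohort List of `cbl_data` data frames with an `rt` column in
#'   seconds.
#' @return A list with `participants` (per-participant data frame:
#'   `participant`, `n_excluded`, `mean_rt_large`, `mean_rt_small`, `r`,
#'   `z`), `paired_test` (`t`, `df`, `p`, `mean_large`, `mean_small`,
#'   `n`), `z_test` (`mean_z`, `se_z`, `t`, `df`, `p`, `n`) and
#'   `dropped` (ids excluded from the paired test).
#' @export
rt_conflict_tests <- function(cohort) {
  per <- lapply(cohort, function(d) {
    if (!"rt" %in% names(d) || all(is.na(d$rt)))
      stop("rt_conflict_tests needs rt values", call. = FALSE)
    ann <- conflict_split(d)
    keep <- .rt_keep(d$rt)
    rt <- d$rt[keep]; lab <- ann$conflict[keep]; fd <- ann$freq_diff[keep]
    r <- if (stats::sd(rt) > 0 && stats::sd(fd) > 0)
      stats::cor(rt, fd) else NA_real_
    data.frame(
      participant = d$participant[1],
      n_excluded = sum(!keep),
      n_large = sum(lab == "large"), n_small = sum(lab == "small"),
      mean_rt_large = if (any(lab == "large")) mean(rt[lab == "large"]) else NA_real_,
      mean_rt_small = if (any(lab == "small")) mean(rt[lab == "small"]) else NA_real_,
      r = r, z = .fisher_z(r))
  })
  per <- do.call(rbind, per)
  ok <- per$n_large >= 2 & per$n_small >= 2 &
    !is.na(per$mean_rt_large) & !is.na(per$mean_rt_small)
  paired <- if (sum(ok) >= 3) {
    tt <- stats::t.test(per$mean_rt_large[ok], per$mean_rt_small[ok],
                        paired = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value,
         mean_large = mean(per$mean_rt_large[ok]),
         mean_small = mean(per$mean_rt_small[ok]), n = sum(ok))
  } else NULL
  zs <- per$z[!is.na(per$z) & is.finite(per$z)]
  z_test <- if (length(zs) >= 3) {
    tt <- stats::t.test(zs, mu = 0)
    list(mean_z = mean(zs), se_z = stats::sd(zs) / sqrt(length(zs)),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, n = length(zs))
  } else NULL
  list(participants = per, paired_test = paired, z_test = z_test,
       dropped = per$participant[!ok])
}

#' Rating-frequency consistency analysis over a cohort
#'
#' Per participant: items are median-split on chosen frequency into
#' high- and low-frequency groups (with an odd item count the median
#' item joins the low-frequency group), and their mean 5-point ratings
#' are compared; the Pearson correlation between chosen frequency and
#' rating is Fisher-Z transformed. Cohort level: a paired t-test of the
#' high- vs low-frequency mean ratings and a one-sample t-test of Z
#' against 0. Participants with zero rating variance have an undefined
#' correlation and are flagged and excluded from the Z test.
#'
#' @param cohort List of `cbl_data` data frames.
#' @param ratings List (parallel to `cohort`) of data frames with
#'   columns `item` and `rating` (integers 1-5), or one long data frame
#'   with a `participant` column.
#' @return A list with `participants` (per-participant `participant`,
#'   `mean_rating_hf`, `mean_rating_lf`, `r`, `z`), `paired_test`,
#'   `z_test` (same shapes as in [rt_conflict_tests()]) and `flagged`
#'   (ids with undefined correlation).
#' @export
rating_consistency <- function(cohort, ratings) {
  if (is.data.frame(ratings)) {
    ratings <- split(ratings, ratings$participant)
    ratings <- ratings[match(vapply(cohort, function(d)
      as.character(d$participant[1]), character(1)), names(ratings))]
  }
  stopifnot(length(ratings) == length(cohort))
  per <- Map(function(d, rat) {
    if (any(!rat$rating %in% 1:5))
      stop("ratings must be integers in 1..5", call. = FALSE)
    n_items <- .check_data(d)
    freq <- chosen_frequency(d)
    rvec <- rat$rating[match(seq_len(n_items), rat$item)]
    if (anyNA(rvec)) stop("ratings missing for some items", call. = FALSE)
    med <- stats::median(freq)
    hf <- freq > med
    lf <- !hf   # median item(s) join the low-frequency group
    r <- if (stats::sd(rvec) > 0 && stats::sd(freq) > 0)
      stats::cor(freq, rvec) else NA_real_
    data.frame(participant = d$participant[1],
               mean_rating_hf = mean(rvec[hf]),
               mean_rating_lf = mean(rvec[lf]),
               r = r, z = .fisher_z(r))
  }, cohort, ratings)
  per <- do.call(rbind, per)
  ok <- !is.na(per$mean_rating_hf) & !is.na(per$mean_rating_lf)
  paired <- if (sum(ok) >= 3) {
    tt <- stats::t.test(per$mean_rating_hf[ok], per$mean_rating_lf[ok],
                        paired = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value,
         mean_hf = mean(per$mean_rating_hf[ok]),
         mean_lf = mean(per$mean_rating_lf[ok]), n = sum(ok))
  } else NULL
  zs <- per$z[!is.na(per$z) & is.finite(per$z)]
  z_test <- if (length(zs) >= 3) {
    tt <- stats::t.test(zs, mu = 0)
    list(mean_z = mean(zs), se_z = stats::sd(zs) / sqrt(length(zs)),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, n = length(zs))
  } else NULL
  list(participants = per, paired_test = paired, z_test = z_test,
       flagged = per$participant[is.na(per$z)])
}
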
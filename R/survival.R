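# Survival-curve estimation and log-rank comparison for fly lifespan cohorts.
# The product-limit estimate comes from the survival package; the Mantel-Cox
# test is the explicit per-event-time summation (tied deaths pooled into one
# event time with hypergeometric variance), which stays defined on the fully
# degenerate tables that arise in tiny cohorts. Median = first time survival
# drops to 0.5 or below.

as_death_df <- function(x, arg = "deaths") {
  if (is.numeric(x)) {
    if (length(x) == 0L) stop_fmt("'%s' is empty", arg)
    return(data.frame(death_day = as.numeric(x), censored = FALSE))
  }
  if (!is.data.frame(x) || !"death_day" %in% names(x))
    stop_fmt("'%s' must be a numeric vector or a data.frame with a 'death_day' column",
             arg)
  if (nrow(x) == 0L) stop_fmt("'%s' has no records", arg)
  if (any(x$death_day <= 0)) stop_fmt("'%s' has non-positive death days", arg)
  data.frame(death_day = as.numeric(x$death_day),
             censored = if ("censored" %in% names(x)) as.logical(x$censored)
               else FALSE)
}

#' Kaplan-Meier survival curve for one cohort
#'
#' Product-limit estimate of the survivor function from individual death
#' records, optionally restricted to one group and diet. Right-censored
#' records (flies lost to handling or starvation before death) reduce the
#' risk set without contributing an event.
#'
#' @param deaths death records: numeric death days, or a data.frame with
#'   `death_day` and optional `censored`, `group_id`, `diet` columns.
#' @param group optional `group_id` to restrict to.
#' @param diet optional diet to restrict to.
#' @return object of class `survival_curve`: data.frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (survival just after `time`),
#'   one row per distinct observed time.
#' @export
km_curve <- function(deaths, group = NULL, diet = NULL) {
  if (is.data.frame(deaths)) {
    if (!is.null(group)) {
      if (!"group_id" %in% names(deaths))
        stop_fmt("death records carry no 'group_id' column")
      deaths <- deaths[deaths$group_id %in% group, , drop = FALSE]
    }
    if (!is.null(diet)) {
      if (!"diet" %in% names(deaths))
        stop_fmt("death records carry no 'diet' column")
      deaths <- deaths[deaths$diet %in% diet, , drop = FALSE]
    }
    if (nrow(deaths) == 0L)
      stop_fmt("no death records for the requested group/diet")
  }
  df <- as_death_df(deaths)
  fit <- survival::survfit(
    survival::Surv(df$death_day, !df$censored) ~ 1,
    conf.type = "none")
  out <- data.frame(time = fit$time,
                    n_risk = fit$n.risk,
                    n_event = fit$n.event,
                    n_censor = fit$n.censor,
                    surv = fit$surv)
  rownames(out) <- NULL
  structure(out, class = c("survival_curve", "data.frame"))
}

#' Median lifespan from a survival curve
#'
#' The smallest observed event time at which survival has dropped to 0.5 or
#' below. No interpolation is used: with deaths recorded on a 2-day check
#' grid, interpolated medians would suggest spurious precision. If survival
#' never reaches 0.5 (heavy censoring), the median is undefined and `NA` is
#' returned with a warning.
#'
#' @param curve a `survival_curve` from [km_curve()].
#' @return the median in days (an observed event time), or `NA`.
#' @export
median_lifespan <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  ev <- curve[curve$n_event > 0, , drop = FALSE]
  hit <- which(ev$surv <= 0.5)
  if (length(hit) == 0L) {
    warn_fmt("survival never reaches 0.5; median lifespan undefined")
    return(NA_real_)
  }
  ev$time[hit[1L]]
}

#' Mantel-Cox log-rank test for two lifespan cohorts
#'
#' At each distinct pooled event time j with d_j deaths among n_j flies at
#' risk (n_Aj in group A), the expected A-deaths are E_Aj = d_j n_Aj / n_j
#' with hypergeometric variance
#' V_j = d_j (n_Aj/n_j)(1 - n_Aj/n_j)(n_j - d_j)/(n_j - 1); times with
#' n_j = 1 contribute zero variance. The statistic is U^2 / V with
#' U = sum(d_Aj - E_Aj), V = sum V_j, referred to a chi-square with 1 df.
#' Tied deaths share one event time.
#'
#' @param deaths_a,deaths_b the two cohorts, each a numeric vector of death
#'   days or a data.frame with `death_day` and optional `censored`.
#' @return object of class `logrank_result`: list with `U` (observed minus
#'   expected in group A), `V`, `statistic`, `df` (1), `p`. When the pooled
#'   variance is zero the statistic is undefined and p = 1 (warning).
#' @export
logrank_test <- function(deaths_a, deaths_b) {
  a <- as_death_df(deaths_a, "deaths_a")
  b <- as_death_df(deaths_b, "deaths_b")
  if (!any(!a$censored) || !any(!b$censored))
    stop_fmt("each group needs at least one uncensored event")
  times <- sort(unique(c(a$death_day[!a$censored], b$death_day[!b$censored])))
  # risk sets: censored-at-t records are still at risk during the event at t
  nA <- vapply(times, function(t) sum(a$death_day >= t), numeric(1))
  nB <- vapply(times, function(t) sum(b$death_day >= t), numeric(1))
  dA <- vapply(times, function(t) sum(a$death_day == t & !a$censored),
               numeric(1))
  dB <- vapply(times, function(t) sum(b$death_day == t & !b$censored),
               numeric(1))
  n <- nA + nB; d <- dA + dB
  U <- sum(dA - d * nA / n)
  vj <- ifelse(n > 1,
               d * (nA / n) * (1 - nA / n) * (n - d) / pmax(n - 1, 1), 0)
  V <- sum(vj)
  if (!is.finite(V) || V <= 0) {
    warn_fmt("log-rank variance is zero; statistic undefined, p set to 1")
    return(structure(list(U = U, V = V, statistic = NA_real_, df = 1L, p = 1),
                     class = "logrank_result"))
  }
  stat <- U^2 / V
  structure(list(U = U, V = V, statistic = stat, df = 1L,
                 p = stats::pchisq(stat, df = 1L, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: U = %.4g, V = %.4g, chisq(1) = %.4g, p = %.4g\n",
              x$U, x$V, x$statistic, x$p))
  invisible(x)
}

#' Per-group survival summary with all pairwise log-rank tests
#'
#' Computes the median lifespan of every group (ordered by group id) and the
#' log-rank p-value for every pair of groups, the layout of a multi-panel
#' lifespan figure.
#'
#' @param deaths data.frame with `group_id`, `death_day` and optional
#'   `censored`, `diet` columns.
#' @param diet optional diet to restrict to.
#' @return list with `medians` (data.frame `group_id`, `n`, `median`) and
#'   `pairwise` (data.frame `group_a`, `group_b`, `statistic`, `p`; zero rows
#'   for a single group).
#' @export
survival_report <- function(deaths, diet = NULL) {
  stopifnot(is.data.frame(deaths), "group_id" %in% names(deaths))
  if (!is.null(diet)) {
    if (!"diet" %in% names(deaths))
      stop_fmt("death records carry no 'diet' column")
    deaths <- deaths[deaths$diet %in% diet, , drop = FALSE]
  }
  if (nrow(deaths) == 0L) stop_fmt("no death records to report on")
  groups <- sort(unique(as.character(deaths$group_id)))
  medians <- data.frame(group_id = groups,
                        n = NA_integer_, median = NA_real_,
                        stringsAsFactors = FALSE)
  per_group <- list()
  for (i in seq_along(groups)) {
    sub <- deaths[deaths$group_id == groups[i], , drop = FALSE]
    per_group[[groups[i]]] <- sub
    medians$n[i] <- nrow(sub)
    medians$median[i] <- median_lifespan(km_curve(sub))
  }
  if (length(groups) < 2L) {
    pairwise <- data.frame(group_a = character(0), group_b = character(0),
                           statistic = numeric(0), p = numeric(0))
  } else {
    combos <- utils::combn(groups, 2L)
    pairwise <- data.frame(group_a = combos[1L, ], group_b = combos[2L, ],
                           statistic = NA_real_, p = NA_real_,
                           stringsAsFactors = FALSE)
    for (k in seq_len(ncol(combos))) {
      lr <- logrank_test(per_group[[combos[1L, k]]],
                         per_group[[combos[2L, k]]])
      pairwise$statistic[k] <- lr$statistic
      pairwise$p[k] <- lr$p
    }
  }
  list(medians = medians, pairwise = pairwise)
}
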
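# Kaplan-Meier estimation, log-rank comparison with hazard-ratio summary,
# and best-cutoff marker dichotomization.
#
# The product-limit and log-rank machinery is delegated to the `survival`
# package; this module adds the O/E hazard-ratio summary and the
# quantile-grid best-cutoff scan.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function under right censoring.
#' Records censored at an event time are counted at risk for that time
#' (standard convention).
#'
#' @param time positive follow-up times (e.g. months).
#' @param event event indicator: 1 = event, 0 = censored.
#' @return object of class `km_curve`: `time` (distinct event/censoring
#'   times), `surv` (S(t)), `n_risk`, `n_event`.
#' @export
km_estimate <- function(time, event) {
  assert_that(length(time) >= 1, "empty survival input")
  assert_that(all(time > 0), "times must be positive")
  assert_that(all(event %in% c(0, 1)), "event flags must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d time points, final S(t) = %.3f\n",
              length(x$time), x$surv[length(x$surv)]))
  invisible(x)
}

#' Two-group log-rank test with O/E hazard ratio
#'
#' Standard two-group log-rank chi-square on 1 degree of freedom, with the
#' hazard ratio summarized from observed/expected event counts,
#' `HR = (O1/E1) / (O2/E2)` — the KM-Plotter-style summary rather than a
#' Cox fit.
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level grouping vector; the first level (sorted, or
#'   factor order) is the numerator of the hazard ratio.
#' @return object of class `logrank_result`: `chisq`, `p`, `observed`,
#'   `expected` (named per group), `hr`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  assert_that(nlevels(droplevels(group)) == 2,
              "exactly two non-empty groups required")
  assert_that(sum(event) > 0, "no events in either group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  obs <- as.vector(sd$obs); exp <- as.vector(sd$exp)
  names(obs) <- names(exp) <- levels(droplevels(group))
  hr <- if (all(exp > 0) && obs[2] > 0) {
    (obs[1] / exp[1]) / (obs[2] / exp[2])
  } else NA_real_
  structure(list(chisq = sd$chisq,
                 p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 observed = obs, expected = exp, hr = unname(hr)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("logrank: chisq = %.3f, p = %.3g, HR = %.3f\n",
              x$chisq, x$p, x$hr))
  invisible(x)
}

#' Best-cutoff marker dichotomization scan
#'
#' Emulates the KM-Plotter "best cutoff" filter: candidate cutoffs are the
#' marker quantiles from 10% to 90% in 5% steps (configurable); for each,
#' patients are split into low (`marker <= cutoff`) and high arms and a
#' log-rank test is computed; the selected cutoff minimizes the log-rank
#' p-value. Because the minimum is taken over many correlated tests, the
#' selected p-value is multiplicity-biased (anticonservative); the result
#' carries an explicit flag and no correction is applied.
#'
#' @param time,event as in [km_estimate()].
#' @param marker scalar marker per patient (expression, methylation, ...).
#' @param probs quantile grid for candidate cutoffs.
#' @return object of class `cutoff_scan`: `scan` (data.frame cutoff, n_low,
#'   n_high, chisq, p), `best_cutoff`, `best_p`, `best_hr` (low vs high),
#'   `multiplicity_biased = TRUE`.
#' @export
best_cutoff_scan <- function(time, event, marker,
                             probs = seq(0.10, 0.90, by = 0.05)) {
  assert_that(length(time) >= 20,
              "need >= 20 patients for a cutoff scan")
  assert_that(stats::sd(marker) > 0, "marker is constant")
  cand <- sort(unique(unname(stats::quantile(marker, probs, type = 7))))
  rows <- lapply(cand, function(ct) {
    low <- marker <= ct
    if (!any(low) || all(low)) return(NULL)
    grp <- factor(ifelse(low, "low", "high"), levels = c("low", "high"))
    if (sum(event) == 0) return(NULL)
    lr <- logrank_test(time, event, grp)
    data.frame(cutoff = ct, n_low = sum(low), n_high = sum(!low),
               chisq = lr$chisq, p = lr$p, hr = lr$hr)
  })
  scan <- do.call(rbind, rows)
  assert_that(!is.null(scan) && nrow(scan) > 0,
              "no admissible cutoff keeps both arms populated")
  best <- which.min(scan$p)
  structure(list(scan = scan, best_cutoff = scan$cutoff[best],
                 best_p = scan$p[best], best_hr = scan$hr[best],
                 multiplicity_biased = TRUE),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf(paste0("cutoff_scan: %d candidates; best cutoff = %.4g ",
                     "(p = %.3g, HR low/high = %.3f)\n"),
              nrow(x$scan), x$best_cutoff, x$best_p, x$best_hr))
  cat("note: minimal p over the grid is multiplicity-biased\n")
  invisible(x)
}
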
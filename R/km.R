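# Kaplan-Meier and log-rank machinery, implemented from first principles.
# At tied times, events are processed before censorings (standard KM
# convention): a subject censored at t is still at risk for an event at t.

#' Kaplan-Meier product-limit estimate
#'
#' @param time_months Positive follow-up times.
#' @param event 0/1 (or logical) event indicators; 0 = censored.
#' @return A `km_curve` data.frame with one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `survival` (the product-limit estimate
#'   just after that time). If no events are observed the curve is
#'   identically 1 (zero rows) and the `no_events` attribute is `TRUE`.
#' @export
km_estimate <- function(time_months, event) {
  event <- as.integer(event)
  stopifnot(length(time_months) == length(event), length(event) >= 1L,
            all(time_months > 0), all(event %in% c(0L, 1L)))
  ut <- sort(unique(time_months[event == 1L]))
  if (!length(ut)) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0))
    class(out) <- c("km_curve", "data.frame")
    attr(out, "no_events") <- TRUE
    return(out)
  }
  n_risk <- vapply(ut, function(t) sum(time_months >= t), integer(1L))
  n_event <- vapply(ut, function(t) sum(time_months == t & event == 1L), integer(1L))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event, survival = surv)
  class(out) <- c("km_curve", "data.frame")
  attr(out, "no_events") <- FALSE
  out
}

# Core O/E/V computation shared by logrank_test and the cut-point scan.
# `high` is logical: TRUE = high group (group whose excess hazard drives
# HR > 1). Returns observed/expected events for the high group, the
# hypergeometric variance, and per-group totals.
logrank_core <- function(time, event, high) {
  n <- length(time)
  ut <- sort(unique(time[event == 1L]))
  if (!length(ut)) {
    return(list(O_high = 0, E_high = 0, O_low = 0, E_low = 0, V = 0,
                total_events = 0L))
  }
  idx <- match(time, ut)                      # NA for times not at an event time
  # at-risk counts: subjects with time >= ut[j]
  brk <- findInterval(ut, sort(time), left.open = TRUE)  # strictly below ut[j]
  n_risk <- n - brk
  time_high <- sort(time[high])
  n_risk_high <- sum(high) - findInterval(ut, time_high, left.open = TRUE)
  ev <- event == 1L & !is.na(idx)
  d <- tabulate(idx[ev], nbins = length(ut))
  d_high <- tabulate(idx[ev & high], nbins = length(ut))
  E_high_t <- d * n_risk_high / n_risk
  keep <- n_risk > 1L
  V_t <- numeric(length(ut))
  V_t[keep] <- d[keep] * (n_risk_high[keep] / n_risk[keep]) *
    ((n_risk[keep] - n_risk_high[keep]) / n_risk[keep]) *
    (n_risk[keep] - d[keep]) / (n_risk[keep] - 1)
  total <- sum(d)
  O_high <- sum(d_high)
  E_high <- sum(E_high_t)
  list(O_high = O_high, E_high = E_high,
       O_low = total - O_high, E_low = total - E_high,
       V = sum(V_t), total_events = total)
}

# Chi-square statistics and p-value from a logrank_core result.
logrank_stats <- function(core, yates) {
  diff <- core$O_high - core$E_high
  if (core$V <= 0) {
    return(list(chi2 = 0, chi2_yates = 0, p_value = 1, informative = FALSE))
  }
  chi2 <- diff^2 / core$V
  adiff <- max(abs(diff) - 0.5, 0)
  chi2_yates <- adiff^2 / core$V
  stat <- if (yates) chi2_yates else chi2
  list(chi2 = chi2, chi2_yates = chi2_yates,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       informative = TRUE)
}

#' Pike (O/E) hazard ratio with 95% confidence interval
#'
#' Estimates the hazard ratio of the high group relative to the low group
#' from the observed and expected event counts of a log-rank test:
#' `HR = (O_high/E_high) / (O_low/E_low)`, with
#' `se(ln HR) = sqrt(1/E_high + 1/E_low)`. The estimate and its 95%
#' confidence interval are reported on the log2 scale (divide the natural-log
#' quantities by `ln 2`); the standard error itself is returned on the
#' natural-log scale.
#'
#' If one group has zero observed events the point estimate is `-Inf` or
#' `Inf`; the finite confidence bound is then computed with the zero count
#' replaced by 0.5 (a continuity adjustment) and the result is flagged
#' `degenerate`.
#'
#' @param o_high,e_high Observed and expected events, high group.
#' @param o_low,e_low Observed and expected events, low group.
#' @return List with `log2_hr`, `se_log_hr` (natural-log scale), `ci95_log2`
#'   (length-2 numeric) and `degenerate` flag.
#' @export
hazard_ratio <- function(o_high, e_high, o_low, e_low) {
  stopifnot(e_high > 0, e_low > 0)
  se <- sqrt(1 / e_high + 1 / e_low)
  degenerate <- (o_high == 0) || (o_low == 0)
  oh <- max(o_high, 0.5); ol <- max(o_low, 0.5)
  ln_hr_adj <- log((oh / e_high) / (ol / e_low))
  if (degenerate) {
    log2_hr <- if (o_high == 0) -Inf else Inf
    ci <- if (o_high == 0) {
      c(-Inf, (ln_hr_adj + 1.96 * se) / log(2))
    } else {
      c((ln_hr_adj - 1.96 * se) / log(2), Inf)
    }
  } else {
    ln_hr <- log((o_high / e_high) / (o_low / e_low))
    log2_hr <- ln_hr / log(2)
    ci <- c(ln_hr - 1.96 * se, ln_hr + 1.96 * se) / log(2)
  }
  list(log2_hr = log2_hr, se_log_hr = se, ci95_log2 = ci, degenerate = degenerate)
}

#' Two-group log-rank test with optional Yates continuity correction
#'
#' At each distinct event time the expected events per group follow the
#' hypergeometric model `E_k = d * n_k / n`, with variance
#' `V = sum d * (n1/n) * (n2/n) * (n - d) / (n - 1)`. The uncorrected
#' statistic is `(O1 - E1)^2 / V`; Yates' correction replaces `|O1 - E1|`
#' with `max(|O1 - E1| - 0.5, 0)` before squaring. When `yates = TRUE`
#' (the default, matching the screening procedure) the reported p-value
#' comes from the corrected statistic on a 1-df chi-square.
#'
#' @param time_months Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group Group labels: logical, 0/1 numeric, or a 2-level factor.
#'   `TRUE` / `1` / the second level is the "high" group whose relative
#'   hazard is reported.
#' @param yates Apply Yates' continuity correction to the reported p-value.
#' @return A `logrank_result` list: `O`, `E` (named low/high), `V`, `chi2`,
#'   `chi2_yates`, `p_value`, `log2_hr`, `se_log_hr`, `ci95_log2`,
#'   `n_per_group`, `degenerate`.
#' @export
logrank_test <- function(time_months, event, group, yates = TRUE) {
  event <- as.integer(event)
  if (is.factor(group)) {
    stopifnot(nlevels(group) == 2L)
    high <- group == levels(group)[2L]
  } else {
    high <- as.logical(group)
  }
  stopifnot(length(time_months) == length(event),
            length(event) == length(high), !anyNA(high),
            all(event %in% c(0L, 1L)))
  if (!any(high) || all(high)) stop("both groups must be non-empty", call. = FALSE)
  if (!any(event == 1L)) stop("at least one event is required", call. = FALSE)

  core <- logrank_core(time_months, event, high)
  st <- logrank_stats(core, yates = yates)
  if (!st$informative) {
    warning("log-rank variance is zero (no informative event times); p = 1", call. = FALSE)
  }
  hr <- if (core$E_high > 0 && core$E_low > 0) {
    hazard_ratio(core$O_high, core$E_high, core$O_low, core$E_low)
  } else {
    list(log2_hr = NA_real_, se_log_hr = NA_real_,
         ci95_log2 = c(NA_real_, NA_real_), degenerate = TRUE)
  }
  structure(list(O = c(low = core$O_low, high = core$O_high),
                 E = c(low = core$E_low, high = core$E_high),
                 V = core$V,
                 chi2 = st$chi2, chi2_yates = st$chi2_yates,
                 p_value = st$p_value,
                 log2_hr = hr$log2_hr, se_log_hr = hr$se_log_hr,
                 ci95_log2 = hr$ci95_log2,
                 n_per_group = c(n_low = sum(!high), n_high = sum(high)),
                 yates = yates,
                 degenerate = hr$degenerate || !st$informative),
            class = "logrank_result")
}

#' @exportS3Method base::print
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test (%s): chi2 = %.4f, chi2_yates = %.4f, p = %.4g\n",
              if (x$yates) "Yates-corrected p" else "uncorrected p",
              x$chi2, x$chi2_yates, x$p_value))
  cat(sprintf("  O (low/high) = %.0f/%.0f, E = %.3f/%.3f, V = %.3f\n",
              x$O["low"], x$O["high"], x$E["low"], x$E["high"], x$V))
  cat(sprintf("  log2 HR = %.3f [%.3f, %.3f], n = %d/%d\n",
              x$log2_hr, x$ci95_log2[1], x$ci95_log2[2],
              x$n_per_group["n_low"], x$n_per_group["n_high"]))
  invisible(x)
}
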
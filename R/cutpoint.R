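# Optimal cut-point screening: for each feature, every admissible low/high
# dichotomisation between the 10-90 and 90-10 percent splits is tested with
# a Yates-corrected log-rank test and the minimum-p split is reported.

#' Significance thresholds for the volcano-style call
#'
#' @param p_cutoff Raw p-value cut-off (strict `<`); default 0.05.
#' @param log2fc_cutoff Minimum `|log2 HR|`; 0.5 is the conventional gene
#'   threshold, 1.0 the protein threshold.
#' @return A `significance_thresholds` list.
#' @export
significance_thresholds <- function(p_cutoff = 0.05, log2fc_cutoff = 0.5) {
  stopifnot(p_cutoff > 0, log2fc_cutoff > 0)
  structure(list(p_cutoff = p_cutoff, log2fc_cutoff = log2fc_cutoff),
            class = "significance_thresholds")
}

#' Default thresholds by datatype
#' @param datatype `"mRNA"` (log2 HR cut-off 0.5) or `"protein"` (1.0).
#' @return A [significance_thresholds()] object.
#' @export
default_thresholds <- function(datatype = c("mRNA", "protein")) {
  datatype <- match.arg(datatype)
  significance_thresholds(0.05, if (datatype == "protein") 1.0 else 0.5)
}

#' Scan dichotomisation cut-points for one feature
#'
#' Patients are sorted by feature value; every split between distinct
#' adjacent values whose low-group fraction lies in `[min_frac, max_frac]`
#' is tested with a Yates-corrected log-rank test (high group = values above
#' the cut). The split minimising p is returned; ties in p are broken toward
#' the most balanced split, then toward the lower cut, deterministically.
#'
#' @param values Named numeric vector (names = sample ids) or unnamed vector
#'   aligned positionally with `survival`; `NA` values are dropped.
#' @param survival Clinical data.frame (`sample_id`, `time_months`, `event`).
#' @param min_frac,max_frac Admissible range for the low-group fraction.
#' @param yates Use Yates' correction for the scanned p-values (default).
#' @return A `scan_result` list: `n_used`, `best_cut_value`, `frac_low`,
#'   `n_low`, `n_high`, `p_min`, `logrank_at_best`, `p_profile` (data.frame
#'   of fraction_low, p), `degenerate` flag and `reason`.
#' @export
scan_cutpoints <- function(values, survival, min_frac = 0.10, max_frac = 0.90,
                           yates = TRUE) {
  stopifnot(min_frac > 0, max_frac < 1, min_frac < max_frac)
  if (!is.null(names(values))) {
    shared <- intersect(names(values), survival$sample_id)
    values <- values[shared]
    survival <- survival[match(shared, survival$sample_id), , drop = FALSE]
  } else {
    stopifnot(length(values) == nrow(survival))
  }
  keep <- !is.na(values)
  values <- values[keep]
  time <- survival$time_months[keep]
  event <- as.integer(survival$event[keep])
  n <- length(values)
  if (n < 10L) stop(sprintf("only %d patients with data; >= 10 required", n), call. = FALSE)

  ord <- order(values)
  v <- values[ord]; time <- time[ord]; event <- event[ord]

  ks <- seq_len(n - 1L)
  frac <- ks / n
  admissible <- frac >= min_frac & frac <= max_frac & v[ks] < v[ks + 1L]
  ks <- ks[admissible]
  degenerate_result <- function(reason) {
    structure(list(n_used = n, best_cut_value = NA_real_, frac_low = NA_real_,
                   n_low = NA_integer_, n_high = NA_integer_,
                   p_min = 1, logrank_at_best = NULL,
                   p_profile = data.frame(fraction_low = numeric(0), p = numeric(0)),
                   degenerate = TRUE, reason = reason),
              class = "scan_result")
  }
  if (!length(ks)) {
    return(degenerate_result(if (length(unique(v)) == 1L) "constant feature"
                             else "no admissible split"))
  }
  if (!any(event == 1L)) return(degenerate_result("no events"))
  if (length(ks) < ceiling(min_frac * n)) {
    warning(sprintf("only %d admissible split(s) for a feature with n = %d", length(ks), n),
            call. = FALSE)
  }

  p <- numeric(length(ks))
  for (i in seq_along(ks)) {
    high <- seq_len(n) > ks[i]
    core <- logrank_core(time, event, high)
    p[i] <- logrank_stats(core, yates = yates)$p_value
  }
  # minimum p; ties -> most balanced split, then lower cut
  best <- which(p == min(p))
  if (length(best) > 1L) {
    bal <- abs(ks[best] / n - 0.5)
    best <- best[bal == min(bal)]
    best <- best[1L]
  }
  k <- ks[best]
  lr <- logrank_test(time, event, seq_len(n) > k, yates = yates)
  structure(list(n_used = n,
                 best_cut_value = (v[k] + v[k + 1L]) / 2,
                 frac_low = k / n,
                 n_low = k, n_high = n - k,
                 p_min = p[best],
                 logrank_at_best = lr,
                 p_profile = data.frame(fraction_low = ks / n, p = p),
                 degenerate = FALSE, reason = NA_character_),
            class = "scan_result")
}

#' Screen every feature of a matrix against event-free survival
#'
#' Runs [scan_cutpoints()] on each feature, using for each feature the
#' patients for whom that feature is non-missing (per-feature n, not
#' listwise deletion), then computes Storey q-values across the screened set
#' and calls significance with the raw-p / |log2 HR| thresholds. Degenerate
#' features (constant values, too few patients, no events) yield flagged
#' rows with p = 1 rather than errors.
#'
#' @param matrix Numeric matrix, features x samples (a `datatype` attribute,
#'   if present, picks the default thresholds).
#' @param survival Clinical data.frame.
#' @param thresholds A [significance_thresholds()]; defaults to the
#'   matrix's datatype convention.
#' @param min_frac,max_frac Scan window, passed to [scan_cutpoints()].
#' @return A `screen_table` data.frame with one row per feature: `feature`,
#'   `n`, `cut_value`, `frac_low`, `n_low`, `n_high`, `log2HR`, `se`,
#'   `ci_low`, `ci_high`, `p`, `q`, `neg_log10_p`, `significant`,
#'   `direction`, `flag`.
#' @export
screen_features <- function(matrix, survival, thresholds = NULL,
                            min_frac = 0.10, max_frac = 0.90) {
  if (is.null(thresholds)) {
    thresholds <- default_thresholds(attr(matrix, "datatype") %||% "mRNA")
  }
  al <- align_samples(matrix, survival, quiet = TRUE)
  if (!ncol(al$matrix)) stop("no shared samples", call. = FALSE)
  feats <- rownames(al$matrix)
  rows <- lapply(feats, function(f) {
    values <- al$matrix[f, ]
    sc <- tryCatch(scan_cutpoints(values, al$clinical, min_frac, max_frac),
                   error = function(e) {
                     structure(list(n_used = sum(!is.na(values)),
                                    best_cut_value = NA_real_, frac_low = NA_real_,
                                    n_low = NA_integer_, n_high = NA_integer_,
                                    p_min = 1, logrank_at_best = NULL,
                                    degenerate = TRUE, reason = conditionMessage(e)),
                               class = "scan_result")
                   })
    lr <- sc$logrank_at_best
    data.frame(feature = f,
               n = sc$n_used,
               cut_value = sc$best_cut_value,
               frac_low = sc$frac_low,
               n_low = if (is.null(lr)) NA_integer_ else sc$n_low,
               n_high = if (is.null(lr)) NA_integer_ else sc$n_high,
               log2HR = if (is.null(lr)) NA_real_ else lr$log2_hr,
               se = if (is.null(lr)) NA_real_ else lr$se_log_hr,
               ci_low = if (is.null(lr)) NA_real_ else lr$ci95_log2[1L],
               ci_high = if (is.null(lr)) NA_real_ else lr$ci95_log2[2L],
               p = sc$p_min,
               flag = if (sc$degenerate) sc$reason %||% "degenerate" else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- storey_qvalues(out$p)
  out$neg_log10_p <- -log10(out$p)
  sig <- vapply(seq_len(nrow(out)), function(i) {
    call_significant(out[i, , drop = FALSE], thresholds)
  }, logical(1L))
  out$significant <- sig & is.na(out$flag)
  out$direction <- ifelse(is.na(out$log2HR), NA_character_,
                          ifelse(out$log2HR > 0, "increased_risk", "decreased_risk"))
  attr(out, "thresholds") <- thresholds
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Volcano-style significance call for one screened feature
#'
#' A feature is significant when its raw minimum scan p-value is strictly
#' below `p_cutoff` and `|log2 HR| >= log2fc_cutoff`. The call uses raw p,
#' not q: the q-value is reported alongside for multiple-testing context.
#'
#' @param row One screen row (list or one-row data.frame with `p` and
#'   `log2HR`).
#' @param thresholds A [significance_thresholds()].
#' @return Logical flag.
#' @export
call_significant <- function(row, thresholds) {
  stopifnot(inherits(thresholds, "significance_thresholds"))
  p <- row$p %||% row$p_value
  l2 <- row$log2HR %||% row$log2_hr
  if (is.na(p) || is.na(l2)) return(FALSE)
  (p < thresholds$p_cutoff) && (abs(l2) >= thresholds$log2fc_cutoff)
}

#' Storey positive-FDR q-values
#'
#' Estimates the null proportion pi0 on the grid lambda = 0.05, 0.10, ...,
#' 0.90 via `pi0(lambda) = #(p > lambda) / (m * (1 - lambda))`, smooths the
#' profile with a cubic polynomial evaluated at the largest lambda, clamps
#' pi0 into (0, 1], and converts sorted p-values with
#' `q_(i) = pi0 * m * p_(i) / i` followed by the step-up monotonicity
#' enforcement. Output is returned in input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
storey_qvalues <- function(p_values) {
  p <- as.numeric(p_values)
  m <- length(p)
  if (!m) stop("empty p-value vector", call. = FALSE)
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  lambda <- seq(0.05, 0.90, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
  pi0_hat <- if (m < 2L || length(unique(pi0_l)) == 1L) {
    pi0_l[length(pi0_l)]
  } else {
    fit <- stats::lm(pi0_l ~ stats::poly(lambda, 3))
    as.numeric(stats::predict(fit, newdata = data.frame(lambda = max(lambda))))
  }
  pi0 <- min(max(pi0_hat, .Machine$double.eps), 1)
  ord <- order(p)
  q_sorted <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
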
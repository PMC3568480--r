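#' @name measures
#' @title Disproportionality measures on a 2x2 contingency table
#'
#' @description Given report counts `a` (drug & symptom), `b` (drug only),
#' `c` (symptom only) and `d` (neither), the package computes the standard
#' pharmacovigilance measures:
#'
#' * **PRR** — proportional reporting ratio `(a/(a+b)) / (c/(c+d))`;
#' * **ROR** — reporting odds ratio `ad / bc`;
#' * **IC**  — information component `log2( a N / ((a+b)(a+c)) )`;
#' * **Yates chi-squared** — `N (|ad-bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`,
#'   with the continuity term clamped at `|ad-bc|` so the statistic is never
#'   driven negative on near-independence tables;
#' * **Leverage** — `a/N - ((a+b)/N)((a+c)/N)`, positive under positive
#'   association, zero under independence.
#'
#' Signal criteria follow the conventional cutoffs: for PRR and ROR the
#' one-sided band `value - 1.96*delta > 1`, where `delta` is the standard
#' error of the log measure (a log-scale variant
#' `exp(log(value) - 1.96*delta) > 1` is available via `ci_scale = "log"`);
#' for IC a plain threshold (default 0); for the MHRA composite the
#' conjunction `PRR >= 2`, `a >= 3` and Yates chi-squared `>= 4`.
#'
#' @section Zero-cell handling:
#' PRR is undefined when no comparator report carries the symptom (`c = 0`).
#' The default `zero_policy = "background"` substitutes the background rate
#' `0.5/(c+d+0.5)` — a half-count continuity rule applied only where a term
#' is undefined; the same half-count replaces individually undefined
#' reciprocal terms in `delta`. Alternatives: `"haldane"` (add 0.5 to all
#' four cells) and `"strict"` (return an infinite, flagged value). ROR
#' always uses the Haldane–Anscombe +0.5 correction when any cell is zero.
#'
#' @param t A [contingency_table()].
#' @param zero_policy One of `"background"`, `"haldane"`, `"strict"`.
#' @param ci_scale `"natural"` (default) or `"log"`; see Description.
#' @param threshold Signal threshold for the IC value.
#' @return A `measure_result` object with fields `name`, `value`,
#'   `lower_bound`, `is_signal`, `zero_corrected`, `degenerate`.
NULL

MEASURE_NAMES <- c("PRR", "ROR", "IC", "CHI2_YATES", "LEVERAGE", "MHRA")

default_thresholds <- function() {
  list(min_count = 3, prr = 2, chi2 = 4, ic = 0)
}

# Vectorized measure engine used by the scalar wrappers and the miners.
# Returns a tibble with value, lower_bound, is_signal, zero_corrected,
# degenerate.
measure_vec <- function(a, b, c, d, measure,
                        zero_policy = c("background", "haldane", "strict"),
                        ci_scale = c("natural", "log"),
                        thresholds = list()) {
  zero_policy <- match.arg(zero_policy)
  ci_scale <- match.arg(ci_scale)
  thr <- modifyList(default_thresholds(), thresholds)
  measure <- toupper(measure)
  n <- a + b + c + d
  half <- function(x) ifelse(x == 0, 2, 1 / x)  # 1/x with half-count at x=0

  ci_signal <- function(value, se) {
    lower <- if (ci_scale == "natural") value - 1.96 * se else
      value * exp(-1.96 * se)
    list(lower = lower, signal = !is.na(lower) & lower > 1)
  }

  if (measure == "PRR" || measure == "MHRA") {
    if (any(a + b == 0)) {
      abort("PRR undefined: no exposed reports (a + b = 0)",
            class = "adrmine_measure_error")
    }
    if (zero_policy == "haldane") {
      zc <- (a == 0 | b == 0 | c == 0 | d == 0)
      a2 <- ifelse(zc, a + 0.5, a); b2 <- ifelse(zc, b + 0.5, b)
      c2 <- ifelse(zc, c + 0.5, c); d2 <- ifelse(zc, d + 0.5, d)
      value <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
      se <- sqrt(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2))
      degen <- rep(FALSE, length(a))
    } else {
      pe <- a / (a + b)
      pb <- ifelse(c == 0 & zero_policy == "background",
                   0.5 / (c + d + 0.5), c / (c + d))
      value <- pe / pb
      zc <- c == 0 & zero_policy == "background"
      degen <- (c == 0 & zero_policy == "strict") | a == 0
      # log-SE with half-count substitution only for undefined terms
      se <- sqrt(pmax(half(a) - half(a + b) + half(c) - half(c + d), 0))
      se[zero_policy == "strict" & c == 0] <- NA_real_
    }
    value[a == 0] <- 0
    cs <- ci_signal(value, se)
    prr_tbl <- tibble(value = value, lower_bound = cs$lower,
                      is_signal = cs$signal & a > 0 & is.finite(value),
                      zero_corrected = zc, degenerate = degen)
    if (measure == "PRR") return(prr_tbl)
    # MHRA: PRR >= 2 AND a >= 3 AND Yates chi2 >= 4; value reported is PRR
    chi <- measure_vec(a, b, c, d, "CHI2_YATES")
    prr_tbl$is_signal <- is.finite(prr_tbl$value) &
      prr_tbl$value >= thr$prr & a >= 3 & chi$value >= thr$chi2
    prr_tbl$lower_bound <- NA_real_
    return(prr_tbl)
  }

  if (measure == "ROR") {
    zc <- (a == 0 | b == 0 | c == 0 | d == 0)
    a2 <- ifelse(zc, a + 0.5, a); b2 <- ifelse(zc, b + 0.5, b)
    c2 <- ifelse(zc, c + 0.5, c); d2 <- ifelse(zc, d + 0.5, d)
    value <- (a2 * d2) / (b2 * c2)
    se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
    cs <- ci_signal(value, se)
    return(tibble(value = value, lower_bound = cs$lower,
                  is_signal = cs$signal, zero_corrected = zc,
                  degenerate = FALSE))
  }

  if (measure == "IC") {
    value <- ifelse(a > 0, log2(a * n / ((a + b) * (a + c))), NA_real_)
    return(tibble(value = value, lower_bound = NA_real_,
                  is_signal = !is.na(value) & value > thr$ic,
                  zero_corrected = FALSE, degenerate = a == 0))
  }

  if (measure == "CHI2_YATES") {
    degen <- (a + b == 0) | (c + d == 0) | (a + c == 0) | (b + d == 0)
    h <- abs(a * d - b * c)
    corr <- pmin(n / 2, h)
    denom <- (a + b) * (c + d) * (a + c) * (b + d)
    value <- ifelse(degen, 0, n * (h - corr)^2 / denom)
    return(tibble(value = value, lower_bound = NA_real_,
                  is_signal = value >= thr$chi2, zero_corrected = FALSE,
                  degenerate = degen))
  }

  if (measure == "LEVERAGE") {
    value <- a / n - ((a + b) / n) * ((a + c) / n)
    return(tibble(value = value, lower_bound = NA_real_,
                  is_signal = value > 0, zero_corrected = FALSE,
                  degenerate = FALSE))
  }

  abort(paste0("unknown measure: ", measure), class = "adrmine_query_error")
}

new_measure_result <- function(name, row, t, zero_policy = NA, ci_scale = NA) {
  structure(list(name = name, value = row$value,
                 lower_bound = row$lower_bound, is_signal = row$is_signal,
                 zero_corrected = row$zero_corrected,
                 degenerate = row$degenerate, table = t,
                 zero_policy = zero_policy, ci_scale = ci_scale),
            class = "measure_result")
}

#' @export
print.measure_result <- function(x, ...) {
  cat(sprintf("<measure_result> %s = %.4g%s%s\n", x$name, x$value,
              if (!is.na(x$lower_bound))
                sprintf(" (lower bound %.4g)", x$lower_bound) else "",
              if (isTRUE(x$is_signal)) "  [signal]" else ""))
  invisible(x)
}

#' @export
tidy.measure_result <- function(x, ...) {
  tibble(measure = x$name, value = x$value, lower_bound = x$lower_bound,
         is_signal = x$is_signal, zero_corrected = x$zero_corrected,
         degenerate = x$degenerate)
}

#' Proportional reporting ratio
#' @rdname measures
#' @export
prr <- function(t, zero_policy = c("background", "haldane", "strict"),
                ci_scale = c("natural", "log")) {
  zero_policy <- match.arg(zero_policy); ci_scale <- match.arg(ci_scale)
  row <- measure_vec(t$a, t$b, t$c, t$d, "PRR", zero_policy, ci_scale)
  new_measure_result("PRR", row, t, zero_policy, ci_scale)
}

#' Reporting odds ratio
#' @rdname measures
#' @export
ror <- function(t, ci_scale = c("natural", "log")) {
  ci_scale <- match.arg(ci_scale)
  row <- measure_vec(t$a, t$b, t$c, t$d, "ROR", ci_scale = ci_scale)
  new_measure_result("ROR", row, t, "haldane", ci_scale)
}

#' Information component
#' @rdname measures
#' @export
ic <- function(t, threshold = 0) {
  row <- measure_vec(t$a, t$b, t$c, t$d, "IC", thresholds = list(ic = threshold))
  new_measure_result("IC", row, t)
}

#' Yates continuity-corrected chi-squared statistic
#' @rdname measures
#' @export
chi2_yates <- function(t) {
  row <- measure_vec(t$a, t$b, t$c, t$d, "CHI2_YATES")
  new_measure_result("CHI2_YATES", row, t)
}

#' Leverage (observed minus expected joint probability)
#' @rdname measures
#' @export
leverage <- function(t) {
  row <- measure_vec(t$a, t$b, t$c, t$d, "LEVERAGE")
  new_measure_result("LEVERAGE", row, t)
}

#' Evaluate a signal criterion on a contingency table
#'
#' Applies the selected measure's signal criterion plus the common minimum
#' case-count gate `a >= min_count` (default 3): PRR/ROR use their
#' confidence-band criterion, MHRA the conjunction `PRR >= 2, a >= 3,
#' chi-squared >= 4`, IC and leverage a value threshold.
#'
#' @param t A [contingency_table()].
#' @param measure One of `"PRR"`, `"ROR"`, `"IC"`, `"MHRA"`, `"CHI2_YATES"`,
#'   `"LEVERAGE"`.
#' @param thresholds Named list overriding `min_count`, `prr`, `chi2`, `ic`.
#' @inheritParams measures
#' @return Logical: does the table qualify as a signal?
#' @export
evaluate_criterion <- function(t, measure, thresholds = list(),
                               zero_policy = "background",
                               ci_scale = "natural") {
  thr <- modifyList(default_thresholds(), thresholds)
  measure <- toupper(measure)
  if (!measure %in% MEASURE_NAMES) {
    abort(paste0("unknown measure: ", measure), class = "adrmine_query_error")
  }
  row <- measure_vec(t$a, t$b, t$c, t$d, measure, zero_policy, ci_scale,
                     thresholds = thr)
  isTRUE(row$is_signal && t$a >= thr$min_count)
}
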
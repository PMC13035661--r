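#' ROC curve and AUC for a prognostic marker
#'
#' Builds the ROC curve over all observed thresholds with the rule
#' "positive if value >= threshold" (higher marker values indicate events;
#' set `direction = "less"` to flip). The AUC is the trapezoid area, which
#' equals the midrank Mann-Whitney statistic with ties counted 0.5.
#'
#' @param values Numeric marker values.
#' @param outcomes Binary outcomes (0/1 or logical), same length. For
#'   data-frame-first evaluation over several markers use
#'   [evaluate_markers()]; this low-level interface takes plain vectors,
#'   like the stats-package tests.
#' @param direction `"greater"` (default): larger values indicate events.
#' @param ci Also compute the DeLong confidence interval (see
#'   [auc_confidence_interval()]).
#' @param level Confidence level when `ci = TRUE`.
#' @return Object of class `roc_result`: thresholds, sensitivity,
#'   specificity per threshold, `auc`, counts, and (with `ci = TRUE`)
#'   `auc_ci_low` / `auc_ci_high`. [tidy()] returns the curve, [glance()]
#'   the scalar summary, [autoplot()] draws the curve.
#' @export
#' @examples
#' r <- roc_auc(c(1, 3, 0, 2), c(1, 1, 0, 0))
#' glance(r)
roc_auc <- function(values, outcomes, direction = c("greater", "less"),
                    ci = FALSE, level = 0.95) {
  direction <- match.arg(direction)
  keep <- is.finite(values) & !is.na(outcomes)
  values <- values[keep]
  y <- as.integer(outcomes[keep] != 0)
  if (length(unique(y)) < 2) {
    abort("both outcome classes must be present")
  }
  x <- if (direction == "less") -values else values
  n1 <- sum(y == 1); n0 <- sum(y == 0)

  thr <- sort(unique(x))
  # positive if x >= t
  sens <- vapply(thr, function(t) sum(x >= t & y == 1) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(x < t & y == 0) / n0, numeric(1))

  r <- rank(x, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  out <- structure(
    list(thresholds = if (direction == "less") -thr else thr,
         sensitivity = sens, specificity = spec,
         auc = auc, n_pos = n1, n_neg = n0,
         direction = direction, values = values, outcomes = y),
    class = "roc_result"
  )
  if (ci) {
    interval <- auc_confidence_interval(values, outcomes, level = level,
                                        direction = direction)
    out$auc_ci_low <- interval[["low"]]
    out$auc_ci_high <- interval[["high"]]
    out$ci_level <- level
  }
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC ", round(x$auc, 3), sep = "")
  if (!is.null(x$auc_ci_low)) {
    cat(" (", 100 * x$ci_level, "% CI ", round(x$auc_ci_low, 3), "-",
        round(x$auc_ci_high, 3), ")", sep = "")
  }
  cat("; ", x$n_pos, " events / ", x$n_neg, " non-events\n", sep = "")
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(
    threshold = x$thresholds,
    sensitivity = x$sensitivity,
    specificity = x$specificity
  )
}

#' @rdname roc_auc
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    auc_ci_low = x$auc_ci_low %||% NA_real_,
    auc_ci_high = x$auc_ci_high %||% NA_real_,
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}

#' @rdname roc_auc
#' @param object A `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tidy(object)
  df <- df[order(1 - df$specificity, df$sensitivity), ]
  df <- rbind(data.frame(threshold = NA, sensitivity = 0, specificity = 1),
              df,
              data.frame(threshold = NA, sensitivity = 1, specificity = 0))
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC = %.2f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DeLong confidence interval for the AUC
#'
#' Variance from the DeLong placement decomposition; Wald interval on the
#' AUC scale, clipped to `[0, 1]`. When all marker values are tied the
#' variance degenerates and the interval collapses to the AUC with a
#' warning. A seeded percentile bootstrap is available as an alternative.
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` (default, deterministic) or `"bootstrap"`.
#' @param boot_n Bootstrap replicates when `method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return Named numeric vector `low`, `high`.
#' @export
auc_confidence_interval <- function(values, outcomes, level = 0.95,
                                    direction = c("greater", "less"),
                                    method = c("delong", "bootstrap"),
                                    boot_n = 2000, seed = 1L) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  y <- as.integer(outcomes != 0)
  x <- if (direction == "less") -values else values
  xs <- x[y == 1]; xn <- x[y == 0]
  n1 <- length(xs); n0 <- length(xn)
  if (n1 < 2 || n0 < 2) abort("need at least 2 cases in each class")

  if (method == "bootstrap") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    aucs <- replicate(boot_n, {
      bs <- sample(xs, n1, replace = TRUE)
      bn <- sample(xn, n0, replace = TRUE)
      pair_auc(bs, bn)
    })
    q <- quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    return(c(low = max(0, q[1]), high = min(1, q[2])))
  }

  auc <- pair_auc(xs, xn)
  # placements
  v10 <- vapply(xs, function(s) mean((s > xn) + 0.5 * (s == xn)), numeric(1))
  v01 <- vapply(xn, function(n) mean((xs > n) + 0.5 * (xs == n)), numeric(1))
  se2 <- var(v10) / n1 + var(v01) / n0
  if (se2 <= 0 || !is.finite(se2)) {
    warn("degenerate DeLong variance (all values tied); interval collapses to the AUC")
    return(c(low = auc, high = auc))
  }
  z <- qnorm(1 - (1 - level) / 2)
  c(low = max(0, auc - z * sqrt(se2)), high = min(1, auc + z * sqrt(se2)))
}

pair_auc <- function(xs, xn) {
  r <- rank(c(xs, xn), ties.method = "average")
  n1 <- length(xs)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(xn))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Youden-index operating point
#'
#' The threshold maximising `J = sensitivity + specificity - 1`, with ties
#' broken toward the lowest threshold (which maximises sensitivity at equal
#' J, the screening-oriented choice). PPV and NPV come from the 2x2 table
#' at that threshold on the same cohort.
#'
#' @param roc A `roc_result` from [roc_auc()].
#' @return One-row tibble: `threshold`, `j`, `se`, `sp`, `ppv`, `npv`.
#' @export
youden_operating_point <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  # thresholds are stored in marker units; "lowest threshold" means the most
  # sensitive operating point, i.e. the smallest cutoff in scan order
  pick <- best[which.min(roc$thresholds[best] * ifelse(roc$direction == "less", -1, 1))]
  thr <- roc$thresholds[pick]
  x <- roc$values
  y <- roc$outcomes
  positive <- if (roc$direction == "less") x <= thr else x >= thr
  tp <- sum(positive & y == 1); fp <- sum(positive & y == 0)
  fn <- sum(!positive & y == 1); tn <- sum(!positive & y == 0)
  tibble::tibble(
    threshold = thr,
    j = j[pick],
    se = tp / (tp + fn),
    sp = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the two empirical cumulative
#' distribution functions, evaluated over the pooled sample points. Used to
#' quantify the distance between the event and event-free marker
#' distributions.
#'
#' @param values_event,values_nonevent Non-empty numeric samples.
#' @return KS distance in `[0, 1]`.
#' @export
ks_statistic <- function(values_event, values_nonevent) {
  a <- values_event[is.finite(values_event)]
  b <- values_nonevent[is.finite(values_nonevent)]
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  pooled <- sort(unique(c(a, b)))
  fa <- vapply(pooled, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pooled, function(t) mean(b <= t), numeric(1))
  max(abs(fa - fb))
}

#' Group-difference test with normality-based selection
#'
#' Student's t-test (paired or two-sample) when each sample has `n >= 30`
#' or passes a Shapiro-Wilk normality check (p > 0.05); otherwise the
#' Wilcoxon signed-rank / Mann-Whitney test. The test actually used is
#' returned as metadata.
#'
#' @param a,b Numeric samples (`n >= 2` each; equal length when paired).
#' @param paired Paired test?
#' @param force_nonparametric Always use the Wilcoxon family (the
#'   convention for bounded scores such as Dice coefficients).
#' @return One-row tibble: `statistic`, `p_value`, `method`.
#' @export
group_difference_test <- function(a, b, paired = FALSE,
                                  force_nonparametric = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("need n >= 2 per group")
  if (paired && length(a) != length(b)) abort("paired test needs equal lengths")

  use_t <- !force_nonparametric && is_plausibly_normal(a, b, paired)
  if (use_t) {
    ht <- t.test(a, b, paired = paired)
    method <- if (paired) "paired t" else "two-sample t"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE))
    method <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney"
  }
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # identical constant groups: zero statistic
  tibble::tibble(statistic = unname(ht$statistic), p_value = p, method = method)
}

is_plausibly_normal <- function(a, b, paired) {
  samples <- if (paired) list(a - b) else list(a, b)
  all(vapply(samples, function(s) {
    if (length(s) >= 30) return(TRUE)
    if (length(s) < 3 || sd(s) == 0) return(FALSE)
    shapiro.test(s)$p.value > 0.05
  }, logical(1)))
}

#' Univariate likelihood-ratio test for a marker
#'
#' Compares a univariate logistic regression of the outcome on the marker
#' against the intercept-only model: the statistic is twice the log-
#' likelihood difference, with a chi-square(1) p-value. Perfect separation
#' (unbounded statistic) is detected and reported as an error.
#'
#' @param marker Numeric marker values.
#' @param outcomes Binary outcomes (0/1), same length.
#' @return One-row tibble: `lr_statistic`, `p_value`, `slope`.
#' @export
likelihood_ratio_test <- function(marker, outcomes) {
  y <- as.integer(outcomes != 0)
  if (length(unique(y)) < 2) abort("both outcome classes must be present")
  fit <- suppressWarnings(
    glm(y ~ marker, family = binomial(), control = list(epsilon = 1e-10, maxit = 100))
  )
  mu <- fit$fitted.values
  if (all(abs(y - mu) < 1e-6) || max(abs(coef(fit)), na.rm = TRUE) > 1e3) {
    abort("perfect separation: the likelihood-ratio statistic is unbounded")
  }
  lr <- fit$null.deviance - fit$deviance
  tibble::tibble(
    lr_statistic = lr,
    p_value = pchisq(lr, df = 1, lower.tail = FALSE),
    slope = unname(coef(fit)[2])
  )
}

#' Evaluate prognostic markers against a binary outcome
#'
#' Runs the full per-marker evaluation on a cohort table: ROC AUC with
#' DeLong confidence interval, the Youden-index operating point with
#' sensitivity, specificity, PPV and NPV (labelled `pnv` in the output for
#' consistency with the clinical reporting convention), the two-sample KS
#' distance, the group-difference test, and the univariate likelihood-ratio
#' test.
#'
#' @param data Cohort data frame: one row per patient, marker columns, and
#'   a binary outcome column.
#' @param markers Character vector of marker column names.
#' @param outcome Name of the binary outcome column (default `"outcome"`).
#' @param level Confidence level for the AUC interval.
#' @param direction Passed to [roc_auc()].
#' @return Tibble, one row per marker: `marker`, `n_event`, `n_nonevent`,
#'   `auc`, `auc_ci_low`, `auc_ci_high`, `threshold`, `se`, `sp`, `ppv`,
#'   `pnv`, `ks`, `group_p`, `group_test`, `lr_statistic`, `lr_p`.
#' @export
evaluate_markers <- function(data, markers, outcome = "outcome", level = 0.95,
                             direction = "greater") {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(markers, outcome), names(data))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("outcome has a single class; both events and non-events are needed")
  }
  purrr::map_dfr(markers, function(m) {
    x <- data[[m]]
    keep <- is.finite(x) & !is.na(y)
    x <- x[keep]; yy <- as.integer(y[keep] != 0)
    roc <- roc_auc(x, yy, direction = direction, ci = TRUE, level = level)
    yj <- youden_operating_point(roc)
    ks <- ks_statistic(x[yy == 1], x[yy == 0])
    gt <- group_difference_test(x[yy == 1], x[yy == 0])
    lr <- tryCatch(likelihood_ratio_test(x, yy),
                   error = function(e) tibble::tibble(lr_statistic = Inf,
                                                      p_value = NA_real_,
                                                      slope = NA_real_))
    tibble::tibble(
      marker = m,
      n_event = sum(yy == 1), n_nonevent = sum(yy == 0),
      auc = roc$auc, auc_ci_low = roc$auc_ci_low, auc_ci_high = roc$auc_ci_high,
      threshold = yj$threshold, se = yj$se, sp = yj$sp,
      ppv = yj$ppv, pnv = yj$npv,
      ks = ks,
      group_p = gt$p_value, group_test = gt$method,
      lr_statistic = lr$lr_statistic, lr_p = lr$p_value
    )
  })
}

#' Density plot of a marker by outcome group
#'
#' Mirrors the diagnostic density displays: one density per outcome group
#' with the KS distance in the subtitle.
#'
#' @inheritParams evaluate_markers
#' @param marker Single marker column name.
#' @return A ggplot object.
#' @export
plot_marker_density <- function(data, marker, outcome = "outcome") {
  y <- as.integer(data[[outcome]] != 0)
  x <- data[[marker]]
  ks <- ks_statistic(x[y == 1], x[y == 0])
  df <- tibble::tibble(
    value = x,
    group = factor(ifelse(y == 1, "event", "no event"),
                   levels = c("event", "no event"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(
      x = marker, y = "Density",
      title = paste0("Distribution of ", marker, " by outcome"),
      subtitle = sprintf("KS = %.2f", ks)
    ) +
    ggplot2::theme_minimal()
}
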
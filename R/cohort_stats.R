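#' Two-tailed two-sample t-test
#'
#' Classical two-sample t statistic with a two-sided p value, in the
#' Student (pooled-variance, default) or Welch variant. The t statistic
#' carries the sign of `mean(group_a) - mean(group_b)`. Degenerate
#' (essentially zero) variance raises a classed error rather than
#' returning a silent p value.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2.
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `variant`.
#' @export
two_tailed_t_test <- function(group_a, group_b,
                              variant = c("student", "welch")) {
  variant <- match.arg(variant)
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("Each group needs at least two finite values.",
          class = "ergkit_error_small_group")
  }
  ht <- tryCatch(
    t.test(group_a, group_b, var.equal = (variant == "student"),
           alternative = "two.sided"),
    error = function(e) {
      abort("Degenerate variance: groups are essentially constant.",
            class = "ergkit_error_degenerate_variance", parent = e)
    })
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
       variant = variant)
}

#' Box-and-whisker five-number summary
#'
#' Median and Tukey-hinge quartiles, with whiskers at the data minimum and
#' maximum (no 1.5 IQR fencing: whiskers reach the extremes).
#'
#' @param values Numeric vector with n >= 1 finite values.
#' @return One-row tibble: `min`, `q1`, `median`, `q3`, `max`, `n`.
#' @export
box_whisker_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) {
    abort("`values` must contain at least one finite value.",
          class = "ergkit_error_empty")
  }
  fn <- fivenum(values)
  tibble(min = fn[1], q1 = fn[2], median = fn[3], q3 = fn[4], max = fn[5],
         n = length(values))
}

#' Per-intensity genotype comparisons of a cohort metrics table
#'
#' For each stimulus intensity, compares every non-reference genotype
#' against the reference with a two-tailed t-test on the chosen metric and
#' attaches group means, their difference and ratio, and exclusion counts.
#' For `implicit_time`, only rows flagged valid by the 50-230 ms filter
#' enter the test (listwise exclusion, counts reported); for other metrics
#' all finite values enter.
#'
#' @param metrics Tibble from [bwave_metrics_table()] (or any table with
#'   `genotype`, `attenuation`, the metric column, and — for implicit
#'   time — `valid`).
#' @param metric Name of the metric column (`"amplitude"`,
#'   `"implicit_time"`, or any numeric column such as `"fff"`).
#' @param reference Reference genotype label (default `"WT"`).
#' @param variant t-test variant, `"student"` or `"welch"`.
#' @return A `group_comparison` tibble, one row per
#'   (attenuation, genotype) pair: group sizes, means, difference
#'   (genotype minus reference), ratio, `t`, `df`, `p`, the variant, and
#'   per-cell exclusion counts. Comparisons with fewer than two usable
#'   values per cell yield `NA` statistics.
#' @export
summarize_cohort <- function(metrics, metric = "amplitude",
                             reference = "WT",
                             variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (!metric %in% names(metrics)) {
    abort(paste0("Metric column `", metric, "` not found."),
          class = "ergkit_error_bad_config")
  }
  if (!reference %in% metrics$genotype) {
    abort(paste0("Reference genotype `", reference, "` absent from data."),
          class = "ergkit_error_missing_reference")
  }
  use_valid <- identical(metric, "implicit_time") &&
    "valid" %in% names(metrics)
  usable <- function(d) {
    v <- d[[metric]]
    if (use_valid) v[d$valid & is.finite(v)] else v[is.finite(v)]
  }
  atts <- sort(unique(metrics$attenuation))
  others <- setdiff(unique(metrics$genotype), reference)
  rows <- list()
  for (a in atts) {
    cell_ref <- metrics[metrics$attenuation == a &
                          metrics$genotype == reference, ]
    v_ref <- usable(cell_ref)
    for (g in others) {
      cell <- metrics[metrics$attenuation == a & metrics$genotype == g, ]
      v <- usable(cell)
      ht <- if (length(v) >= 2L && length(v_ref) >= 2L) {
        tryCatch(two_tailed_t_test(v, v_ref, variant),
                 ergkit_error_degenerate_variance = function(e) NULL)
      } else NULL
      rows[[length(rows) + 1L]] <- tibble(
        attenuation = a, reference = reference, genotype = g,
        metric = metric,
        n_ref = length(v_ref), n = length(v),
        excluded_ref = nrow(cell_ref) - length(v_ref),
        excluded = nrow(cell) - length(v),
        mean_ref = if (length(v_ref)) mean(v_ref) else NA_real_,
        mean = if (length(v)) mean(v) else NA_real_,
        mean_diff = if (length(v) && length(v_ref)) {
          mean(v) - mean(v_ref)
        } else NA_real_,
        mean_ratio = if (length(v) && length(v_ref) &&
                         mean(v_ref) != 0) {
          mean(v) / mean(v_ref)
        } else NA_real_,
        t = if (is.null(ht)) NA_real_ else ht$t,
        df = if (is.null(ht)) NA_real_ else ht$df,
        p = if (is.null(ht)) NA_real_ else ht$p,
        variant = variant)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", class(out))
  out
}

#' Per-cell box-and-whisker summaries of a cohort metrics table
#'
#' @inheritParams summarize_cohort
#' @return Tibble with one row per (attenuation, genotype):
#'   min/q1/median/q3/max/n of the usable metric values.
#' @export
cohort_box_summaries <- function(metrics, metric = "amplitude") {
  use_valid <- identical(metric, "implicit_time") &&
    "valid" %in% names(metrics)
  cells <- unique(metrics[, c("attenuation", "genotype")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- metrics[metrics$attenuation == cells$attenuation[i] &
                   metrics$genotype == cells$genotype[i], ]
    v <- d[[metric]]
    v <- if (use_valid) v[d$valid & is.finite(v)] else v[is.finite(v)]
    if (length(v) == 0L) {
      tibble(attenuation = cells$attenuation[i],
             genotype = cells$genotype[i],
             min = NA_real_, q1 = NA_real_, median = NA_real_,
             q3 = NA_real_, max = NA_real_, n = 0L)
    } else {
      cbind(cells[i, ], box_whisker_summary(v)) |> as_tibble()
    }
  })
  do.call(rbind, rows)
}
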
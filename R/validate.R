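#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) of the measurement
#' magnitudes divided by the absolute mean: the run-to-run repeatability
#' statistic used throughout the validation study. Scale-invariant:
#' `cv(k * v) == cv(v)` for `k > 0`.
#'
#' @param values Numeric vector of measurements (µm magnitudes; signs are
#'   dropped), length >= 2.
#' @return The CV as a ratio.
#' @examples
#' cv(c(1900, 2100, 2000, 1900)) # 0.04848
#' @export
cv <- function(values) {
  if (length(values) < 2) stop("cv needs at least two values", call. = FALSE)
  v <- abs(values)
  m <- mean(v)
  if (m == 0) stop("cv undefined: mean is zero", call. = FALSE)
  stats::sd(v) / m
}

#' Pooled ("total") coefficient of variation
#'
#' The unweighted arithmetic mean of per-coordinate (or per-target) CVs, the
#' single repeatability figure reported for a whole table.
#'
#' @param cvs Numeric vector of CVs (length >= 1).
#' @return Mean CV.
#' @export
total_cv <- function(cvs) {
  if (length(cvs) < 1) stop("total_cv needs at least one CV", call. = FALSE)
  mean(cvs)
}

#' Pearson correlation between paired measurement sets
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return Product-moment correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("pearson_r needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Paired two-tailed t-test
#'
#' Student's paired t on matched measurement pairs:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = x - y` and `n - 1` degrees of
#' freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 2; the differences must have
#'   nonzero variance.
#' @return A one-row tibble `t`, `df`, `p` (two-tailed), `n`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("paired_t needs n >= 2", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("degenerate paired test: differences have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    n = length(x),
    mean_diff = mean(d)
  )
}

#' Assemble a validation report
#'
#' Reproduces the validation arithmetic of a repeatability study on
#' position-known phantoms: per-coordinate CVs of the measured positions over
#' repeated runs and their total, the Pearson correlation between the pooled
#' foreknown and measured values, per-target CVs of actual cutting-forward
#' distances and their total, the CV of the expected distances, and the
#' paired comparison of actual vs expected distances.
#'
#' @param positions Data frame, one row per target-axis: columns `target`,
#'   `axis`, `foreknown`, and one `run*` column per measurement round (µm
#'   magnitudes).
#' @param distances Data frame, one row per target-run: columns `target`,
#'   `run`, `actual`, `expected` (µm).
#' @return An object of class `validation_report`; see [tidy()] and
#'   [glance()] methods.
#' @examples
#' rep <- build_report(threetarget_position_runs(), threetarget_distance_runs())
#' glance(rep)
#' @export
build_report <- function(positions, distances) {
  positions <- tibble::as_tibble(positions)
  distances <- tibble::as_tibble(distances)
  run_cols <- grep("^run", names(positions), value = TRUE)
  if (!all(c("target", "axis", "foreknown") %in% names(positions)) ||
    length(run_cols) < 2) {
    stop("positions must have target, axis, foreknown and >= 2 run* columns",
      call. = FALSE
    )
  }
  if (!all(c("target", "run", "actual", "expected") %in% names(distances))) {
    stop("distances must have target, run, actual, expected columns",
      call. = FALSE
    )
  }
  pos_long <- tidyr::pivot_longer(
    positions, dplyr::all_of(run_cols),
    names_to = "run", values_to = "measured"
  )
  position_cv <- pos_long |>
    dplyr::group_by(.data$target, .data$axis) |>
    dplyr::summarise(cv = cv(.data$measured), .groups = "drop")
  # keep the input row order of the table
  position_cv <- dplyr::left_join(
    dplyr::distinct(positions[, c("target", "axis")]), position_cv,
    by = c("target", "axis")
  )
  r <- pearson_r(abs(pos_long$foreknown), abs(pos_long$measured))
  dist_cv <- distances |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(cv_actual = cv(.data$actual), .groups = "drop")
  dist_cv <- dplyr::left_join(
    dplyr::distinct(distances[, "target"]), dist_cv,
    by = "target"
  )
  expected_by_run <- distances |>
    dplyr::distinct(.data$run, .data$expected)
  pt <- paired_t(distances$actual, distances$expected)
  structure(
    list(
      position_cv = position_cv,
      total_position_cv = total_cv(position_cv$cv),
      pearson = tibble::tibble(r = r, n = nrow(pos_long)),
      positions_long = pos_long,
      distance_cv = dist_cv,
      total_actual_cv = total_cv(dist_cv$cv_actual),
      expected_cv = cv(expected_by_run$expected),
      paired = pt,
      n_runs = length(run_cols)
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d targets x %d runs\n",
    length(unique(x$position_cv$target)), x$n_runs
  ))
  cat(sprintf(
    "  total position CV %.5f; pooled Pearson r %.6f (n = %d)\n",
    x$total_position_cv, x$pearson$r, x$pearson$n
  ))
  cat(sprintf(
    "  total actual-distance CV %.4f; expected-distance CV %.4f\n",
    x$total_actual_cv, x$expected_cv
  ))
  cat(sprintf(
    "  paired actual vs expected: t = %.3f, df = %d, p = %.4f\n",
    x$paired$t, x$paired$df, x$paired$p
  ))
  invisible(x)
}

#' Tidy a validation report
#'
#' One row per statistic: per-coordinate position CVs, per-target actual
#' distance CVs, totals, the pooled correlation, and the paired-test summary.
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A tibble `statistic`, `target`, `axis`, `value`.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      statistic = "position_cv",
      target = x$position_cv$target,
      axis = x$position_cv$axis,
      value = x$position_cv$cv
    ),
    tibble::tibble(
      statistic = "total_position_cv", target = NA, axis = NA,
      value = x$total_position_cv
    ),
    tibble::tibble(
      statistic = "pearson_r", target = NA, axis = NA,
      value = x$pearson$r
    ),
    tibble::tibble(
      statistic = "actual_distance_cv",
      target = x$distance_cv$target, axis = NA,
      value = x$distance_cv$cv_actual
    ),
    tibble::tibble(
      statistic = "total_actual_distance_cv", target = NA, axis = NA,
      value = x$total_actual_cv
    ),
    tibble::tibble(
      statistic = "expected_distance_cv", target = NA, axis = NA,
      value = x$expected_cv
    ),
    tibble::tibble(
      statistic = c("paired_t", "paired_df", "paired_p"),
      target = NA, axis = NA,
      value = c(x$paired$t, x$paired$df, x$paired$p)
    )
  )
}

#' Glance at a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A one-row tibble with the headline statistics.
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    total_position_cv = x$total_position_cv,
    pearson_r = x$pearson$r,
    pearson_n = x$pearson$n,
    total_actual_cv = x$total_actual_cv,
    expected_cv = x$expected_cv,
    paired_t = x$paired$t,
    paired_df = x$paired$df,
    paired_p = x$paired$p
  )
}

#' Plot foreknown vs measured positions of a validation report
#'
#' Scatter of the pooled (foreknown, measured) coordinate magnitudes with the
#' identity line, annotated with the Pearson correlation.
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- object$positions_long
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = abs(.data$foreknown), y = abs(.data$measured))
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$target), alpha = 0.8) +
    ggplot2::labs(
      x = "foreknown position (µm)",
      y = "measured position (µm)",
      title = sprintf(
        "Pooled foreknown vs measured (n = %d, Pearson r = %.6f)",
        object$pearson$n, object$pearson$r
      )
    ) +
    ggplot2::theme_minimal()
}
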
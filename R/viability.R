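# Combining the two counters into a viability percentage, truth viability
# from labels, and the evaluation report.

#' Combine total and dead counts into a viability percentage
#'
#' `V = 100 * (1 - D / T)`, clamped to 0..100. Degenerate rules (vectorised,
#' each occurrence logged): `T = 0, D = 0` gives the undefined-viability
#' sentinel `NA`; `T = 0, D > 0` gives 0% with a warning; `D > T` clamps to
#' 0% with a warning.
#'
#' @param t_hat Total-cell count(s), >= 0.
#' @param d_hat Dead-cell count(s), >= 0.
#' @return Viability percentage(s) in 0..100, or `NA` where undefined.
#' @examples
#' combine_viability(100, 25) # 75
#' @export
combine_viability <- function(t_hat, d_hat) {
  if (any(t_hat < 0, na.rm = TRUE) || any(d_hat < 0, na.rm = TRUE)) {
    abort("Counts must be non-negative.")
  }
  n <- max(length(t_hat), length(d_hat))
  t_hat <- rep_len(t_hat, n)
  d_hat <- rep_len(d_hat, n)
  v <- 100 * (1 - d_hat / t_hat)
  undef <- t_hat == 0 & d_hat == 0
  if (any(undef)) {
    inform(sprintf(
      "%d case(s) with no cells at all: viability undefined (NA).", sum(undef)
    ))
    v[undef] <- NA_real_
  }
  zero_t <- t_hat == 0 & d_hat > 0
  if (any(zero_t)) {
    warn(sprintf(
      "%d case(s) with dead cells but zero total count: reporting 0%% viability.",
      sum(zero_t)
    ))
    v[zero_t] <- 0
  }
  over <- !is.na(v) & d_hat > t_hat & t_hat > 0
  if (any(over)) {
    warn(sprintf(
      "%d case(s) with dead count exceeding total count: clamped to 0%%.",
      sum(over)
    ))
  }
  clamp(v, 0, 100)
}

#' Truth viability of an annotation set
#'
#' `100 * n_live / n_total`; an empty set yields the undefined-viability
#' sentinel `NA`. Because `total = live + dead`, this agrees exactly with
#' [combine_viability()] whenever the counts are exact.
#'
#' @param set An [annotation_set()].
#' @return Percentage in 0..100, or `NA` for an empty set.
#' @export
truth_viability <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  if (n_total(set) == 0) {
    inform("Empty annotation set: truth viability undefined (NA).")
    return(NA_real_)
  }
  100 * n_live(set) / n_total(set)
}

#' Assemble one image's viability result row
#'
#' @param image_id Image identifier.
#' @param t_hat,d_hat Predicted total and dead counts for the image.
#' @param set The image's [annotation_set()] (supplies the truth).
#' @return A one-row tibble: `image_id`, `T_hat`, `D_hat`, `T_truth`,
#'   `D_truth`, `V_hat`, `V_truth`.
#' @export
viability_result <- function(image_id, t_hat, d_hat, set) {
  tibble::tibble(
    image_id = image_id,
    T_hat = t_hat, D_hat = d_hat,
    T_truth = n_total(set), D_truth = n_dead(set),
    V_hat = combine_viability(t_hat, d_hat),
    V_truth = truth_viability(set)
  )
}

#' Evaluate viability predictions against the labelled truth
#'
#' Produces the evaluation surfaces of the method: per-counter accuracy
#' (mean absolute error and mean signed error, i.e. bias, of the total and
#' dead counts), and predicted-vs-truth viability with MAE, bias and the
#' ordinary least-squares slope/intercept of predicted on truth. With a
#' single image the regression is undefined and flagged (`slope`/`intercept`
#' `NA`, `fit_flag = "undefined"`).
#'
#' @param results A tibble of per-image rows as from [viability_result()]
#'   (columns `image_id`, `V_hat`, `V_truth`, optionally `T_hat`/`T_truth`
#'   and `D_hat`/`D_truth`).
#' @param tile_counts Optional tibble of per-tile diagnostics with columns
#'   `target`, `.pred`, `truth` (kept in the report for plotting).
#' @return An object of class `viability_eval`; see [tidy.viability_eval()],
#'   [glance.viability_eval()] and [autoplot.viability_eval()].
#' @export
evaluate_viability <- function(results, tile_counts = NULL) {
  if (nrow(results) < 1) abort("At least one viability result is required.")
  metr <- function(pred, truth) {
    list(mae = mean(abs(pred - truth)), bias = mean(pred - truth))
  }
  v <- metr(results$V_hat, results$V_truth)
  counts <- NULL
  if (all(c("T_hat", "T_truth", "D_hat", "D_truth") %in% names(results))) {
    tm <- metr(results$T_hat, results$T_truth)
    dm <- metr(results$D_hat, results$D_truth)
    counts <- tibble::tibble(
      counter = c("total", "dead"),
      mae = c(tm$mae, dm$mae),
      bias = c(tm$bias, dm$bias)
    )
  }
  if (nrow(results) >= 2 && stats::sd(results$V_truth) > 0) {
    fit <- lm(V_hat ~ V_truth, data = results)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    fit_flag <- "ok"
  } else {
    slope <- NA_real_
    intercept <- NA_real_
    fit_flag <- "undefined"
  }
  structure(
    list(
      results = results, counts = counts, tile_counts = tile_counts,
      viability = tibble::tibble(
        mae = v$mae, bias = v$bias,
        slope = slope, intercept = intercept, fit_flag = fit_flag,
        n_images = nrow(results)
      )
    ),
    class = "viability_eval"
  )
}

#' @export
print.viability_eval <- function(x, ...) {
  cat(sprintf(
    "<viability_eval> %d image(s) | viability MAE %.2f pp, bias %+.2f pp\n",
    x$viability$n_images, x$viability$mae, x$viability$bias
  ))
  if (!is.null(x$counts)) {
    cat(sprintf(
      "  total counter: MAE %.2f (bias %+.2f); dead counter: MAE %.2f (bias %+.2f)\n",
      x$counts$mae[1], x$counts$bias[1], x$counts$mae[2], x$counts$bias[2]
    ))
  }
  invisible(x)
}

#' Tidiers for viability evaluations
#'
#' `tidy()` returns the per-image result table; `glance()` the one-row
#' summary with viability MAE/bias, regression slope/intercept, and (when
#' counts were supplied) per-counter MAE and bias.
#'
#' @param x A `viability_eval`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy viability_eval
#' @export
tidy.viability_eval <- function(x, ...) {
  x$results
}

#' @rdname tidy.viability_eval
#' @method glance viability_eval
#' @export
glance.viability_eval <- function(x, ...) {
  out <- x$viability
  if (!is.null(x$counts)) {
    out$total_mae <- x$counts$mae[x$counts$counter == "total"]
    out$total_bias <- x$counts$bias[x$counts$counter == "total"]
    out$dead_mae <- x$counts$mae[x$counts$counter == "dead"]
    out$dead_bias <- x$counts$bias[x$counts$counter == "dead"]
  }
  out
}

scatter_panel <- function(df, xlab, ylab, title) {
  ggplot2::ggplot(df, ggplot2::aes(.data$truth, .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = xlab, y = ylab, title = title) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation: predicted vs truth with the identity line
#'
#' One scatter panel per available surface (total counts, dead counts,
#' viability percentage), combined with patchwork when installed, otherwise
#' the viability panel alone.
#'
#' @param object A `viability_eval`.
#' @param ... Unused.
#' @return A ggplot (or patchwork) object.
#' @method autoplot viability_eval
#' @export
autoplot.viability_eval <- function(object, ...) {
  res <- object$results
  panels <- list()
  if (all(c("T_hat", "T_truth") %in% names(res))) {
    panels$total <- scatter_panel(
      tibble::tibble(truth = res$T_truth, pred = res$T_hat),
      "true total count", "predicted total count", "Total-cell counter"
    )
  }
  if (all(c("D_hat", "D_truth") %in% names(res))) {
    panels$dead <- scatter_panel(
      tibble::tibble(truth = res$D_truth, pred = res$D_hat),
      "true dead count", "predicted dead count", "Dead-cell counter"
    )
  }
  panels$viability <- scatter_panel(
    tibble::tibble(truth = res$V_truth, pred = res$V_hat),
    "truth viability (%)", "predicted viability (%)", "Viability"
  )
  if (length(panels) > 1 && requireNamespace("patchwork", quietly = TRUE)) {
    Reduce(`+`, panels)
  } else {
    panels$viability
  }
}
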
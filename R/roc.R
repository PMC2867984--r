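#' ROC analysis of the concordance statistic
#'
#' Subject-level receiver-operating-characteristic analysis for separating
#' diseased (low-concordance) from normal subjects. A subject is called
#' positive when its concordance falls strictly below the cutoff, so the ROC is
#' swept over all observed concordance values (plus an all-positive endpoint).
#' The area under the trapezoidal curve equals the Mann-Whitney pairwise
#' probability that a random positive scores below a random negative, with ties
#' counted 1/2. The reported operating point maximizes Youden's J
#' (sensitivity + specificity - 1), ties broken toward higher specificity.
#'
#' @param records A data frame with columns `subject_id`, `group` and
#'   `concordance` (percent in `[0, 100]`); one row per subject.
#' @param positive The `group` label of the diseased class. Default
#'   `"positive"`.
#' @return A `concordance_roc` object: list with `points` (tibble: `cutoff`,
#'   `sensitivity`, `specificity`), `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `n_positive`, `n_negative`.
#' @examples
#' rec <- tibble::tibble(
#'   subject_id = paste0("s", 1:6),
#'   group = rep(c("positive", "negative"), each = 3),
#'   concordance = c(60, 70, 80, 75, 85, 95))
#' glance(concordance_roc(rec))
#' @export
concordance_roc <- function(records, positive = "positive") {
  if (!is.data.frame(records) ||
      !all(c("group", "concordance") %in% names(records)))
    abort("`records` must have columns `group` and `concordance`.",
          class = "lgequant_parameter_error")
  conc <- as.numeric(records$concordance)
  if (any(!is.finite(conc)) || any(conc < 0 | conc > 100))
    abort("`concordance` must lie in [0, 100].", class = "lgequant_parameter_error")
  is_pos <- records$group == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos < 1L || n_neg < 1L)
    abort("Need at least one subject in each group.",
          class = "lgequant_grouping_error")

  pos <- conc[is_pos]
  neg <- conc[!is_pos]
  cutoffs <- c(sort(unique(conc)), Inf)
  points <- tibble(
    cutoff = cutoffs,
    sensitivity = vapply(cutoffs, function(c) mean(pos < c), numeric(1)),
    specificity = vapply(cutoffs, function(c) mean(neg >= c), numeric(1))
  )

  # trapezoid over (FPR, TPR), including the (0,0) endpoint below all cutoffs
  fpr <- c(0, 1 - points$specificity)
  tpr <- c(0, points$sensitivity)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) + utils::tail(tpr[ord], -1)) / 2)

  finite <- points[is.finite(points$cutoff), ]
  j <- finite$sensitivity + finite$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1L)
    best <- best[which.max(finite$specificity[best])]
  structure(list(points = points,
                 auc = auc,
                 cutoff = finite$cutoff[best],
                 sensitivity = finite$sensitivity[best],
                 specificity = finite$specificity[best],
                 n_positive = n_pos,
                 n_negative = n_neg),
            class = "concordance_roc")
}

#' @export
print.concordance_roc <- function(x, ...) {
  cat(sprintf("<concordance_roc> %d positive / %d negative subjects\n",
              x$n_positive, x$n_negative))
  cat(sprintf("  AUC %.3f; cutoff %.1f%% -> sensitivity %.1f%%, specificity %.1f%%\n",
              x$auc, x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' @rdname concordance_roc
#' @param x,object A `concordance_roc` object.
#' @param ... Unused.
#' @method tidy concordance_roc
#' @export
tidy.concordance_roc <- function(x, ...) x$points

#' @rdname concordance_roc
#' @method glance concordance_roc
#' @export
glance.concordance_roc <- function(x, ...) {
  tibble(auc = x$auc, cutoff = x$cutoff,
         sensitivity = x$sensitivity, specificity = x$specificity,
         n_positive = x$n_positive, n_negative = x$n_negative)
}

#' @rdname concordance_roc
#' @method autoplot concordance_roc
#' @export
autoplot.concordance_roc <- function(object, ...) {
  pts <- object$points
  df <- tibble(fpr = c(0, 1 - pts$specificity), tpr = c(0, pts$sensitivity))
  df <- df[order(df$fpr, df$tpr), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "gray60") +
    ggplot2::geom_step(colour = "#2166AC") +
    ggplot2::annotate("point",
                      x = 1 - object$specificity, y = object$sensitivity,
                      colour = "#D6604D", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC %.3f, cutoff %.1f%%", object$auc, object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Write ROC results to files
#'
#' @param roc A `concordance_roc` object.
#' @param points_csv Path for the operating-points CSV.
#' @param summary_json Path for the summary JSON (AUC, cutoff, sensitivity,
#'   specificity).
#' @return `summary_json`, invisibly.
#' @export
write_roc_results <- function(roc, points_csv, summary_json) {
  if (!inherits(roc, "concordance_roc"))
    abort("`roc` must be a `concordance_roc`.", class = "lgequant_parameter_error")
  utils::write.csv(as.data.frame(roc$points), points_csv, row.names = FALSE)
  jsonlite::write_json(glance(roc), summary_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(summary_json)
}
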
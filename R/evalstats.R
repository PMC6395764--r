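# Skeleton validation against ground truth (precision-recall with a
# spatial tolerance) and multivariate comparison of treatment groups.

#' Precision-recall of a skeleton against ground truth
#'
#' Skeleton pixels are matched one-to-one to ground-truth pixels by greedy
#' nearest-first assignment within the tolerance radius (half the minimum
#' tubule FWHM by convention), so one truth pixel cannot absorb several
#' automated pixels. Precision `P = TP / (TP + FP)`, recall
#' `R = TP / (TP + FN)` and `F1 = 2 P R / (P + R)` (the Dice coefficient
#' of the matched sets).
#'
#' @param auto,truth `er_skeleton` objects or logical matrices on the same
#'   grid (truth thinned and masked identically, cisternae excluded).
#' @param tolerance_px Matching radius in pixels.
#' @return Object of class `er_pr`: `TP`, `FP`, `FN`, `precision`,
#'   `recall`, `f1`, `tolerance_px`.
#' @export
precision_recall <- function(auto, truth, tolerance_px = 2.5) {
  a <- if (inherits(auto, "er_skeleton")) auto$pixels else auto
  t_ <- if (inherits(truth, "er_skeleton")) truth$pixels else truth
  stopifnot(all(dim(a) == dim(t_)))
  if (!any(t_)) stop("precision_recall: empty ground truth, recall undefined")
  wd <- ceiling(tolerance_px)
  pairs <- NULL
  for (dy in -wd:wd) for (dx in -wd:wd) {
    d <- sqrt(dy^2 + dx^2)
    if (d > tolerance_px) next
    ts <- mat_shift(t_, -dy, -dx, FALSE)   # truth pixel at (y+dy, x+dx)
    sel <- which(a & ts)
    if (!length(sel)) next
    ny <- nrow(a)
    tidx <- sel + dx * ny + dy
    pairs <- rbind(pairs, cbind(dist = d, a = sel, t = tidx))
  }
  TP <- 0L
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, "dist"]), , drop = FALSE]
    a_used <- integer(0); t_used <- integer(0)
    a_seen <- new.env(hash = TRUE); t_seen <- new.env(hash = TRUE)
    for (k in seq_len(nrow(pairs))) {
      ak <- as.character(pairs[k, "a"]); tk <- as.character(pairs[k, "t"])
      if (is.null(a_seen[[ak]]) && is.null(t_seen[[tk]])) {
        a_seen[[ak]] <- TRUE; t_seen[[tk]] <- TRUE
        TP <- TP + 1L
      }
    }
  }
  FP <- sum(a) - TP
  FN <- sum(t_) - TP
  P <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  R <- TP / (TP + FN)
  f1 <- if (isTRUE(P + R > 0)) 2 * P * R / (P + R) else 0
  structure(list(TP = TP, FP = FP, FN = FN, precision = P, recall = R,
                 f1 = f1, tolerance_px = tolerance_px), class = "er_pr")
}

#' @export
print.er_pr <- function(x, ...) {
  cat(sprintf("precision %.3f, recall %.3f, F1 %.3f (TP %d, FP %d, FN %d, tol %.1f px)\n",
              x$precision, x$recall, x$f1, x$TP, x$FP, x$FN, x$tolerance_px))
  invisible(x)
}

#' Transform metric columns towards normality
#'
#' Applies the declared transform per column: `"arcsin"` (`asin(sqrt(x))`
#' for metrics bounded in `[0, 1]`), `"log"` (positive wide-range metrics
#' such as length, area or speed), `"logit"` (after clamping to
#' `[0.025, 0.975]`), `"sqrt"`, or `"none"`. The transform spec is
#' recorded in the result so it can be inverted.
#'
#' @param table Data frame of metric columns (plus any grouping columns).
#' @param transforms Named character vector, names = columns.
#' @return The transformed data frame with attribute `transforms`.
#' @export
transform_metrics <- function(table, transforms) {
  out <- table
  for (col in names(transforms)) {
    tr <- transforms[[col]]
    x <- table[[col]]
    out[[col]] <- switch(tr,
      none = x,
      arcsin = {
        if (any(x < 0 | x > 1, na.rm = TRUE))
          stop("transform_metrics: column '", col, "' outside [0, 1] for arcsin")
        asin(sqrt(x))
      },
      log = {
        bad <- which(x <= 0)
        if (length(bad))
          stop("transform_metrics: non-positive value in column '", col,
               "' row ", bad[1], " for log transform")
        log(x)
      },
      logit = {
        z <- pmin(pmax(x, 0.025), 0.975)
        log(z / (1 - z))
      },
      sqrt = {
        if (any(x < 0, na.rm = TRUE))
          stop("transform_metrics: negative value in column '", col,
               "' for sqrt transform")
        sqrt(x)
      },
      stop("transform_metrics: unknown transform '", tr, "'"))
  }
  attr(out, "transforms") <- transforms
  out
}

#' Invert recorded metric transforms
#'
#' @param table Output of [transform_metrics] (attribute `transforms`).
#' @return Data frame on the original scale (exact away from logit clamps).
#' @export
inverse_transform_metrics <- function(table) {
  transforms <- attr(table, "transforms")
  stopifnot(!is.null(transforms))
  out <- table
  for (col in names(transforms)) {
    x <- table[[col]]
    out[[col]] <- switch(transforms[[col]],
      none = x,
      arcsin = sin(x)^2,
      log = exp(x),
      logit = exp(x) / (1 + exp(x)),
      sqrt = x^2)
  }
  attr(out, "transforms") <- NULL
  out
}

# Per-metric one-way ANOVA with Tukey HSD contrasts against the control
# group. Returns F, p and the adjusted p-value of each group-vs-control
# contrast.
tukey_vs_control <- function(table, metrics, group_col = "group",
                             control = NULL) {
  gr <- factor(table[[group_col]])
  if (is.null(control)) control <- levels(gr)[1]
  res <- list()
  for (m in metrics) {
    df <- data.frame(y = table[[m]], g = gr)
    fit <- stats::aov(y ~ g, data = df)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    cn <- rownames(tk)
    vs <- grepl(paste0("^", control, "-"), cn) |
      grepl(paste0("-", control, "$"), cn)
    contr <- tk[vs, , drop = FALSE]
    other <- sub(paste0("^", control, "-"), "",
                 sub(paste0("-", control, "$"), "", rownames(contr)))
    p <- contr[, "p adj"]
    res[[m]] <- data.frame(
      metric = m, F = an$`F value`[1], p = an$`Pr(>F)`[1],
      group = other, p_tukey = p,
      signif = cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", "")),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare treatment groups across a metric table
#'
#' Parametric MANOVA with Pillai's trace and Roy's largest root, followed
#' by per-metric one-way ANOVA with Tukey HSD contrasts against the
#' control group, and canonical discriminant scores for visualising group
#' separation.
#'
#' @param table Data frame: one row per movie, metric columns plus a group
#'   column.
#' @param control_label Name of the control group.
#' @param metrics Metric columns to include (default: all numeric).
#' @param group_col Name of the grouping column.
#' @return Object of class `er_group_report`: `manova` (Pillai/Roy
#'   statistics with F approximations and p-values), `anova` (per-metric F,
#'   p and Tukey flags vs control), `canonical` (scores per row, first
#'   columns of the discriminant space).
#' @export
compare_groups <- function(table, control_label, metrics = NULL,
                           group_col = "group") {
  gr <- factor(table[[group_col]])
  if (nlevels(gr) < 2) stop("compare_groups: need at least 2 groups")
  if (any(table(gr) < 2)) stop("compare_groups: every group needs >= 2 rows")
  if (!control_label %in% levels(gr))
    stop("compare_groups: control group '", control_label, "' not found")
  if (is.null(metrics))
    metrics <- names(table)[vapply(table, is.numeric, logical(1))]
  X <- as.matrix(table[, metrics, drop = FALSE])
  if (anyNA(X)) stop("compare_groups: missing cells in the metric table")
  fit <- tryCatch(stats::manova(X ~ gr),
                  error = function(e) stop("compare_groups: MANOVA failed (",
                                           conditionMessage(e), ")"))
  sum_p <- tryCatch(summary(fit, test = "Pillai")$stats,
                    error = function(e)
                      stop("compare_groups: singular covariance; reduce the ",
                           "metric subset (", conditionMessage(e), ")"))
  sum_r <- summary(fit, test = "Roy")$stats
  manova_out <- data.frame(
    test = c("Pillai", "Roy"),
    statistic = c(sum_p[1, "Pillai"], sum_r[1, "Roy"]),
    F = c(sum_p[1, "approx F"], sum_r[1, "approx F"]),
    df1 = c(sum_p[1, "num Df"], sum_r[1, "num Df"]),
    df2 = c(sum_p[1, "den Df"], sum_r[1, "den Df"]),
    p = c(sum_p[1, "Pr(>F)"], sum_r[1, "Pr(>F)"]))
  # canonical discriminant scores from the eigenvectors of W^-1 B
  Xc <- scale(X, scale = FALSE)
  H <- crossprod(stats::fitted(stats::lm(Xc ~ gr)))
  E <- crossprod(stats::residuals(stats::lm(Xc ~ gr)))
  can <- tryCatch({
    ev <- eigen(solve(E) %*% H)
    k <- min(nlevels(gr) - 1, ncol(X))
    sc <- Re(Xc %*% ev$vectors[, seq_len(k), drop = FALSE])
    colnames(sc) <- paste0("can", seq_len(k))
    data.frame(group = gr, sc)
  }, error = function(e) NULL)
  anova_out <- tukey_vs_control(table, metrics, group_col, control_label)
  structure(list(manova = manova_out, anova = anova_out, canonical = can,
                 control = control_label, metrics = metrics),
            class = "er_group_report")
}

#' @export
print.er_group_report <- function(x, ...) {
  cat("Group comparison vs control '", x$control, "'\n", sep = "")
  print(x$manova, row.names = FALSE)
  cat("\nPer-metric ANOVA (Tukey HSD vs control):\n")
  print(x$anova, row.names = FALSE)
  invisible(x)
}
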
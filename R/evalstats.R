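# Leave-one-session-out cross-validation, accuracy tables and the
# non-parametric comparison battery: Friedman test with tie correction,
# Kendall's coefficient of concordance, pairwise Wilcoxon signed-rank tests
# with Bonferroni correction.

#' Leave-one-session-out cross-validation
#'
#' For each session `s`, trains on all other sessions and tests on `s`.
#' `pipeline` is a function `(train, test) -> predicted labels` (integer
#' vector aligned with the test trials). A session missing some class raises
#' a warning but the fold still runs.
#'
#' @param dataset A `cvep_epochs` with at least 2 sessions.
#' @param pipeline Function of `(train, test)` returning predicted labels.
#' @param method Method tag stored in the report.
#' @param subject Subject tag stored in the report.
#' @return A `cvep_cvreport`: per-fold accuracy (%), `mean`, `sd`, fold
#'   definition (held-out session ids) and tags.
#' @export
session_cv <- function(dataset, pipeline, method = "method", subject = 1L) {
  stopifnot(inherits(dataset, "cvep_epochs"))
  sessions <- sort(unique(dataset$session_id))
  if (length(sessions) < 2L) stop("need at least 2 sessions")
  n_classes <- max(dataset$labels)
  acc <- numeric(length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[i]
    test_idx <- dataset$session_id == s
    train <- subset_epochs(dataset, !test_idx)
    test <- subset_epochs(dataset, test_idx)
    if (length(unique(train$labels)) < n_classes ||
        length(unique(test$labels)) < n_classes)
      warning("fold ", s, ": some class missing from train or test",
              call. = FALSE)
    pred <- pipeline(train, test)
    acc[i] <- 100 * mean(pred == test$labels)
  }
  structure(list(fold_accuracy = acc, mean = mean(acc),
                 sd = stats::sd(acc), folds = sessions,
                 method = method, subject = subject),
            class = "cvep_cvreport")
}

#' @export
print.cvep_cvreport <- function(x, ...) {
  cat(sprintf("<cvep_cvreport> %s (subject %s): %.2f +/- %.2f %%  [%s]\n",
              x$method, x$subject, x$mean, x$sd,
              paste(sprintf("%.1f", x$fold_accuracy), collapse = ", ")))
  invisible(x)
}

# mid-ranks per row (ties averaged)
row_ranks <- function(acc) t(apply(acc, 1, rank))

#' Friedman test with Kendall's coefficient of concordance
#'
#' Subjects in rows, methods in columns. Mid-ranks with the standard tie
#' correction; `W = chi2 / (n (k - 1))`, `df = k - 1`.
#'
#' @param acc Numeric `subjects x methods` matrix (at least 2 of each).
#' @return List with `chi2`, `df`, `p`, `ranks` (average rank per method) and
#'   `W`.
#' @export
friedman_test <- function(acc) {
  acc <- as.matrix(acc)
  n <- nrow(acc); k <- ncol(acc)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 methods")
  R <- row_ranks(acc)
  if (all(apply(acc, 1, function(r) length(unique(r)) == 1L)))
    stop("all rows are constant: concordance undefined")
  Rj <- colSums(R)
  S <- sum((Rj - n * (k + 1) / 2)^2)
  # tie correction: sum over rows of (t^3 - t) per tie group
  TT <- sum(apply(acc, 1, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  denom <- n^2 * (k^3 - k) / 12 - n * TT / 12
  W <- S / denom
  chi2 <- n * (k - 1) * W
  df <- k - 1
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       ranks = Rj / n, W = W)
}

#' Pairwise Wilcoxon signed-rank tests with Bonferroni correction
#'
#' All `choose(k, 2)` method pairs; the family alpha is divided by the pair
#' count (9 methods give 36 pairs and adjusted alpha 0.05/36 = 0.0014).
#' Zero differences are discarded (Wilcoxon convention); the exact
#' distribution is used for up to 25 nonzero differences without ties,
#' otherwise the normal approximation. A pair with no nonzero differences is
#' flagged degenerate and carries no p-value.
#'
#' @param acc Numeric `subjects x methods` matrix.
#' @param family_alpha Family-wise error level (default 0.05).
#' @return A `cvep_comparison`: the Friedman summary plus a data frame
#'   `pairs` (method indices, p-value, significance flag, degenerate flag)
#'   and `alpha_adj`.
#' @export
pairwise_wilcoxon <- function(acc, family_alpha = 0.05) {
  acc <- as.matrix(acc)
  k <- ncol(acc)
  fr <- friedman_test(acc)
  cmb <- utils::combn(k, 2)
  alpha_adj <- family_alpha / ncol(cmb)
  res <- data.frame(method_a = cmb[1, ], method_b = cmb[2, ],
                    p = NA_real_, significant = FALSE, degenerate = FALSE)
  for (i in seq_len(ncol(cmb))) {
    d <- acc[, cmb[1, i]] - acc[, cmb[2, i]]
    d <- d[d != 0]
    if (!length(d)) {
      res$degenerate[i] <- TRUE
      next
    }
    exact <- length(d) <= 25L && !any(duplicated(abs(d)))
    p <- suppressWarnings(stats::wilcox.test(
      acc[, cmb[1, i]], acc[, cmb[2, i]], paired = TRUE,
      exact = exact)$p.value)
    res$p[i] <- p
    res$significant[i] <- is.finite(p) && p < alpha_adj
  }
  structure(list(friedman = fr, pairs = res, alpha_adj = alpha_adj,
                 n_methods = k),
            class = "cvep_comparison")
}

#' @export
print.cvep_comparison <- function(x, ...) {
  cat(sprintf(
    "<cvep_comparison> Friedman chi2(%d) = %.2f, p = %.3g, W = %.3f\n",
    x$friedman$df, x$friedman$chi2, x$friedman$p, x$friedman$W))
  cat(sprintf("  %d pairwise Wilcoxon tests, adjusted alpha = %.4f, %d significant\n",
              nrow(x$pairs), x$alpha_adj, sum(x$pairs$significant)))
  invisible(x)
}

#' Accuracy table from a collection of CV reports
#'
#' Rows are subjects, columns methods, entries `"mean +/- SD"` over folds,
#' plus Mean and SD summary rows over subjects. Missing cells are blank.
#'
#' @param reports List of [session_cv()] reports.
#' @return Character matrix with subject rows and method columns; the
#'   numeric means are attached as attribute `"means"`.
#' @export
accuracy_table <- function(reports) {
  subs <- sort(unique(vapply(reports, function(r) as.integer(r$subject), 1L)))
  methods <- unique(vapply(reports, `[[`, "", "method"))
  tab <- matrix("", length(subs) + 2L, length(methods),
                dimnames = list(c(paste0("subject", subs), "Mean", "SD"),
                                methods))
  means <- matrix(NA_real_, length(subs), length(methods),
                  dimnames = list(paste0("subject", subs), methods))
  for (r in reports) {
    i <- match(as.integer(r$subject), subs)
    j <- match(r$method, methods)
    tab[i, j] <- sprintf("%.2f ± %.2f", r$mean, r$sd)
    means[i, j] <- r$mean
  }
  for (j in seq_along(methods)) {
    v <- means[, j]
    if (all(is.na(v))) next
    tab[length(subs) + 1L, j] <- sprintf("%.2f", mean(v, na.rm = TRUE))
    tab[length(subs) + 2L, j] <-
      sprintf("%.2f", if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE)
              else 0)
  }
  attr(tab, "means") <- means
  tab
}

#' Export a CV report collection and comparison summary
#'
#' `write_cv_csv` writes one row per (subject, method, fold);
#' `write_comparison_json` writes the Friedman summary and all pairwise
#' p-values/flags.
#'
#' @param reports List of `cvep_cvreport`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, function(r)
    data.frame(subject = r$subject, method = r$method, fold = r$folds,
               accuracy = r$fold_accuracy)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cv_csv
#' @param comparison A [pairwise_wilcoxon()] result.
#' @export
write_comparison_json <- function(comparison, path) {
  jsonlite::write_json(
    list(friedman = comparison$friedman[c("chi2", "df", "p", "W", "ranks")],
         alpha_adj = comparison$alpha_adj,
         pairs = comparison$pairs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
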
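#' Error metrics of an age-prediction set
#'
#' MAE = mean |estimated - actual|, MBE = mean (estimated - actual) (so a
#' negative bias means underestimation), RMSE = sqrt(mean squared error).
#'
#' @param predictions data frame with columns \code{estimated_age} and
#'   \code{actual_age} (one row per scan or per individual).
#' @return named numeric vector \code{c(mae, mbe, rmse)} in years.
#' @export
compute_metrics <- function(predictions) {
  est <- predictions$estimated_age
  act <- predictions$actual_age
  if (length(est) == 0L) stop("empty prediction set")
  if (any(act <= 0)) stop("actual ages must be positive")
  d <- est - act
  c(mae = mean(abs(d)), mbe = mean(d), rmse = sqrt(mean(d^2)))
}

#' Average bilateral estimates per individual
#'
#' When both the right and left symphysis of an individual are present, the
#' individual's estimated age is the average over both bones; single-scan
#' individuals pass through unchanged.
#'
#' @param predictions data frame with \code{individual_id},
#'   \code{estimated_age}, \code{actual_age} and optionally \code{fold}.
#' @return one row per individual.
#' @export
aggregate_individuals <- function(predictions) {
  ids <- as.character(predictions$individual_id)
  chk <- tapply(predictions$actual_age, ids,
                function(a) diff(range(a)) > 1e-9)
  if (any(chk))
    stop("conflicting actual ages for individual(s): ",
         paste(names(chk)[chk], collapse = ", "))
  est <- tapply(predictions$estimated_age, ids, mean)
  act <- tapply(predictions$actual_age, ids, function(a) a[1])
  out <- data.frame(individual_id = names(est),
                    estimated_age = as.numeric(est),
                    actual_age = as.numeric(act),
                    stringsAsFactors = FALSE)
  if ("fold" %in% names(predictions)) {
    fold <- tapply(predictions$fold, ids, function(f) f[1])
    out$fold <- as.integer(fold[out$individual_id])
  }
  rownames(out) <- NULL
  out
}

#' k-fold cross-validation of the age model
#'
#' Randomly partitions the data into k near-equal disjoint subsamples, fits
#' the model on k-1 of them and predicts the held-out fold, repeating until
#' every subsample has served once as the validation set. By default the
#' partition unit is the individual, so both bones of one person share a
#' fold and cannot leak between training and validation; scan-level
#' partitioning is available. Pooled out-of-fold predictions (aggregated to
#' individuals when \code{unit = "individual"}) give the reported metrics.
#'
#' @param features data frame with \code{individual_id}, \code{age} and the
#'   feature columns (\code{scan_id}/\code{side} carried through if present).
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param unit partition unit: \code{"individual"} or \code{"scan"}.
#' @param subset feature columns to fit.
#' @return list of class \code{eval_report}: pooled \code{mae}, \code{mbe},
#'   \code{rmse}, \code{n}, \code{per_fold} data frame, \code{per_age}
#'   dispersion table (see \code{\link{age_dispersion_table}}) and the
#'   pooled \code{predictions}.
#' @export
crossval <- function(features, k = 5L, seed = 1L,
                     unit = c("individual", "scan"),
                     subset = paste0("x", 1:6)) {
  unit <- match.arg(unit)
  k <- as.integer(k)
  n <- nrow(features)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("fewer rows than folds")
  if (!"individual_id" %in% names(features))
    features$individual_id <- seq_len(n)
  if (!"age" %in% names(features)) stop("features must contain an age column")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  units <- if (unit == "individual")
    sort(unique(as.character(features$individual_id))) else seq_len(n)
  fold_of_unit <- sample(rep_len(seq_len(k), length(units)))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  fold <- if (unit == "individual")
    fold_of_unit[match(as.character(features$individual_id), units)]
  else fold_of_unit

  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- features[fold != f, , drop = FALSE]
    test <- features[fold == f, , drop = FALSE]
    if (nrow(train) < length(subset) + 2L)
      stop("fold ", f, " leaves too few training rows")
    m <- fit_age_model(train, subset = subset)
    preds[[f]] <- data.frame(
      individual_id = test$individual_id,
      scan_id = if ("scan_id" %in% names(test)) test$scan_id else NA,
      side = if ("side" %in% names(test)) test$side else "unknown",
      estimated_age = estimate_age(test, m),
      actual_age = test$age,
      fold = f, stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, preds)
  scored <- if (unit == "individual") aggregate_individuals(pooled) else pooled
  met <- compute_metrics(scored)
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    p <- scored[scored$fold == f, , drop = FALSE]
    m <- compute_metrics(p)
    data.frame(fold = f, n = nrow(p), mae = m["mae"], mbe = m["mbe"],
               rmse = m["rmse"], row.names = NULL)
  }))
  structure(list(mae = unname(met["mae"]), mbe = unname(met["mbe"]),
                 rmse = unname(met["rmse"]), n = nrow(scored),
                 per_fold = per_fold,
                 per_age = age_dispersion_table(scored),
                 predictions = scored),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (n = %d): MAE %.2f, MBE %.2f, RMSE %.2f years\n",
              x$n, x$mae, x$mbe, x$rmse))
  invisible(x)
}

#' Per-age dispersion of the estimates
#'
#' Groups predictions by integer actual age (one-year intervals) and
#' summarizes the estimates in each group by their five-number summary.
#'
#' @param predictions data frame with \code{estimated_age} and
#'   \code{actual_age}.
#' @param quartiles \code{"linear"} for linear interpolation between order
#'   statistics (the common convention) or \code{"nearest"} for
#'   nearest-rank quartiles.
#' @return data frame with columns \code{age}, \code{n}, \code{min},
#'   \code{q1}, \code{median}, \code{q3}, \code{max}.
#' @export
age_dispersion_table <- function(predictions,
                                 quartiles = c("linear", "nearest")) {
  quartiles <- match.arg(quartiles)
  if (nrow(predictions) == 0L) stop("empty prediction set")
  type <- if (quartiles == "linear") 7L else 1L
  age <- as.integer(round(predictions$actual_age))
  rows <- lapply(sort(unique(age)), function(a) {
    e <- predictions$estimated_age[age == a]
    q <- stats::quantile(e, c(0.25, 0.5, 0.75), type = type, names = FALSE)
    data.frame(age = a, n = length(e), min = min(e), q1 = q[1],
               median = q[2], q3 = q[3], max = max(e))
  })
  do.call(rbind, rows)
}

#' Write an evaluation report as delimited text
#'
#' Writes the pooled metrics, the per-fold table and the per-age dispersion
#' table into one tab-delimited file with commented section headers.
#'
#' @param report an \code{\link{crossval}} result.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pooled", con)
  utils::write.table(data.frame(n = report$n, mae = report$mae,
                                mbe = report$mbe, rmse = report$rmse),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# per_fold", con)
  utils::write.table(report$per_fold, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("# per_age", con)
  utils::write.table(report$per_age, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Box-plot style figure of estimates per actual age
#'
#' Draws the per-age five-number summaries as boxes with a median trace and
#' the dashed identity line marking ideal estimation. Requires
#' \pkg{ggplot2}.
#'
#' @param report an \code{\link{crossval}} result (or any object with a
#'   \code{per_age} table).
#' @return a ggplot object.
#' @export
plot_age_dispersion <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("the ggplot2 package is required for plotting")
  tab <- report$per_age
  ggplot2::ggplot(tab, ggplot2::aes(x = age)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = min, ymax = max),
                           width = 0.3, linewidth = 0.3) +
    ggplot2::geom_crossbar(ggplot2::aes(y = median, ymin = q1, ymax = q3),
                           width = 0.8, linewidth = 0.3, fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = median), colour = "#8B4513") +
    ggplot2::labs(x = "actual age (years)", y = "estimated age (years)") +
    ggplot2::theme_minimal()
}
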
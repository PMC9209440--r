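#' Construct an age-estimation model
#'
#' A multi-linear model: estimated age = sum(slopes * features) + offset.
#'
#' @param slopes named numeric vector of slope coefficients (years per
#'   feature unit); names are the feature names.
#' @param offset intercept K in years.
#' @param fit_metadata optional list (sample size, residual variance,
#'   provenance).
#' @return an object of class \code{age_model}.
#' @export
age_model <- function(slopes, offset, fit_metadata = list()) {
  stopifnot(is.numeric(slopes), length(names(slopes)) == length(slopes),
            all(nzchar(names(slopes))), is.finite(offset))
  structure(list(slopes = slopes, offset = unname(offset),
                 feature_names = names(slopes),
                 fit_metadata = fit_metadata),
            class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat("age_model:", length(x$slopes), "features, offset =",
      format(x$offset), "years\n")
  print(x$slopes)
  if (!is.null(x$fit_metadata$n))
    cat("  fitted on n =", x$fit_metadata$n, "\n")
  invisible(x)
}

#' The published six-feature symphyseal age model
#'
#' The multi-linear regression fitted on the original 483-bone reference
#' sample. Slopes (years per feature unit): x1 3,118,517.53 (sd of local
#' Dirichlet normal energy; the feature is numerically tiny, hence the large
#' slope -- features are deliberately not rescaled so these coefficients
#' apply verbatim), x2 191.36 (sd of local curvature), x3 0.10 (total
#' ellipses), x4 1.03 (horizontal ellipses), x5 -3.18 (vertical ellipses),
#' x6 0.14 (holes); offset K = 17.85 years.
#'
#' @return an \code{\link{age_model}}.
#' @export
published_sass_model <- function() {
  age_model(c(x1 = 3118517.53, x2 = 191.36, x3 = 0.10,
              x4 = 1.03, x5 = -3.18, x6 = 0.14),
            offset = 17.85,
            fit_metadata = list(n = 483L,
                                provenance = "published reference fit"))
}

#' Estimate age from a feature vector or feature table
#'
#' The dot product of the features with the model slopes plus the offset.
#' Estimates are not clamped to the adult range: the raw regression output
#' is reported (clamping is available via \code{clamp}).
#'
#' @param features a \code{\link{extract_features}} vector, a named numeric
#'   vector, or a data frame containing the model's feature columns.
#' @param model an \code{\link{age_model}}.
#' @param clamp optional length-2 numeric; estimates are clipped into this
#'   range when supplied.
#' @return estimated age(s) in years.
#' @export
estimate_age <- function(features, model = published_sass_model(),
                         clamp = NULL) {
  stopifnot(inherits(model, "age_model"))
  fn <- model$feature_names
  if (is.data.frame(features)) {
    if (!all(fn %in% names(features)))
      stop("feature table lacks model features: ",
           paste(setdiff(fn, names(features)), collapse = ", "))
    X <- as.matrix(features[, fn, drop = FALSE])
  } else {
    x <- unclass(features)
    if (!all(fn %in% names(x)))
      stop("feature vector lacks model features: ",
           paste(setdiff(fn, names(x)), collapse = ", "))
    X <- matrix(x[fn], nrow = 1)
  }
  if (!all(is.finite(X))) stop("non-finite feature value")
  est <- as.vector(X %*% model$slopes[fn]) + model$offset
  if (!is.null(clamp)) est <- pmin(pmax(est, clamp[1]), clamp[2])
  est
}

#' Fit the age model by ordinary least squares
#'
#' @param features data frame with an \code{age} column and the candidate
#'   feature columns.
#' @param subset character vector of feature column names to use.
#' @return an \code{\link{age_model}} with \code{fit_metadata} holding the
#'   sample size and residual variance.
#' @export
fit_age_model <- function(features, subset = paste0("x", 1:6)) {
  if (!"age" %in% names(features)) stop("features must contain an age column")
  if (!all(subset %in% names(features)))
    stop("missing feature columns: ",
         paste(setdiff(subset, names(features)), collapse = ", "))
  n <- nrow(features)
  if (n <= length(subset) + 1L)
    stop("need more rows than features + 1 to fit")
  X <- as.matrix(features[, subset, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    aliased <- setdiff(seq_len(ncol(X) + 1L), qrX$pivot[seq_len(qrX$rank)])
    stop("collinear design; offending column(s): ",
         paste(c("(intercept)", subset)[aliased], collapse = ", "))
  }
  fit <- stats::lm(stats::reformulate(subset, response = "age"),
                   data = features)
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  age_model(cf[subset], offset = cf[["(Intercept)"]],
            fit_metadata = list(n = n,
                                residual_variance = rss / fit$df.residual,
                                rss = rss,
                                se = suppressWarnings(
                                  summary(fit)$coefficients[, 2]),
                                provenance = "ols fit"))
}

# least-squares AIC with the error variance profiled out;
# k counts the slopes plus the intercept
ols_aic <- function(features, subset) {
  n <- nrow(features)
  rss <- if (length(subset) == 0L) {
    sum((features$age - mean(features$age))^2)
  } else {
    fit <- stats::lm(stats::reformulate(subset, response = "age"),
                     data = features)
    sum(stats::residuals(fit)^2)
  }
  n * log(rss / n) + 2 * (length(subset) + 1)
}

#' Greedy forward feature selection by AIC
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' whose addition gives the lowest AIC (computed as n log(RSS/n) + 2k with
#' k the parameter count including the intercept) and stops when no addition
#' lowers the AIC. Ties break deterministically by candidate order.
#'
#' @param features data frame with \code{age} and the candidate columns.
#' @param candidates character vector of candidate feature names.
#' @return character vector of selected feature names (possibly empty).
#' @export
greedy_select <- function(features, candidates = paste0("x", 1:6)) {
  stopifnot(length(candidates) >= 2L)
  if (nrow(features) <= length(candidates) + 2L)
    stop("too few rows for selection over ", length(candidates),
         " candidates")
  selected <- character(0)
  best <- ols_aic(features, selected)
  remaining <- candidates
  while (length(remaining) > 0L) {
    aics <- vapply(remaining,
                   function(cand) ols_aic(features, c(selected, cand)), 0)
    i <- which.min(aics)  # first minimum: tie-break by candidate order
    if (aics[i] >= best) break
    best <- aics[i]
    selected <- c(selected, remaining[i])
    remaining <- remaining[-i]
  }
  selected
}

#' Baseline age estimators
#'
#' The two naive reference models: \code{random_uniform} draws ages
#' uniformly from [low, high] (the reference sample spans 18-92 years) and
#' \code{constant} always answers a fixed value (54.1 years, the reference
#' sample's mean age). They carry no estimation power and serve as
#' performance floors.
#'
#' @param kind \code{"random_uniform"} or \code{"constant"}.
#' @param low,high years; range of the uniform draw.
#' @param value years; the constant answer.
#' @param seed integer seed making the uniform baseline reproducible.
#' @return a \code{baseline_model}.
#' @export
baseline_model <- function(kind = c("random_uniform", "constant"),
                           low = 18, high = 92, value = 54.1, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "random_uniform" && low >= high) stop("low must be < high")
  structure(list(kind = kind, low = low, high = high, value = value,
                 seed = as.integer(seed)),
            class = "baseline_model")
}

#' @rdname baseline_model
#' @param b a \code{baseline_model}.
#' @param n number of estimates to produce.
#' @return numeric vector of \code{n} estimated ages.
#' @export
baseline_predict <- function(b, n) {
  stopifnot(inherits(b, "baseline_model"), n >= 1)
  if (b$kind == "constant") return(rep(b$value, n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(b$seed)
  stats::runif(n, b$low, b$high)
}

#' Write / read an age model as plain text
#'
#' A small key-value text format holding feature names, slopes, offset and
#' scalar metadata; digits are preserved exactly.
#'
#' @param model an \code{\link{age_model}}.
#' @param path file path.
#' @return \code{path} (writer) or an \code{age_model} (reader).
#' @export
write_age_model <- function(model, path) {
  stopifnot(inherits(model, "age_model"))
  lines <- c("# symphage age_model",
             paste("offset", sprintf("%.17g", model$offset)),
             paste("slope", model$feature_names,
                   sprintf("%.17g", model$slopes)))
  md <- model$fit_metadata
  scal <- md[vapply(md, function(x) is.atomic(x) && length(x) == 1L, TRUE)]
  if (length(scal))
    lines <- c(lines, paste("meta", names(scal), unlist(scal)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  tok <- strsplit(lines, "\\s+")
  kind <- vapply(tok, `[[`, "", 1L)
  offset <- as.numeric(tok[[which(kind == "offset")[1]]][2])
  sl <- tok[kind == "slope"]
  slopes <- stats::setNames(vapply(sl, function(t) as.numeric(t[3]), 0),
                            vapply(sl, `[[`, "", 2L))
  md <- list()
  for (t in tok[kind == "meta"]) {
    v <- suppressWarnings(as.numeric(t[3]))
    md[[t[2]]] <- if (is.na(v)) t[3] else v
  }
  age_model(slopes, offset, fit_metadata = md)
}
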
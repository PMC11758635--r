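#' @keywords internal
grade_labels <- function() {
  c("poor", "relatively poor", "medium", "relatively good", "good")
}

#' Construct a grade scale from per-indicator interval points
#'
#' A grade scale holds, for each indicator, five interval points ordered from
#' the "poor" grade to the "good" grade. The axis direction is inferred from
#' the ordering of the points: strictly increasing points mean larger values
#' are better; strictly decreasing points mean smaller values are better.
#'
#' @param points numeric matrix or data frame, one row per indicator
#'   (rownames = indicator names), five columns ordered poor to good.
#' @return a `grade_scale` object.
#' @export
grade_scale <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 5) stop("a grade scale needs exactly five interval points")
  if (is.null(rownames(points))) stop("interval points need indicator rownames")
  colnames(points) <- grade_labels()
  dirs <- apply(points, 1, function(p) {
    d <- diff(p)
    if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing" else NA_character_
  })
  bad <- is.na(dirs)
  if (any(bad)) {
    stop("interval points must be strictly monotone: ",
         paste(rownames(points)[bad], collapse = ", "))
  }
  structure(list(points = points, direction = dirs), class = "grade_scale")
}

#' Build a quintile grade scale from reference-ecosystem values
#'
#' Interval points are the 20th, 40th, 60th, 80th and 100th percentiles
#' (linear-interpolation quantiles by default) of each indicator's reference
#' distribution. For positive indicators the quintiles are assigned poor to
#' good in increasing order; for negative indicators (larger is worse) in
#' decreasing order, so the resulting scale's axis runs good-ward either way.
#'
#' @param reference_values named list of numeric vectors, one per indicator,
#'   each with at least 5 values.
#' @param directions named character vector, `"positive"` or `"negative"`
#'   per indicator.
#' @param quantile_type quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return a [grade_scale()].
#' @export
build_grade_scale <- function(reference_values, directions,
                              quantile_type = 7) {
  stopifnot(is.list(reference_values))
  nms <- names(reference_values)
  if (is.null(nms) || any(nms == "")) stop("reference values must be named per indicator")
  missing_dir <- setdiff(nms, names(directions))
  if (length(missing_dir) > 0) {
    stop("no direction given for: ", paste(missing_dir, collapse = ", "))
  }
  pts <- matrix(NA_real_, length(nms), 5, dimnames = list(nms, grade_labels()))
  for (ind in nms) {
    v <- reference_values[[ind]]
    v <- v[is.finite(v)]
    if (length(v) < 5) stop("indicator ", ind, " has fewer than 5 reference values")
    q <- stats::quantile(v, probs = c(0.2, 0.4, 0.6, 0.8, 1.0),
                         type = quantile_type, names = FALSE)
    if (any(diff(q) <= 0)) {
      stop("degenerate reference distribution for ", ind,
           " (tied quintiles)")
    }
    dir <- match.arg(directions[[ind]], c("positive", "negative"))
    pts[ind, ] <- if (dir == "positive") q else rev(q)
  }
  grade_scale(pts)
}

#' @export
print.grade_scale <- function(x, ...) {
  cat(sprintf("<grade_scale> %d indicators\n", nrow(x$points)))
  print(round(x$points, 4))
  invisible(x)
}

#' Triangular fuzzy membership of a value in the five grades
#'
#' Membership functions are triangular with vertices at the five interval
#' points: a value lying between adjacent points splits its membership
#' linearly between the two bracketing grades; values beyond the extreme
#' points take full membership in the extreme grade. The same interpolation
#' applies on a decreasing axis. The returned vector always sums to 1.
#'
#' @param value indicator value (finite scalar)
#' @param indicator indicator name present in the scale
#' @param scale a [grade_scale()]
#' @return numeric 5-vector named poor to good.
#' @export
membership <- function(value, indicator, scale) {
  stopifnot(inherits(scale, "grade_scale"))
  if (!indicator %in% rownames(scale$points)) {
    stop("indicator not in scale: ", indicator)
  }
  if (!is.finite(value)) stop("non-finite value for indicator ", indicator)
  p <- scale$points[indicator, ]
  decreasing <- scale$direction[[indicator]] == "decreasing"
  # work on the good-ward axis; flip a decreasing scale so points increase
  pp <- if (decreasing) -p else p
  v <- if (decreasing) -value else value

  m <- numeric(5)
  if (v <= pp[1]) {
    m[1] <- 1
  } else if (v >= pp[5]) {
    m[5] <- 1
  } else {
    k <- findInterval(v, pp, rightmost.closed = TRUE)
    w <- (pp[k + 1] - v) / (pp[k + 1] - pp[k])
    m[k] <- w
    m[k + 1] <- 1 - w
  }
  stats::setNames(m, grade_labels())
}

#' Fuzzy comprehensive evaluation of ecosystem status
#'
#' Computes the membership matrix of every weighted indicator, aggregates the
#' grade memberships with the indicator weights, and assigns the final grade
#' by the maximum-membership principle. Ties are broken toward the better
#' grade with a warning.
#'
#' @param indices named numeric vector or `ena_index_set` of indicator values
#' @param scale a [grade_scale()]
#' @param weights named numeric vector of indicator weights (non-negative,
#'   summing to 1 within 1 percent)
#' @return an `evaluation_result`: `membership` (indicator x grade matrix),
#'   `aggregate` (grade 5-vector summing to the weight total), `grade`
#'   (label), and `weights`.
#' @export
evaluate_status <- function(indices, scale, weights) {
  if (inherits(indices, "ena_index_set")) indices <- unlist(indices)
  wn <- names(weights)
  if (is.null(wn)) stop("weights must be named")
  if (any(weights < 0)) stop("weights must be non-negative")
  wt <- sum(weights)
  if (wt < 0.99 || wt > 1.01) {
    stop(sprintf("weights must sum to ~1 (got %.4f)", wt))
  }
  gap <- setdiff(wn, names(indices))
  if (length(gap) > 0) {
    stop("index set lacks weighted indicators: ", paste(gap, collapse = ", "))
  }
  M <- t(vapply(wn, function(ind) membership(indices[[ind]], ind, scale),
                numeric(5)))
  agg <- as.numeric(weights %*% M)
  names(agg) <- grade_labels()
  best <- which(agg == max(agg))
  if (length(best) > 1) {
    warning("tied aggregate membership; taking the better grade")
  }
  structure(list(
    membership = M,
    aggregate = agg,
    grade = grade_labels()[max(best)],
    weights = weights
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> grade: %s\n", x$grade))
  print(round(rbind(x$membership, aggregate = x$aggregate), 3))
  invisible(x)
}
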
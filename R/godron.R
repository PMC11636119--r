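# Coverage-based M. Godron community-stability measurement.
#
# Species are ranked by dominance and the cumulative percentage of
# species (x) is plotted against the cumulative relative coverage (y).
# A smooth polynomial is fitted through the scatter and intersected with
# the anti-diagonal joining (0,100) and (100,0). A perfectly stable
# community crosses at the 20/80 configuration; the Euclidean distance
# of the intersection from (20,80) measures departure from it, with
# sqrt(10^2 + 10^2) = 14.142 as the stability threshold. The classical
# method cumulates species frequency; here coverage replaces frequency,
# which is better suited to clonal sandy-land herbs whose ramet counts
# are ambiguous.

#' The Godron stability threshold
#'
#' Distance from the 20/80 stability point at or below which a community
#' is deemed stable: `sqrt(10^2 + 10^2) = 14.142...`, i.e. a 10-point
#' departure on each axis.
#'
#' @return `sqrt(200)`.
#' @export
godron_threshold <- function() sqrt(200)

#' Build the cumulative rank-coverage curve
#'
#' Species are sorted by the measure in decreasing order (ties broken by
#' species name for determinism); point `i` of `S` is
#' `x = 100 i / S`, `y = 100 * cumsum(measure) / total`. The final point
#' is always (100, 100).
#'
#' @param measure named non-negative numeric vector, one entry per
#'   species (coverage by default; the classical method uses frequency).
#'   Total must be positive.
#' @param measure_name `"coverage"` or `"frequency"` (label only).
#' @return object of class `godron_curve`: list with `points`
#'   (data.frame `x`, `y`), `S`, `species` (rank order), `shares`,
#'   `measure`.
#' @export
build_cumulative_curve <- function(measure,
                                   measure_name = c("coverage",
                                                    "frequency")) {
  measure_name <- match.arg(measure_name)
  if (length(measure) == 0L) stop("no species", call. = FALSE)
  if (any(!is.finite(measure)) || any(measure < 0))
    stop("measure values must be finite and >= 0", call. = FALSE)
  tot <- sum(measure)
  if (tot <= 0)
    stop("degenerate input: total ", measure_name, " is zero", call. = FALSE)
  nm <- names(measure)
  if (is.null(nm)) nm <- sprintf("species_%02d", seq_along(measure))
  ord <- order(-measure, nm)
  measure <- measure[ord]
  nm <- nm[ord]
  S <- length(measure)
  pts <- data.frame(x = 100 * seq_len(S) / S,
                    y = as.numeric(100 * cumsum(measure) / tot))
  structure(list(points = pts, S = S, species = nm,
                 shares = as.numeric(measure) / tot,
                 measure = measure_name),
            class = "godron_curve")
}

#' @export
print.godron_curve <- function(x, ...) {
  cat("<godron_curve> ", x$S, " species, cumulative ", x$measure, "\n",
      sep = "")
  print(utils::head(x$points, 5))
  if (x$S > 5) cat("  ... ", x$S - 5, " more points\n")
  invisible(x)
}

#' Fit a smooth polynomial through a cumulative curve
#'
#' Ordinary least squares of degree 1 or 2 on the curve's points. The
#' origin is deliberately not forced: the empirical curves of interest
#' have a large first-species share, so an unconstrained intercept is
#' needed to follow the data.
#'
#' @param curve a [build_cumulative_curve()] result.
#' @param degree 1 (line) or 2 (parabola); needs at least `degree + 1`
#'   points.
#' @return object of class `godron_fit`: list with `degree`,
#'   `coefficients` `(c0, c1, c2)` in ascending powers (`c2 = 0` for a
#'   line), and `r_squared`.
#' @export
fit_smooth_curve <- function(curve, degree = 2) {
  stopifnot(inherits(curve, "godron_curve"), degree %in% c(1, 2))
  pts <- curve$points
  if (nrow(pts) < degree + 1)
    stop("need at least ", degree + 1, " points to fit degree ", degree,
         " (have ", nrow(pts), ")", call. = FALSE)
  if (length(unique(pts$x)) < degree + 1)
    stop("singular design: too few distinct x values", call. = FALSE)
  fit <- if (degree == 2) stats::lm(y ~ x + I(x^2), data = pts)
         else stats::lm(y ~ x, data = pts)
  cf <- unname(stats::coef(fit))
  if (degree == 1) cf <- c(cf, 0)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pts$y - mean(pts$y))^2)
  r2 <- if (ss_tot <= .Machine$double.eps) {
    if (ss_res <= .Machine$double.eps) 1 else 0
  } else {
    max(0, min(1, 1 - ss_res / ss_tot))
  }
  structure(list(degree = degree, coefficients = cf, r_squared = r2),
            class = "godron_fit")
}

#' Construct a fitted curve from known coefficients
#'
#' Wraps published or externally fitted polynomial coefficients in the
#' object [intersect_with_antidiagonal()] expects, for re-analysis of
#' printed stability tables.
#'
#' @param c0,c1,c2 coefficients of `y = c0 + c1 x + c2 x^2`.
#' @param r_squared optional determination coefficient (`NA` if unknown).
#' @return a `godron_fit`.
#' @export
godron_fit <- function(c0, c1, c2 = 0, r_squared = NA_real_) {
  stopifnot(is.finite(c0), is.finite(c1), is.finite(c2))
  structure(list(degree = if (c2 == 0) 1L else 2L,
                 coefficients = c(c0, c1, c2), r_squared = r_squared),
            class = "godron_fit")
}

#' @export
print.godron_fit <- function(x, ...) {
  cf <- x$coefficients
  eq <- if (x$degree == 2)
    sprintf("y = %.4gx^2 + %.4gx + %.4g", cf[3], cf[2], cf[1])
  else sprintf("y = %.4gx + %.4g", cf[2], cf[1])
  cat("<godron_fit> ", eq, "  (R^2 = ",
      ifelse(is.na(x$r_squared), "NA", format(x$r_squared, digits = 3)),
      ")\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted curve
#' @param fit a `godron_fit`.
#' @param x numeric vector.
#' @return fitted `y` values.
#' @export
predict_curve <- function(fit, x) {
  stopifnot(inherits(fit, "godron_fit"))
  cf <- fit$coefficients
  cf[1] + cf[2] * x + cf[3] * x^2
}

#' Intersect a fitted curve with the anti-diagonal
#'
#' Solves `f(x) = 100 - x` in closed form (linear or quadratic) and
#' returns the smallest real root in `[0, 100]` together with
#' `y* = 100 - x*`. If both quadratic roots fall in range the smaller is
#' taken and a note is emitted.
#'
#' @param fit a `godron_fit`.
#' @return named numeric vector `c(x_star, y_star)`.
#' @export
intersect_with_antidiagonal <- function(fit) {
  stopifnot(inherits(fit, "godron_fit"))
  cf <- fit$coefficients
  # c2 x^2 + (c1 + 1) x + (c0 - 100) = 0
  a <- cf[3]; b <- cf[2] + 1; cc <- cf[1] - 100
  eps <- 1e-9
  if (a == 0) {
    if (b == 0) stop("curve is parallel to the anti-diagonal", call. = FALSE)
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0)
      stop("no real intersection with the anti-diagonal", call. = FALSE)
    roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  }
  in_range <- roots[roots >= -eps & roots <= 100 + eps]
  if (length(in_range) == 0L)
    stop("no intersection with the anti-diagonal inside [0, 100]",
         call. = FALSE)
  if (length(in_range) > 1L)
    message("two intersections in [0, 100]; keeping the smaller (x = ",
            format(min(in_range), digits = 6), ")")
  x_star <- min(pmax(pmin(in_range, 100), 0))
  c(x_star = x_star, y_star = 100 - x_star)
}

#' Euclidean distance to the stability point
#'
#' For an intersection on the anti-diagonal this equals
#' `sqrt(2) * |x - 20|`.
#'
#' @param point numeric `(x, y)`.
#' @param reference the stability point, default `(20, 80)`.
#' @return Euclidean distance, `>= 0`.
#' @export
distance_to_stability_point <- function(point, reference = c(20, 80)) {
  stopifnot(length(point) == 2L, length(reference) == 2L,
            all(is.finite(point)), all(is.finite(reference)))
  sqrt(sum((as.numeric(point) - as.numeric(reference))^2))
}

#' Classify a distance as stable or unstable
#'
#' Stable if and only if the distance does not exceed the threshold
#' (inclusive at the boundary).
#'
#' @param distance Euclidean distance from the stability point, `>= 0`.
#' @param threshold default [godron_threshold()].
#' @return logical: `TRUE` if stable.
#' @export
classify_stability <- function(distance, threshold = godron_threshold()) {
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be finite and >= 0", call. = FALSE)
  distance <= threshold
}

#' Full Godron stability assessment of one stratum
#'
#' Composes the pipeline: per-species coverage totals -> cumulative
#' rank-coverage curve -> least-squares polynomial -> anti-diagonal
#' intersection -> Euclidean distance from (20,80) -> stable/unstable.
#' With fewer than 3 species the quadratic is not identifiable beyond a
#' straight line and the fit falls back to degree 1.
#'
#' `paper_compat = TRUE` reproduces the arithmetic convention of printed
#' stability tables: the intersection coordinates are rounded to 2
#' decimals *before* the distance is computed, and the distance is then
#' rounded to 2 decimals. Full precision is the default for scientific
#' use.
#'
#' @param x stratum observations (data.frame with `species` and
#'   `coverage`, e.g. from [stratify()]) or a named per-species coverage
#'   vector.
#' @param degree polynomial degree, default 2.
#' @param paper_compat round as published tables do (see Details).
#' @param reference stability point, default `(20, 80)`.
#' @param threshold default [godron_threshold()].
#' @return object of class `stability_assessment`: list with `curve`,
#'   `fit`, `intersection`, `distance`, `threshold`, `reference`,
#'   `stable`, `paper_compat`.
#' @export
assess_stability <- function(x, degree = 2, paper_compat = FALSE,
                             reference = c(20, 80),
                             threshold = godron_threshold()) {
  measure <- if (is.data.frame(x)) {
    stopifnot(all(c("species", "coverage") %in% names(x)))
    tapply(x$coverage, x$species, sum)
  } else {
    x
  }
  curve <- build_cumulative_curve(measure)
  if (curve$S < 3 && degree == 2) {
    message("fewer than 3 species; falling back to a degree-1 fit")
    degree <- 1
  }
  fit <- fit_smooth_curve(curve, degree)
  p <- intersect_with_antidiagonal(fit)
  if (paper_compat) p <- round(p, 2)
  d <- distance_to_stability_point(p, reference)
  if (paper_compat) d <- round(d, 2)
  structure(list(curve = curve, fit = fit, intersection = p,
                 distance = d, threshold = threshold,
                 reference = reference,
                 stable = classify_stability(d, threshold),
                 paper_compat = paper_compat),
            class = "stability_assessment")
}

#' @export
print.stability_assessment <- function(x, ...) {
  cat("<stability_assessment>", if (x$paper_compat) " [paper_compat]" else "",
      "\n", sep = "")
  print(x$fit)
  cat(sprintf("  intersection: (%.2f, %.2f)\n",
              x$intersection[1], x$intersection[2]))
  cat(sprintf("  distance to (%g, %g): %.2f  [threshold %.3f]\n",
              x$reference[1], x$reference[2], x$distance, x$threshold))
  cat("  verdict: ", if (x$stable) "stable" else "unstable", "\n", sep = "")
  invisible(x)
}

#' Godron stability for every stratum of a dataset
#'
#' @param dataset a [community_dataset()].
#' @param degree,paper_compat passed to [assess_stability()].
#' @return data.frame with one row per stratum: `restoration_years`,
#'   `position`, `S`, `degree`, `c0`, `c1`, `c2`, `r_squared`, `x_star`,
#'   `y_star`, `distance`, `threshold`, `stable`.
#' @export
stability_table <- function(dataset, degree = 2, paper_compat = FALSE) {
  st <- strata(dataset)
  rows <- lapply(seq_len(nrow(st)), function(i) {
    obs <- stratify(dataset, st$restoration_years[i], st$position[i])
    a <- assess_stability(obs, degree = degree, paper_compat = paper_compat)
    cf <- a$fit$coefficients
    data.frame(restoration_years = st$restoration_years[i],
               position = st$position[i],
               S = a$curve$S, degree = a$fit$degree,
               c0 = cf[1], c1 = cf[2], c2 = cf[3],
               r_squared = a$fit$r_squared,
               x_star = unname(a$intersection[1]),
               y_star = unname(a$intersection[2]),
               distance = a$distance, threshold = a$threshold,
               stable = a$stable)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
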
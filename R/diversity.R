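# Importance values and alpha-diversity indices per stratum.
#
# Importance value of species i within a stratum:
#   Iv_i = (relative height_i + relative coverage_i + relative density_i) / 3
# where each relative component is the species' stratum-level aggregate
# divided by the stratum total. Aggregation across a stratum's quadrats:
# mean for height, sum for coverage and density (sums preserve relative
# proportions; the mean keeps height on a per-plant scale).

#' Species importance values for a stratum
#'
#' @param obs data.frame of species observations for one stratum
#'   (columns `species`, `height`, `coverage`, `density`; typically from
#'   [stratify()]). Multiple quadrats per species are aggregated: mean
#'   height, summed coverage, summed density.
#' @return data.frame with columns `species`, `relative_height`,
#'   `relative_coverage`, `relative_density`, `Iv`, sorted by `Iv`
#'   descending (ties broken by species name). The `Iv` column sums to 1.
#' @export
importance_values <- function(obs) {
  obs <- as.data.frame(obs)
  stopifnot(all(c("species", "height", "coverage", "density") %in% names(obs)))
  if (nrow(obs) == 0L) stop("empty stratum: no observations", call. = FALSE)
  sp <- sort(unique(obs$species))
  agg <- data.frame(
    species  = sp,
    height   = vapply(sp, function(s) mean(obs$height[obs$species == s]), 0),
    coverage = vapply(sp, function(s) sum(obs$coverage[obs$species == s]), 0),
    density  = vapply(sp, function(s) sum(obs$density[obs$species == s]), 0)
  )
  for (comp in c("height", "coverage", "density")) {
    tot <- sum(agg[[comp]])
    if (!is.finite(tot) || tot <= 0)
      stop("degenerate stratum: total ", comp, " is zero", call. = FALSE)
    agg[[paste0("relative_", comp)]] <- agg[[comp]] / tot
  }
  agg$Iv <- (agg$relative_height + agg$relative_coverage +
               agg$relative_density) / 3
  agg <- agg[order(-agg$Iv, agg$species), ]
  rownames(agg) <- NULL
  agg[c("species", "relative_height", "relative_coverage",
        "relative_density", "Iv")]
}

#' Normalise per-species weights to proportions
#'
#' Computes `P_i = N_i / N`. Zero-weight species are dropped with a
#' message (a species that contributes nothing carries no diversity
#' information).
#'
#' @param weights non-negative numeric vector, optionally named; at least
#'   one weight must be positive.
#' @return numeric vector of proportions summing to 1.
#' @export
proportions <- function(weights) {
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and >= 0", call. = FALSE)
  if (all(weights == 0))
    stop("degenerate input: all weights are zero", call. = FALSE)
  if (any(weights == 0)) {
    message("dropping ", sum(weights == 0), " zero-weight species")
    weights <- weights[weights > 0]
  }
  weights / sum(weights)
}

#' Margalef's richness index
#'
#' `R = (S - 1) / ln N`, where `S` is the species count and `N` the total
#' number of individuals. A monoculture has `R = 0` by the zero numerator.
#'
#' @param S integer species count, `>= 1`.
#' @param N total individual count, `> 1` whenever `S >= 2`.
#' @return richness index.
#' @export
margalef_richness <- function(S, N) {
  stopifnot(length(S) == 1L, length(N) == 1L, S >= 1)
  if (S == 1L) return(0)
  if (!is.finite(N) || N <= 1)
    stop("Margalef richness needs N > 1 (ln N must be positive); got N = ",
         N, call. = FALSE)
  (S - 1) / log(N)
}

.check_proportions <- function(P, tol = 1e-6) {
  if (any(!is.finite(P)) || any(P < 0))
    stop("proportions must be finite and >= 0", call. = FALSE)
  if (abs(sum(P) - 1) > tol)
    stop("proportions must sum to 1 (got ", format(sum(P)), ")",
         call. = FALSE)
}

#' Simpson's dominance diversity index
#'
#' `D = 1 - sum(P_i^2)`: the probability that two random draws are
#' different species. Bounded by `1 - 1/S`.
#'
#' @param P proportions summing to 1.
#' @return Simpson index in `[0, 1)`.
#' @export
simpson_index <- function(P) {
  .check_proportions(P)
  1 - sum(P^2)
}

#' Shannon-Wiener diversity index
#'
#' `H = -sum(P_i ln P_i)` (natural logarithm); zero proportions
#' contribute nothing. Bounded by `ln S`.
#'
#' @param P proportions summing to 1.
#' @return Shannon-Wiener index, `>= 0`.
#' @export
shannon_index <- function(P) {
  .check_proportions(P)
  P <- P[P > 0]
  -sum(P * log(P))
}

#' Pielou's evenness index
#'
#' `E = H / ln S` for `S >= 2`. For a monoculture (`S = 1`) the ratio is
#' 0/0 and has no canonical value: `NA` is returned with a warning, and
#' result tables print it as NA.
#'
#' @param H Shannon-Wiener index.
#' @param S integer species count.
#' @return evenness in `[0, 1]`, or `NA` when `S = 1`.
#' @export
pielou_evenness <- function(H, S) {
  stopifnot(length(H) == 1L, length(S) == 1L, S >= 1, H >= -1e-12)
  if (S == 1L) {
    warning("Pielou evenness is undefined for a single species; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  if (H > log(S) + 1e-9)
    stop("inconsistent input: H = ", format(H), " exceeds ln S = ",
         format(log(S)), call. = FALSE)
  min(H / log(S), 1)
}

#' Alpha-diversity profile of one stratum
#'
#' Composes the index functions over a stratum's observations. The
#' proportions `P_i` default to species importance values (`weight_mode =
#' "importance_value"`): importance values are the study's stand-in for
#' individual counts where clonal herbs make counting ambiguous. With
#' `weight_mode = "abundance"` the `P_i` come from abundance counts
#' (falling back to density when no abundance column is present).
#'
#' `N` for Margalef richness is always an individual total — summed
#' abundance when available, otherwise total density rounded to the
#' nearest integer — never the importance-value total (which is 1 and
#' would make `ln N` meaningless).
#'
#' @param obs stratum observations (see [importance_values()]).
#' @param weight_mode `"importance_value"` (default) or `"abundance"`.
#' @return one-row data.frame: `S`, `N`, `R`, `D`, `H`, `E`,
#'   `weight_mode`.
#' @export
diversity_profile <- function(obs,
                              weight_mode = c("importance_value",
                                              "abundance")) {
  weight_mode <- match.arg(weight_mode)
  obs <- as.data.frame(obs)
  iv <- importance_values(obs)
  S <- nrow(iv)

  counts <- if ("abundance" %in% names(obs) && !anyNA(obs$abundance)) {
    tapply(obs$abundance, obs$species, sum)
  } else {
    tapply(obs$density, obs$species, sum)
  }
  N <- round(sum(counts))

  P <- if (weight_mode == "importance_value") {
    stats::setNames(iv$Iv, iv$species)
  } else {
    proportions(as.numeric(counts))
  }

  H <- shannon_index(P)
  D <- simpson_index(P)
  E <- if (S == 1L) suppressWarnings(pielou_evenness(H, S))
       else pielou_evenness(H, S)
  R <- if (S == 1L) 0 else margalef_richness(S, N)

  data.frame(S = S, N = N, R = R, D = D, H = H, E = E,
             weight_mode = weight_mode)
}

#' Diversity profiles for every stratum of a dataset
#'
#' @param dataset a [community_dataset()].
#' @param weight_mode passed to [diversity_profile()].
#' @param position_wildcard if `TRUE`, also include per-age profiles
#'   pooled over positions (`position = "all"`).
#' @return data.frame with one row per stratum: `restoration_years`,
#'   `position`, then the [diversity_profile()] columns.
#' @export
diversity_table <- function(dataset,
                            weight_mode = c("importance_value", "abundance"),
                            position_wildcard = FALSE) {
  weight_mode <- match.arg(weight_mode)
  st <- strata(dataset)
  if (position_wildcard) {
    extra <- data.frame(restoration_years = unique(st$restoration_years),
                        position = "all")
    st <- rbind(st, extra)
  }
  rows <- lapply(seq_len(nrow(st)), function(i) {
    obs <- stratify(dataset, st$restoration_years[i], st$position[i])
    cbind(st[i, , drop = FALSE], diversity_profile(obs, weight_mode))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Importance-value table for every stratum of a dataset
#'
#' @inheritParams diversity_table
#' @return data.frame: `restoration_years`, `position`, then the
#'   [importance_values()] columns.
#' @export
importance_table <- function(dataset) {
  st <- strata(dataset)
  rows <- lapply(seq_len(nrow(st)), function(i) {
    obs <- stratify(dataset, st$restoration_years[i], st$position[i])
    cbind(st[i, , drop = FALSE], importance_values(obs), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
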
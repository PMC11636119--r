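# Seeded generator of synthetic quadrat-community and soil tables with
# the statistical structure a sandy-land restoration chronosequence
# produces, so every pipeline stage is testable without field data.
#
# Community model: within a stratum the S(year) species follow a
# geometric (niche-preemption) rank-abundance with ratio k: coverage
# shares proportional to k^(i-1), renormalised. Larger k means a more
# even community; k rises with restoration age (dominance decays).
# Richness rises with age and is depressed under the crown (canopy
# shading excludes part of the species pool), a contrast that shrinks
# with age. The pool is nested, so late-successional species ids only
# appear in older strata.
#
# Soil model: multiplicative trend surface mean(year, layer, position) =
# base * year_factor * layer_factor * position_factor for SOM/AN/TP with
# mean-corrected lognormal noise, and an additive year trend with normal
# noise for pH. The 45-yr/control SOM and AN factors are the calibration
# targets 3.5008 and 5.4243 (i.e. +250.08 % and +442.43 %); TP is flat
# across years but elevated in the 0-20 cm layer and under the crown.

#' Configuration of the synthetic chronosequence generator
#'
#' Defaults encode the study conditions the generator emulates: ages
#' 0/13/25/45 with richness 3/12/16/21, two canopy positions with three
#' 0.25 m^2 quadrats each, geometric rank-abundance whose evenness ratio
#' rises with age, an under-crown richness depression decaying with age,
#' and soil trends with SOM and AN 45-yr/control ratios 3.5008 and
#' 5.4243, decreasing pH, and TP concentrated in the 0-20 cm layer.
#'
#' @param seed integer RNG seed; the same config and seed always yield
#'   identical tables.
#' @param years restoration ages (first entry is the control).
#' @param positions canopy positions of the vegetation quadrats.
#' @param quadrats_per_stratum quadrat replication per stratum.
#' @param richness_by_year named integer vector (names = years),
#'   non-decreasing with age.
#' @param evenness_by_year named vector of geometric ratios k in (0,1);
#'   coverage shares are proportional to `k^(i-1)`.
#' @param under_crown_contrast initial relative richness depression under
#'   the crown (0.15 = 15 % fewer species at year 0).
#' @param contrast_halflife age (years) over which the under-crown
#'   contrast halves.
#' @param total_cover_by_year named vector: expected total vegetation
#'   cover (percent) per quadrat.
#' @param total_density_by_year named vector: expected individuals per
#'   quadrat.
#' @param quadrat_area quadrat area in m^2.
#' @param soil_positions canopy positions of the soil profiles (the soil
#'   survey also samples the crown edge).
#' @param soil_reps composite samples per (year, layer, position) cell.
#' @param soil_base named list: control-level means of `pH`, `SOM`
#'   (g/kg), `AN` (mg/kg), `TP` (g/kg).
#' @param som_year_factors,an_year_factors,tp_year_factors named vectors
#'   of multiplicative year effects (control = 1).
#' @param ph_year_offsets named vector of additive pH year effects
#'   (control = 0), decreasing with age.
#' @param layer_factors list of per-layer multiplicative effects for
#'   `SOM`, `AN`, `TP` (names `d0_20`, `d20_40`, `d40_60`).
#' @param position_factors list of per-position multiplicative effects.
#' @param noise list of noise scales: lognormal sigma for `coverage`,
#'   `height`, `density`, `soil`; normal sd for `pH`.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(
    seed = 1L,
    years = c(0L, 13L, 25L, 45L),
    positions = c("under_crown", "outside_crown"),
    quadrats_per_stratum = 3L,
    richness_by_year = c("0" = 3L, "13" = 12L, "25" = 16L, "45" = 21L),
    evenness_by_year = c("0" = 0.55, "13" = 0.74, "25" = 0.78, "45" = 0.82),
    under_crown_contrast = 0.15,
    contrast_halflife = 15,
    total_cover_by_year = c("0" = 15, "13" = 45, "25" = 60, "45" = 75),
    total_density_by_year = c("0" = 12, "13" = 40, "25" = 55, "45" = 70),
    quadrat_area = 0.25,
    soil_positions = c("under_crown", "crown_edge", "outside_crown"),
    soil_reps = 3L,
    soil_base = list(pH = 8.9, SOM = 2.2, AN = 11.5, TP = 0.32),
    som_year_factors = c("0" = 1, "13" = 1.9, "25" = 2.7, "45" = 3.5008),
    an_year_factors = c("0" = 1, "13" = 2.5, "25" = 4.0, "45" = 5.4243),
    tp_year_factors = c("0" = 1, "13" = 1, "25" = 1, "45" = 1),
    ph_year_offsets = c("0" = 0, "13" = -0.35, "25" = -0.55, "45" = -0.8),
    layer_factors = list(
      SOM = c(d0_20 = 1.25, d20_40 = 0.95, d40_60 = 0.80),
      AN  = c(d0_20 = 1.10, d20_40 = 0.98, d40_60 = 0.92),
      TP  = c(d0_20 = 1.30, d20_40 = 0.95, d40_60 = 0.90)),
    position_factors = list(
      SOM = c(under_crown = 1.12, crown_edge = 1.04, outside_crown = 1.00),
      AN  = c(under_crown = 1.10, crown_edge = 1.03, outside_crown = 1.00),
      TP  = c(under_crown = 1.08, crown_edge = 1.00, outside_crown = 1.00)),
    noise = list(coverage = 0.25, height = 0.15, density = 0.30,
                 soil = 0.20, pH = 0.08)) {
  cfg <- list(seed = as.integer(seed), years = as.integer(years),
              positions = positions,
              quadrats_per_stratum = as.integer(quadrats_per_stratum),
              richness_by_year = richness_by_year,
              evenness_by_year = evenness_by_year,
              under_crown_contrast = under_crown_contrast,
              contrast_halflife = contrast_halflife,
              total_cover_by_year = total_cover_by_year,
              total_density_by_year = total_density_by_year,
              quadrat_area = quadrat_area,
              soil_positions = soil_positions, soil_reps = as.integer(soil_reps),
              soil_base = soil_base,
              som_year_factors = som_year_factors,
              an_year_factors = an_year_factors,
              tp_year_factors = tp_year_factors,
              ph_year_offsets = ph_year_offsets,
              layer_factors = layer_factors,
              position_factors = position_factors,
              noise = noise)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  yrs <- as.character(cfg$years)
  for (fld in c("richness_by_year", "evenness_by_year",
                "total_cover_by_year", "total_density_by_year",
                "som_year_factors", "an_year_factors", "tp_year_factors",
                "ph_year_offsets")) {
    missing <- setdiff(yrs, names(cfg[[fld]]))
    if (length(missing))
      stop(fld, " lacks entries for year(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  rich <- cfg$richness_by_year[yrs]
  if (any(diff(rich) < 0))
    stop("richness_by_year must be non-decreasing with age", call. = FALSE)
  k <- cfg$evenness_by_year[yrs]
  if (any(k <= 0 | k >= 1))
    stop("evenness ratios must lie in (0, 1)", call. = FALSE)
  if (cfg$under_crown_contrast < 0)
    stop("under_crown_contrast must be >= 0", call. = FALSE)
  if (any(unlist(cfg$soil_base) <= 0) ||
      any(c(cfg$som_year_factors, cfg$an_year_factors,
            cfg$tp_year_factors) <= 0))
    stop("soil bases and year factors must be > 0", call. = FALSE)
  if (any(unlist(cfg$noise) < 0)) stop("noise scales must be >= 0",
                                       call. = FALSE)
  invisible(cfg)
}

#' Geometric (niche-preemption) coverage shares
#'
#' Shares proportional to `k^(i-1)` for ranks `i = 1..S`, renormalised to
#' sum to 1. `k = 0.5, S = 3` gives `(4/7, 2/7, 1/7)`. Larger `k` is more
#' even; the dominant's share decreases strictly as `k` increases.
#'
#' @param k geometric ratio in (0, 1\].
#' @param S number of species.
#' @return numeric vector of `S` shares summing to 1.
#' @export
geometric_shares <- function(k, S) {
  stopifnot(k > 0, k <= 1, S >= 1)
  s <- k^(seq_len(S) - 1)
  s / sum(s)
}

# under-crown contrast at a given age, halving every contrast_halflife yr
.contrast_at <- function(cfg, year) {
  cfg$under_crown_contrast * 2^(-year / cfg$contrast_halflife)
}

# effective richness for a stratum: canopy shading excludes a fraction of
# the species pool under the crown, a gap that closes with age
.S_effective <- function(cfg, year, position) {
  S <- unname(cfg$richness_by_year[as.character(year)])
  if (position == "under_crown")
    S <- min(S, max(1L, as.integer(round(S * (1 - .contrast_at(cfg, year))))))
  S
}

# mean-corrected lognormal multiplier: expectation is exactly 1
.lnoise <- function(n, sigma) {
  if (sigma == 0) rep(1, n) else exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

.species_pool <- function(S_max) {
  pool <- sprintf("species_%02d", seq_len(S_max))
  # late-successional tail of the pool is annual; the control community
  # and early strata (low ids) are purely perennial
  life <- rep("perennial_herb", S_max)
  if (S_max >= 5) life[seq(S_max - min(3, S_max - 1), S_max)] <- "annual_herb"
  data.frame(species = pool, life_form = life)
}

#' Generate a synthetic quadrat community table
#'
#' @param config a [synth_config()].
#' @return list with `community` (long data.frame consumable by
#'   [community_dataset()] via its columns) and `manifest` (ground truth:
#'   per-stratum species, true shares, effective evenness ratio).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  pool <- .species_pool(max(cfg$richness_by_year))
  rows <- list()
  manifest <- list()
  for (year in cfg$years) {
    for (pos in cfg$positions) {
      S <- .S_effective(cfg, year, pos)
      k <- unname(cfg$evenness_by_year[as.character(year)])
      shares <- geometric_shares(k, S)
      sp <- pool$species[seq_len(S)]
      life <- pool$life_form[seq_len(S)]
      total_cov <- unname(cfg$total_cover_by_year[as.character(year)])
      total_den <- unname(cfg$total_density_by_year[as.character(year)])
      # expected height proportional to share: dominants are taller, and
      # with zero noise every importance-value component then equals the
      # geometric share exactly (clean parameter recovery)
      base_height <- 150 * shares
      stratum_key <- sprintf("Y%02d_%s", year,
                             c(under_crown = "UC", crown_edge = "CE",
                               outside_crown = "OC")[pos])
      for (q in seq_len(cfg$quadrats_per_stratum)) {
        qid <- sprintf("%s_Q%d", stratum_key, q)
        cov <- shares * total_cov * .lnoise(S, cfg$noise$coverage)
        cov <- pmin(cov, 100)
        den <- shares * total_den * .lnoise(S, cfg$noise$density)
        hei <- base_height * .lnoise(S, cfg$noise$height)
        rows[[length(rows) + 1L]] <- data.frame(
          quadrat_id = qid, restoration_years = year, position = pos,
          area = cfg$quadrat_area, species = sp, life_form = life,
          height = hei, coverage = cov, density = den,
          abundance = pmax(1L, as.integer(round(den))))
      }
      manifest[[sprintf("%d_%s", year, pos)]] <- list(
        restoration_years = year, position = pos, S = S,
        k_effective = k, shares = shares, species = sp,
        total_cover = total_cov, total_density = total_den)
    }
  }
  community <- do.call(rbind, rows)
  rownames(community) <- NULL
  list(community = community, manifest = manifest)
}

#' Generate a synthetic soil sample table
#'
#' @param config a [synth_config()].
#' @return list with `soil` (data.frame consumable by [soil_summary()])
#'   and `manifest` (the noise-free trend means per cell).
#' @export
generate_soil <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed + 1L)
  layers <- c("d0_20", "d20_40", "d40_60")
  rows <- list()
  trend <- list()
  for (year in cfg$years) {
    yc <- as.character(year)
    for (layer in layers) {
      for (pos in cfg$soil_positions) {
        mu <- c(
          pH  = cfg$soil_base$pH + unname(cfg$ph_year_offsets[yc]),
          SOM = cfg$soil_base$SOM * unname(cfg$som_year_factors[yc]) *
            unname(cfg$layer_factors$SOM[layer]) *
            unname(cfg$position_factors$SOM[pos]),
          AN  = cfg$soil_base$AN * unname(cfg$an_year_factors[yc]) *
            unname(cfg$layer_factors$AN[layer]) *
            unname(cfg$position_factors$AN[pos]),
          TP  = cfg$soil_base$TP * unname(cfg$tp_year_factors[yc]) *
            unname(cfg$layer_factors$TP[layer]) *
            unname(cfg$position_factors$TP[pos]))
        n <- cfg$soil_reps
        rows[[length(rows) + 1L]] <- data.frame(
          restoration_years = year, depth_layer = layer, position = pos,
          pH  = mu[["pH"]] + stats::rnorm(n, 0, cfg$noise$pH),
          SOM = mu[["SOM"]] * .lnoise(n, cfg$noise$soil),
          AN  = mu[["AN"]] * .lnoise(n, cfg$noise$soil),
          TP  = mu[["TP"]] * .lnoise(n, cfg$noise$soil))
        trend[[sprintf("%d_%s_%s", year, layer, pos)]] <- as.list(mu)
      }
    }
  }
  soil <- do.call(rbind, rows)
  rownames(soil) <- NULL
  list(soil = soil, manifest = trend)
}

#' Generate a synthetic dataset in memory
#'
#' Convenience wrapper assembling the community and soil generators into
#' a validated [community_dataset()], with the ground-truth manifests
#' attached as attribute `"manifest"`.
#'
#' @param config a [synth_config()].
#' @return a `community_dataset` with a soil table.
#' @export
synth_dataset <- function(config) {
  com <- generate_community(config)
  soi <- generate_soil(config)
  tab <- com$community
  quadrats <- unique(tab[c("quadrat_id", "restoration_years", "position",
                           "area")])
  obs <- tab[setdiff(names(tab), c("restoration_years", "position", "area"))]
  d <- community_dataset(quadrats, obs, soil = soi$soil)
  attr(d, "manifest") <- list(community = com$manifest,
                              soil_trend = soi$manifest)
  d
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes `community.csv`, `soil.csv` and `manifest.yaml` (config echo
#' plus per-stratum ground truth) into `out_dir`. The files round-trip
#' through [read_community_table()] and [read_soil_table()] unchanged.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a named list of the three file paths.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  com <- generate_community(config)
  soi <- generate_soil(config)
  p_com <- file.path(out_dir, "community.csv")
  p_soil <- file.path(out_dir, "soil.csv")
  p_man <- file.path(out_dir, "manifest.yaml")
  com$community$height <- signif(com$community$height, 10)
  com$community$coverage <- signif(com$community$coverage, 10)
  com$community$density <- signif(com$community$density, 10)
  utils::write.csv(com$community, p_com, row.names = FALSE, quote = TRUE)
  utils::write.csv(soi$soil, p_soil, row.names = FALSE, quote = TRUE)
  manifest <- list(config = unclass(config),
                   community = com$manifest, soil_trend = soi$manifest)
  yaml::write_yaml(manifest, p_man, precision = 12)
  invisible(list(community = p_com, soil = p_soil, manifest = p_man))
}

#' Coverage shares calibrated to a target stability point
#'
#' Constructs a per-species coverage vector whose full Godron assessment
#' ([assess_stability()], degree 2) reproduces a requested anti-diagonal
#' intersection *exactly*: the cumulative points are placed on a concave
#' quadratic through (100, 100) that meets `y = 100 - x` at `x_star`, so
#' the least-squares fit recovers that quadratic and the pipeline returns
#' the requested stability point and distance.
#'
#' A cumulative-coverage curve is non-decreasing, concave under the
#' dominance-ranked ordering, and ends at (100, 100), which bounds the
#' feasible curvature twice over: the quadratic must still be rising at
#' x = 100 (else the implied tail shares go negative) and its intercept
#' must stay positive (else the implied first share does). Both bounds
#' force `x_star < 50` — a ranked cumulative curve always sits on or
#' above the diagonal. `curvature_frac` positions the curvature at that
#' fraction of the tighter bound.
#'
#' @param x_star target intersection abscissa in (0, 50); the published
#'   45-yr outside-crown stability point is `x_star = 29.88`.
#' @param S number of species.
#' @param curvature_frac fraction in \[0, 1) of the maximal feasible
#'   curvature (default 0.9).
#' @return named coverage vector (percent, summing to 100) in rank order.
#' @export
shares_for_stability_point <- function(x_star, S, curvature_frac = 0.9) {
  stopifnot(S >= 3, curvature_frac >= 0, curvature_frac < 1)
  if (x_star <= 0 || x_star >= 50)
    stop("infeasible target: a ranked cumulative curve lies on or above ",
         "the diagonal, so the stability point must satisfy 0 < x_star < 50",
         call. = FALSE)
  # curvature bounds: still rising at x = 100; positive intercept
  lb_slope <- -x_star / (100 - x_star)^2
  lb_intercept <- -(100 - 2 * x_star) / ((100 - x_star) * x_star)
  c2 <- curvature_frac * max(lb_slope, lb_intercept)
  c1 <- x_star / (100 - x_star) - (100 + x_star) * c2
  c0 <- 100 - 100 * c1 - 1e4 * c2
  x <- 100 * seq_len(S) / S
  y <- c0 + c1 * x + c2 * x^2
  shares <- diff(c(0, y))
  if (any(shares <= 0) || any(diff(shares) > 1e-9))
    stop("infeasible target: implied shares are not positive decreasing",
         call. = FALSE)
  stats::setNames(shares, sprintf("species_%02d", seq_len(S)))
}
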
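# shared fixture builders (all fixtures are generated in code)

# a minimal stratum observation table
make_obs <- function(species, height, coverage, density,
                     quadrat_id = "Q1", abundance = NULL) {
  df <- data.frame(quadrat_id = quadrat_id, species = species,
                   life_form = "perennial_herb", height = height,
                   coverage = coverage, density = density)
  if (!is.null(abundance)) df$abundance <- abundance
  df
}

# a tiny valid dataset: one quadrat, n species
make_dataset <- function(n = 2, years = 13, position = "outside_crown") {
  obs <- make_obs(sprintf("sp%02d", seq_len(n)),
                  height = seq(10, 30, length.out = n),
                  coverage = seq(40, 10, length.out = n),
                  density = rep(5, n))
  quadrats <- data.frame(quadrat_id = "Q1", restoration_years = years,
                         position = position, area = 0.25)
  community_dataset(quadrats, obs)
}

# write a long community table to a temp CSV, returning the path
write_community_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

# a single-quadrat long table ready for read_community_table()
long_row <- function(coverage = 30, quadrat_id = "Q1", species = "sp01") {
  data.frame(quadrat_id = quadrat_id, restoration_years = 13,
             position = "outside_crown", area = 0.25, species = species,
             life_form = "perennial_herb", height = 20,
             coverage = coverage, density = 4, abundance = 4L)
}

# independent polynomial least squares via the normal equations,
# kept deliberately separate from the package's lm-based fit
normal_equations_fit <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# independent root bracketing for f(x) = 100 - x on [0, 100]
bisection_intersection <- function(c0, c1, c2, tol = 1e-9) {
  g <- function(x) c0 + c1 * x + c2 * x^2 - (100 - x)
  xs <- seq(0, 100, length.out = 4001)
  gs <- g(xs)
  i <- which(gs[-1] * gs[-length(gs)] <= 0)[1]
  if (is.na(i)) stop("no sign change on [0, 100]")
  stats::uniroot(g, c(xs[i], xs[i + 1]), tol = tol)$root
}
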
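# Data model, readers and validation for quadrat community tables and
# soil tables, plus stratification by restoration age and canopy position.

#' Canopy positions recognised by the data model
#' @export
CANOPY_POSITIONS <- c("under_crown", "crown_edge", "outside_crown")

#' Life forms recognised by the data model
#' @export
LIFE_FORMS <- c("annual_herb", "perennial_herb", "shrub")

SOIL_LAYERS <- c("d0_20", "d20_40", "d40_60")

# required columns of the long community table; abundance is optional
.community_cols <- c("quadrat_id", "restoration_years", "position", "area",
                     "species", "life_form", "height", "coverage", "density")
.soil_cols <- c("restoration_years", "depth_layer", "position",
                "pH", "SOM", "AN", "TP")

.stop_field <- function(rows, field, why) {
  stop(sprintf("invalid %s in row(s) %s: %s", field,
               paste(rows, collapse = ", "), why), call. = FALSE)
}

#' Assemble a validated community dataset
#'
#' Bundles quadrat metadata, species observations and (optionally) soil
#' samples into a single object, checking the field-level invariants:
#' coverage in \[0,100\] percent, positive heights, non-negative
#' densities, recognised positions and life forms, unique
#' (quadrat, species) pairs, and that every observation's `quadrat_id`
#' resolves to a quadrat.
#'
#' Coverage is stored as a percentage of quadrat area in \[0, 100\]; a
#' per-unit value in \[0, 1\] is *not* rescaled — out-of-convention input
#' should be fixed upstream, not guessed at.
#'
#' @param quadrats data.frame with columns `quadrat_id`,
#'   `restoration_years`, `position`, `area` (m^2).
#' @param observations data.frame with columns `quadrat_id`, `species`,
#'   `life_form`, `height` (cm), `coverage` (percent), `density`
#'   (individuals per quadrat) and optionally `abundance` (integer count).
#' @param soil optional data.frame of soil samples (see
#'   [read_soil_table()]).
#' @return an object of class `community_dataset`: a list with elements
#'   `quadrats`, `observations`, `soil`.
#' @export
community_dataset <- function(quadrats, observations, soil = NULL) {
  quadrats <- as.data.frame(quadrats)
  observations <- as.data.frame(observations)
  missing_q <- setdiff(c("quadrat_id", "restoration_years", "position", "area"),
                       names(quadrats))
  if (length(missing_q))
    stop("quadrat table lacks column(s): ", paste(missing_q, collapse = ", "),
         call. = FALSE)
  obs_req <- setdiff(.community_cols,
                     c("restoration_years", "position", "area"))
  missing_o <- setdiff(obs_req, names(observations))
  if (length(missing_o))
    stop("observation table lacks column(s): ",
         paste(missing_o, collapse = ", "), call. = FALSE)

  if (anyDuplicated(quadrats$quadrat_id))
    stop("duplicated quadrat_id in quadrat table", call. = FALSE)
  bad <- which(!(quadrats$position %in% CANOPY_POSITIONS))
  if (length(bad)) .stop_field(bad, "position",
                               paste("must be one of",
                                     paste(CANOPY_POSITIONS, collapse = "/")))
  bad <- which(!is.finite(quadrats$restoration_years) |
                 quadrats$restoration_years < 0)
  if (length(bad)) .stop_field(bad, "restoration_years", "must be >= 0")
  bad <- which(!is.finite(quadrats$area) | quadrats$area <= 0)
  if (length(bad)) .stop_field(bad, "area", "must be > 0")

  o <- observations
  bad <- which(!(o$life_form %in% LIFE_FORMS))
  if (length(bad)) .stop_field(bad, "life_form",
                               paste("must be one of",
                                     paste(LIFE_FORMS, collapse = "/")))
  bad <- which(!is.finite(o$height) | o$height <= 0)
  if (length(bad)) .stop_field(bad, "height", "must be > 0 (cm)")
  bad <- which(!is.finite(o$coverage) | o$coverage < 0 | o$coverage > 100)
  if (length(bad)) .stop_field(bad, "coverage", "must lie in [0, 100] percent")
  bad <- which(!is.finite(o$density) | o$density < 0)
  if (length(bad)) .stop_field(bad, "density", "must be >= 0")
  if ("abundance" %in% names(o)) {
    bad <- which(!is.na(o$abundance) &
                   (o$abundance < 0 | o$abundance != round(o$abundance)))
    if (length(bad)) .stop_field(bad, "abundance",
                                 "must be a non-negative integer count")
  }
  dup <- which(duplicated(o[c("quadrat_id", "species")]))
  if (length(dup)) .stop_field(dup, "(quadrat_id, species)",
                               "pair duplicated within the dataset")
  dangling <- setdiff(unique(o$quadrat_id), quadrats$quadrat_id)
  if (length(dangling))
    stop("observation(s) reference unknown quadrat_id: ",
         paste(dangling, collapse = ", "), call. = FALSE)

  if (!is.null(soil)) soil <- validate_soil(soil)

  structure(list(quadrats = quadrats, observations = observations,
                 soil = soil),
            class = "community_dataset")
}

#' @export
print.community_dataset <- function(x, ...) {
  yrs <- sort(unique(x$quadrats$restoration_years))
  cat("<community_dataset>\n")
  cat("  quadrats:     ", nrow(x$quadrats), "\n")
  cat("  observations: ", nrow(x$observations), " (",
      length(unique(x$observations$species)), " species)\n", sep = "")
  cat("  restoration years: ", paste(yrs, collapse = ", "), "\n")
  cat("  soil samples: ", if (is.null(x$soil)) 0 else nrow(x$soil), "\n")
  invisible(x)
}

validate_soil <- function(soil) {
  soil <- as.data.frame(soil)
  missing_s <- setdiff(.soil_cols, names(soil))
  if (length(missing_s))
    stop("soil table lacks column(s): ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  bad <- which(!(soil$depth_layer %in% SOIL_LAYERS))
  if (length(bad)) .stop_field(bad, "depth_layer",
                               paste("must be one of",
                                     paste(SOIL_LAYERS, collapse = "/")))
  bad <- which(!(soil$position %in% CANOPY_POSITIONS))
  if (length(bad)) .stop_field(bad, "position", "unknown canopy position")
  bad <- which(!is.finite(soil$pH) | soil$pH <= 0 | soil$pH >= 14)
  if (length(bad)) .stop_field(bad, "pH", "must lie in (0, 14)")
  for (v in c("SOM", "AN", "TP")) {
    bad <- which(!is.finite(soil[[v]]) | soil[[v]] < 0)
    if (length(bad)) .stop_field(bad, v, "must be >= 0")
  }
  soil
}

.read_delim_checked <- function(path, required, optional = character(),
                                sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE, encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra))
    warning(sprintf("%s: ignoring unknown column(s): %s", basename(path),
                    paste(extra, collapse = ", ")), call. = FALSE)
  df[intersect(c(required, optional), names(df))]
}

#' Read a long-format quadrat community table
#'
#' Reads an RFC-4180-style delimited text file with one row per species
#' observation within a quadrat, and returns a validated
#' [community_dataset()]. Required columns (renameable via `columns`):
#' `quadrat_id`, `restoration_years`, `position`, `area`, `species`,
#' `life_form`, `height`, `coverage`, `density`; `abundance` is optional.
#' Quadrat-level fields must be consistent across the rows of a quadrat.
#' Unknown columns are dropped with a warning; numeric cells that fail to
#' parse and out-of-range values raise errors naming the row and field.
#'
#' @param path path to a delimited text file with a header row.
#' @param columns named character vector mapping the canonical column
#'   names above to the names used in the file, e.g.
#'   `c(species = "taxon")`. Unmapped names are taken as-is.
#' @param sep field delimiter (default comma).
#' @return a `community_dataset` (with no soil table).
#' @export
read_community_table <- function(path, columns = character(), sep = ",") {
  canonical <- c(.community_cols, "abundance")
  file_names <- canonical
  if (length(columns)) {
    unknown <- setdiff(names(columns), canonical)
    if (length(unknown))
      stop("column mapping refers to unknown field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    file_names[match(names(columns), canonical)] <- unname(columns)
  }
  has_abund_map <- file_names[length(file_names)]
  df <- .read_delim_checked(path, required = file_names[seq_len(9)],
                            optional = has_abund_map, sep = sep)
  names(df) <- canonical[match(names(df), file_names)]

  for (v in c("restoration_years", "area", "height", "coverage", "density",
              if ("abundance" %in% names(df)) "abundance")) {
    x <- df[[v]]
    if (!is.numeric(x)) {
      parsed <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(parsed) & !is.na(x) & nzchar(trimws(x)))
      if (length(bad))
        stop(sprintf("%s: unparseable numeric value for '%s' at data row(s) %s",
                     basename(path), v, paste(bad, collapse = ", ")),
             call. = FALSE)
      df[[v]] <- parsed
    }
  }

  qcols <- c("quadrat_id", "restoration_years", "position", "area")
  quadrats <- unique(df[qcols])
  if (anyDuplicated(quadrats$quadrat_id))
    stop("inconsistent restoration_years/position/area within a quadrat_id",
         call. = FALSE)
  obs <- df[setdiff(names(df), c("restoration_years", "position", "area"))]
  community_dataset(quadrats, obs)
}

#' Read a soil sample table
#'
#' One row per depth-layer composite sample: `restoration_years`,
#' `depth_layer` (`d0_20`/`d20_40`/`d40_60`), `position`, `pH`, `SOM`
#' (g/kg), `AN` (mg/kg), `TP` (g/kg).
#'
#' @inheritParams read_community_table
#' @return a validated data.frame of soil samples.
#' @export
read_soil_table <- function(path, sep = ",") {
  df <- .read_delim_checked(path, required = .soil_cols, sep = sep)
  validate_soil(df)
}

#' Select the observations of one stratum
#'
#' A stratum is one restoration age crossed with one canopy position;
#' `position = "all"` is a wildcard matching every position. The returned
#' observations carry their quadrat's `restoration_years` and `position`
#' for convenience.
#'
#' @param dataset a [community_dataset()].
#' @param restoration_years integer restoration age; must be present in
#'   the dataset.
#' @param position one of `r paste0('"', CANOPY_POSITIONS, '"', collapse = ", ")`
#'   or `"all"`.
#' @return data.frame of species observations (possibly empty).
#' @export
stratify <- function(dataset, restoration_years, position = "all") {
  stopifnot(inherits(dataset, "community_dataset"))
  q <- dataset$quadrats
  if (!restoration_years %in% q$restoration_years)
    stop("restoration age ", restoration_years, " not present in dataset",
         call. = FALSE)
  if (!position %in% c(CANOPY_POSITIONS, "all"))
    stop("unknown position: ", position, call. = FALSE)
  keep <- q$restoration_years == restoration_years
  if (position != "all") keep <- keep & q$position == position
  ids <- q$quadrat_id[keep]
  o <- dataset$observations[dataset$observations$quadrat_id %in% ids, ,
                            drop = FALSE]
  m <- match(o$quadrat_id, q$quadrat_id)
  o$restoration_years <- q$restoration_years[m]
  o$position <- q$position[m]
  rownames(o) <- NULL
  o
}

#' Enumerate the strata of a dataset
#'
#' @param dataset a [community_dataset()].
#' @return data.frame with one row per observed (restoration_years,
#'   position) pair, sorted by age then position.
#' @export
strata <- function(dataset) {
  stopifnot(inherits(dataset, "community_dataset"))
  s <- unique(dataset$quadrats[c("restoration_years", "position")])
  s <- s[order(s$restoration_years, match(s$position, CANOPY_POSITIONS)), ]
  rownames(s) <- NULL
  s
}

#' Write result tables as delimited text
#'
#' Writes one CSV per table in `results` (named list of data.frames) into
#' `out_dir`. The default mode keeps full double precision so that a
#' write/read round trip is bit-identical; `mode = "paper_compat"` rounds
#' numeric columns to 2 decimals, the precision used in published
#' community-stability tables.
#'
#' @param results named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @param mode `"full"` (default) or `"paper_compat"`.
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, out_dir, mode = c("full", "paper_compat")) {
  mode <- match.arg(mode)
  stopifnot(is.list(results), !is.null(names(results)),
            all(nzchar(names(results))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    tab <- as.data.frame(results[[nm]])
    num <- vapply(tab, is.double, logical(1))
    if (mode == "paper_compat") {
      tab[num] <- lapply(tab[num], round, digits = 2)
    } else {
      # %.17g guarantees a lossless double -> text -> double round trip
      tab[num] <- lapply(tab[num], function(x)
        ifelse(is.na(x), NA_character_, sprintf("%.17g", x)))
    }
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE, quote = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
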
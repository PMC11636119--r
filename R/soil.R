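# Stratified soil summaries and percent-change-vs-control computations.

SOIL_VARIABLES <- c("pH", "SOM", "AN", "TP")

#' Stratified soil summary
#'
#' Arithmetic mean, sample (n-1) standard deviation and count of each
#' soil variable within each group. Grouping keys default to restoration
#' age only (depth layers and positions pooled); pass any subset of
#' `c("restoration_years", "depth_layer", "position")`, or an empty
#' vector for the grand summary.
#'
#' @param soil validated soil data.frame (see [read_soil_table()]).
#' @param by character vector of grouping columns (possibly empty).
#' @param variables which of `pH`, `SOM` (g/kg), `AN` (mg/kg), `TP`
#'   (g/kg) to summarise.
#' @return data.frame: the grouping columns, `variable`, `mean`, `sd`
#'   (0 when `n = 1`), `n`.
#' @export
soil_summary <- function(soil, by = "restoration_years",
                         variables = SOIL_VARIABLES) {
  soil <- validate_soil(soil)
  bad <- setdiff(by, c("restoration_years", "depth_layer", "position"))
  if (length(bad))
    stop("unknown grouping column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(variables, SOIL_VARIABLES)
  if (length(bad))
    stop("unknown soil variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (nrow(soil) == 0L) stop("empty soil table", call. = FALSE)

  key <- if (length(by)) interaction(soil[by], drop = TRUE, sep = "\r")
         else factor(rep("all", nrow(soil)))
  groups <- split(seq_len(nrow(soil)), key)
  rows <- lapply(groups, function(idx) {
    head_row <- soil[idx[1], by, drop = FALSE]
    do.call(rbind, lapply(variables, function(v) {
      x <- soil[[v]][idx]
      cbind(head_row,
            data.frame(variable = v, mean = mean(x),
                       sd = if (length(x) == 1L) 0 else stats::sd(x),
                       n = length(x)),
            row.names = NULL)
    }))
  })
  out <- do.call(rbind, rows)
  ord <- do.call(order, c(lapply(by, function(b) out[[b]]),
                          list(match(out$variable, SOIL_VARIABLES))))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent change of a treatment mean versus a control mean
#'
#' `100 * (treatment - control) / control`, the "X % higher than the
#' control" convention: +250.08 % means a 3.5008-fold ratio.
#'
#' @param treatment_mean numeric.
#' @param control_mean numeric, strictly positive.
#' @return percent change (vectorised).
#' @export
percent_change_vs_control <- function(treatment_mean, control_mean) {
  if (any(!is.finite(control_mean)) || any(control_mean <= 0))
    stop("control mean must be finite and > 0", call. = FALSE)
  100 * (treatment_mean - control_mean) / control_mean
}

#' Soil change versus the unrestored control, by restoration age
#'
#' Summarises each variable by restoration age (layers and positions
#' pooled) and expresses every age's mean as a percent change versus the
#' control age.
#'
#' @param soil validated soil data.frame.
#' @param control_years restoration age of the control (default 0,
#'   unrestored mobile sandy land).
#' @param variables which variables to report.
#' @return data.frame: `restoration_years`, `variable`, `mean`, `sd`,
#'   `n`, `pct_change_vs_control` (`NA` for pH, which is not a ratio
#'   variable, and 0 for the control itself).
#' @export
soil_change_table <- function(soil, control_years = 0,
                              variables = SOIL_VARIABLES) {
  s <- soil_summary(soil, by = "restoration_years", variables = variables)
  if (!control_years %in% s$restoration_years)
    stop("control age ", control_years, " absent from soil table",
         call. = FALSE)
  s$pct_change_vs_control <- NA_real_
  for (v in setdiff(variables, "pH")) {
    ctrl <- s$mean[s$restoration_years == control_years & s$variable == v]
    sel <- s$variable == v
    s$pct_change_vs_control[sel] <-
      percent_change_vs_control(s$mean[sel], ctrl)
  }
  s
}
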
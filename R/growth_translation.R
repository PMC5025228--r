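# Growth-curve and reporter-kinetics metrics for plate-reader experiments:
# per-interval reporter production rate, maximal rate and total production
# (area under the rate curve), maximal growth rate, replicate averaging.

#' Construct a kinetics table
#'
#' @param time Strictly increasing time points (minutes).
#' @param od OD600 readings (> 0 wherever a rate is computed).
#' @param fluo Optional reporter fluorescence (arbitrary units).
#' @param replicate_id Replicate label.
#' @return data.frame of class `kinetics_table`.
#' @export
kinetics_table <- function(time, od, fluo = NULL, replicate_id = "rep1") {
  stopifnot(length(time) == length(od), all(diff(time) > 0))
  if (!is.null(fluo)) stopifnot(length(fluo) == length(time))
  df <- data.frame(time = as.numeric(time), od = as.numeric(od),
                   fluo = if (is.null(fluo)) NA_real_ else as.numeric(fluo),
                   replicate_id = replicate_id)
  class(df) <- c("kinetics_table", "data.frame")
  df
}

#' Read / write kinetics tables as TSV
#' @param path TSV with columns `time`, `od`, optionally `fluo`,
#'   `replicate_id`.
#' @return `read_kinetics_tsv`: list of `kinetics_table`, one per replicate.
#' @export
read_kinetics_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (is.null(df$replicate_id)) df$replicate_id <- "rep1"
  lapply(split(df, df$replicate_id), function(d)
    kinetics_table(d$time, d$od, d$fluo, d$replicate_id[1]))
}

#' @rdname read_kinetics_tsv
#' @param tables A `kinetics_table` or list of them.
#' @export
write_kinetics_tsv <- function(tables, path) {
  if (inherits(tables, "kinetics_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, as.data.frame))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-interval reporter production rate
#'
#' `r_t = (F_t - F_(t-1)) / OD_t` for t >= 2: the reporter increment over
#' each measurement interval normalized by the cell density at its end, i.e.
#' per-cell production over the interval.
#'
#' @param table A `kinetics_table` with fluorescence.
#' @return data.frame with `time` (interval end) and `rate`, length n - 1.
#' @export
production_rate <- function(table) {
  stopifnot(inherits(table, "kinetics_table"))
  if (all(is.na(table$fluo))) stop("no fluorescence column in table")
  n <- nrow(table)
  if (n < 2L) stop("need at least two time points")
  od <- table$od[-1L]
  if (any(od <= 0)) stop("OD must be positive where rates are computed")
  data.frame(time = table$time[-1L],
             rate = diff(table$fluo) / od)
}

#' Maximal sliding-window growth rate from ln(OD)
#'
#' Maximum slope (per minute) of a least-squares line fit to `ln(OD)` in a
#' sliding window of `window` consecutive points.
#'
#' @param table A `kinetics_table`.
#' @param window Window size in points (default 5).
#' @return Maximal slope (1/min).
#' @export
max_growth_rate <- function(table, window = 5L) {
  stopifnot(inherits(table, "kinetics_table"), window >= 2L)
  n <- nrow(table)
  if (n < window) stop("fewer time points than the window size")
  if (any(table$od <= 0)) stop("OD must be positive")
  y <- log(table$od)
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    tt <- table$time[idx]
    unname(coef(lm(y[idx] ~ tt))[2])
  }, 0)
  max(slopes)
}

#' Summarize reporter kinetics
#'
#' Maximal production rate = highest value of the [production_rate()] series;
#' total production = trapezoidal area under that series over time; maximal
#' growth rate from [max_growth_rate()]. With a `reference` summary,
#' percentages relative to the reference are attached.
#'
#' @param table A `kinetics_table`.
#' @param reference Optional `kinetics_summary` to express values against.
#' @param growth_window Window for [max_growth_rate()].
#' @return list of class `kinetics_summary`: `max_production_rate`,
#'   `total_production`, `max_growth_rate`, and (given a reference)
#'   `relative` with the same metrics as percentages.
#' @export
summarize_kinetics <- function(table, reference = NULL, growth_window = 5L) {
  r <- production_rate(table)
  maxr <- max(r$rate)
  total <- trapezoid_area(r$time, r$rate)
  mug <- max_growth_rate(table, growth_window)
  out <- list(max_production_rate = maxr, total_production = total,
              max_growth_rate = mug)
  if (!is.null(reference)) {
    rel <- function(v, ref) {
      if (ref == 0) stop("reference value is zero for a requested ratio")
      100 * v / ref
    }
    out$relative <- list(
      max_production_rate = rel(maxr, reference$max_production_rate),
      total_production = rel(total, reference$total_production),
      max_growth_rate = rel(mug, reference$max_growth_rate))
  }
  class(out) <- "kinetics_summary"
  out
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf("max production rate: %.4g\ntotal production:   %.4g\n",
              x$max_production_rate, x$total_production))
  cat(sprintf("max growth rate:    %.4g /min\n", x$max_growth_rate))
  if (!is.null(x$relative))
    cat(sprintf("relative to reference: rate %.1f%%, total %.1f%%, growth %.1f%%\n",
                x$relative$max_production_rate,
                x$relative$total_production,
                x$relative$max_growth_rate))
  invisible(x)
}

#' Trapezoidal area under a sampled curve
#' @param x Ordered abscissae.
#' @param y Ordinates.
#' @return Trapezoid-rule integral.
#' @export
trapezoid_area <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (length(x) == 1L) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Pointwise mean and standard deviation across replicate curves
#'
#' @param tables List of `kinetics_table` on identical time grids.
#' @return data.frame with `time`, `od_mean`, `od_sd`, `fluo_mean`,
#'   `fluo_sd`, `n`.
#' @export
average_curves <- function(tables) {
  stopifnot(length(tables) >= 1L)
  grid <- tables[[1]]$time
  for (t_ in tables)
    if (!isTRUE(all.equal(t_$time, grid)))
      stop("replicates are not on identical time grids")
  odm <- sapply(tables, function(t_) t_$od)
  flm <- sapply(tables, function(t_) t_$fluo)
  data.frame(
    time = grid,
    od_mean = rowMeans(odm), od_sd = apply(odm, 1, sd),
    fluo_mean = rowMeans(flm), fluo_sd = apply(flm, 1, sd),
    n = length(tables))
}
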
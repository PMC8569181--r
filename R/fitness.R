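# Serial-transfer competition fitness.
#
# Model of the assay: each daily transfer dilutes the coculture 1:D and the
# culture regrows to the same stationary density, so the total population
# expands exactly D-fold per transfer. A strain at fraction f0 initially
# and f_T after T transfers has therefore realized
# log2(f_T * D^T / f0) doublings, and the relative fitness W of the
# reference strain versus the test strain is the ratio of their doubling
# numbers.

#' Realized doublings of a strain across serial transfers
#'
#' @param f_initial,f_final Strain fraction of the population at the start
#'   and end of the interval, strictly inside (0, 1).
#' @param n_transfers Number of transfers in the interval (>= 1).
#' @param dilution_factor Fold dilution (= fold regrowth) per transfer
#'   (default 100).
#' @return `log2(f_final * dilution_factor^n_transfers / f_initial)`.
#' @examples
#' doublings(0.5, 0.5, 1, 100)  # neutral: log2(100)
#' @export
doublings <- function(f_initial, f_final, n_transfers,
                      dilution_factor = 100) {
  if (any(f_initial <= 0 | f_initial >= 1 | f_final <= 0 | f_final >= 1)) {
    abort(paste0("strain fractions must lie strictly in (0, 1); a fraction ",
                 "of 0 or 1 means extinction/fixation and doublings are ",
                 "undefined"))
  }
  stopifnot(all(n_transfers >= 1), all(dilution_factor >= 1))
  log2(f_final * dilution_factor^n_transfers / f_initial)
}

#' Relative fitness from a competition time series
#'
#' Computes per-replicate doublings of both strains over an interval and
#' their ratio W. With the default `reference = "B"`, W is the reference
#' (non-test) strain's doublings divided by the test strain A's, so W > 1
#' means the reference out-competed the test strain. Swapping the reference
#' maps W to 1/W.
#'
#' @param series Competition tibble (see [read_competition_csv()]):
#'   `time`, `replicate`, and either `count_a` + `total` or `fraction_a`.
#' @param interval Length-2 numeric, the start and end transfer index
#'   (e.g. `c(0, 5)` for T5 vs T0).
#' @param dilution_factor Fold dilution per transfer (default 100).
#' @param reference `"B"` (default) or `"A"`: which strain is the
#'   numerator of W.
#' @return A `fitness_result` object; see [tidy.fitness_result()] and
#'   [glance.fitness_result()].
#' @examples
#' series <- tibble::tibble(time = c(0, 1), replicate = 1,
#'                          fraction_a = c(0.52, 0.48))
#' glance(relative_fitness(series, c(0, 1)))
#' @export
relative_fitness <- function(series, interval, dilution_factor = 100,
                             reference = c("B", "A")) {
  reference <- match.arg(reference)
  series <- as_tibble(series)
  require_columns(series, c("time", "replicate"), "series")
  if (!"fraction_a" %in% names(series)) {
    require_columns(series, c("count_a", "total"), "series")
    if (any(series$total <= 0)) abort("colony totals must be positive")
    series$fraction_a <- series$count_a / series$total
  }
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  endpoints <- series %>%
    filter(.data$time %in% interval) %>%
    select("time", "replicate", "fraction_a") %>%
    tidyr::pivot_wider(names_from = "time", values_from = "fraction_a",
                       names_prefix = "t")
  t0_col <- paste0("t", interval[1]); t1_col <- paste0("t", interval[2])
  if (!all(c(t0_col, t1_col) %in% names(endpoints)) ||
      any(is.na(endpoints[[t0_col]]) | any(is.na(endpoints[[t1_col]])))) {
    abort(paste0("both interval endpoints (T", interval[1], ", T",
                 interval[2], ") must be present for every replicate"))
  }
  n_transfers <- interval[2] - interval[1]
  per <- endpoints %>%
    mutate(
      doublings_a = doublings(.data[[t0_col]], .data[[t1_col]],
                              n_transfers, dilution_factor),
      doublings_b = doublings(1 - .data[[t0_col]], 1 - .data[[t1_col]],
                              n_transfers, dilution_factor),
      W = if (reference == "B") .data$doublings_b / .data$doublings_a
          else .data$doublings_a / .data$doublings_b,
      degenerate = .data$doublings_a <= 0 | .data$doublings_b <= 0
    ) %>%
    select("replicate", f_initial = all_of(t0_col),
           f_final = all_of(t1_col), "doublings_a", "doublings_b", "W",
           "degenerate")
  structure(
    list(
      per_replicate = per,
      interval = interval,
      dilution_factor = dilution_factor,
      reference = reference,
      mean_W = mean(per$W),
      sd_W = if (nrow(per) > 1) sd(per$W) else NA_real_,
      n_replicates = nrow(per)
    ),
    class = "fitness_result"
  )
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf(
    "<fitness_result> T%g vs T%g (1:%g transfers), reference strain %s\n",
    x$interval[2], x$interval[1], x$dilution_factor, x$reference))
  cat(sprintf("  W = %.4f", x$mean_W))
  if (!is.na(x$sd_W)) cat(sprintf(" +/- %.4f (s.d., n = %d)", x$sd_W,
                                  x$n_replicates))
  cat("\n")
  if (any(x$per_replicate$degenerate)) {
    cat("  warning: degenerate doublings (<= 0) in some replicate(s)\n")
  }
  invisible(x)
}

#' Tidy a fitness result into per-replicate rows
#'
#' @param x A `fitness_result` from [relative_fitness()].
#' @param ... Unused.
#' @return Tibble with one row per replicate: fractions, doublings of both
#'   strains, `W` and a `degenerate` flag.
#' @method tidy fitness_result
#' @export
tidy.fitness_result <- function(x, ...) {
  x$per_replicate
}

#' One-row summary of a fitness result
#'
#' @param x A `fitness_result` from [relative_fitness()].
#' @param ... Unused.
#' @return One-row tibble: `mean_W`, `sd_W`, `n_replicates`, `t_start`,
#'   `t_end`, `dilution_factor`, `reference`.
#' @method glance fitness_result
#' @export
glance.fitness_result <- function(x, ...) {
  tibble(mean_W = x$mean_W, sd_W = x$sd_W, n_replicates = x$n_replicates,
         t_start = x$interval[1], t_end = x$interval[2],
         dilution_factor = x$dilution_factor, reference = x$reference)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
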
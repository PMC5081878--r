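#' Pre-correct traits for contemporary-group means
#'
#' Subtracts the herd-year-month (HYM) contemporary-group mean from
#' each trait, so adjusted values have exactly zero mean within every
#' group. This removes the dominant shared-management signal before
#' computing descriptive phenotypic correlations.
#'
#' @param records Edited records with class assignments.
#' @param traits Trait columns to adjust.
#' @return The records with the trait columns replaced by their
#'   within-HYM deviations.
#' @export
precorrect <- function(records, traits = c("scs", "milk", "fat_kg", "protein_kg")) {
  miss <- setdiff(c(traits, "hym"), names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(tibble::as_tibble(records), .data$hym),
    dplyr::across(dplyr::all_of(traits), ~ .x - mean(.x))
  ))
}

#' Daily (DIM-windowed) phenotypic correlations
#'
#' Pearson correlations between trait pairs within consecutive
#' days-in-milk windows tiling \[5, 305\]. Windows with fewer than
#' `min_n` records, or with a degenerate variance, report a missing
#' correlation (`NA`).
#'
#' @param records Records (typically [precorrect()]ed; pass raw edited
#'   records for the unadjusted version).
#' @param pairs List of 2-vectors of trait column names; default SCS
#'   against each yield.
#' @param window_days Window width in days (>= 1; default 15).
#' @param min_n Minimum records per window (default 30).
#' @return Tibble: `dim_lo`, `dim_hi`, `pair`, `r`, `n`.
#' @export
daily_correlations <- function(records,
                               pairs = list(c("scs", "milk"), c("scs", "fat_kg"),
                                            c("scs", "protein_kg")),
                               window_days = 15, min_n = 30) {
  if (window_days < 1) stop("window_days must be >= 1")
  lo <- seq(5, 305, by = window_days)
  hi <- pmin(lo + window_days - 1, 305)
  purrr::map_dfr(seq_along(lo), function(w) {
    win <- records[records$dim >= lo[w] & records$dim <= hi[w], , drop = FALSE]
    purrr::map_dfr(pairs, function(p) {
      x <- win[[p[1]]]
      y <- win[[p[2]]]
      n <- nrow(win)
      r <- NA_real_
      if (n >= min_n && stats::sd(x) > 0 && stats::sd(y) > 0) {
        r <- stats::cor(x, y)
      }
      tibble::tibble(dim_lo = lo[w], dim_hi = hi[w],
                     pair = paste(p, collapse = "-"), r = r, n = n)
    })
  })
}

#' Record-count-weighted average of window correlations
#'
#' @param daily Tibble from [daily_correlations()].
#' @return Tibble with one weighted mean correlation per pair
#'   (windows with missing `r` are dropped from both numerator and
#'   weights).
#' @export
average_daily_correlation <- function(daily) {
  ok <- daily[!is.na(daily$r), , drop = FALSE]
  if (!nrow(ok)) stop("no populated windows to average")
  dplyr::summarise(
    dplyr::group_by(ok, .data$pair),
    r = stats::weighted.mean(.data$r, .data$n),
    n = sum(.data$n),
    .groups = "drop"
  )
}

#' Plot daily correlations against days in milk
#'
#' @param daily Tibble from [daily_correlations()].
#' @return A ggplot of window correlation (window midpoint on x) per
#'   trait pair.
#' @export
plot_daily_correlations <- function(daily) {
  d <- dplyr::mutate(daily, dim_mid = (.data$dim_lo + .data$dim_hi) / 2)
  ggplot2::ggplot(d[!is.na(d$r), ],
                  ggplot2::aes(x = .data$dim_mid, y = .data$r, colour = .data$pair)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "days in milk", y = "phenotypic correlation", colour = NULL)
}
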
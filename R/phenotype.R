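#' Somatic cell score from somatic cell count
#'
#' The base-2 log transform used throughout dairy recording:
#' `SCS = log2(SCC / 100) + 3`, with SCC in thousands of cells per mL.
#' An SCC of 100 (x1000 cells/mL) maps to SCS 3, and every doubling of
#' SCC adds one score unit.
#'
#' @param scc Somatic cell count, x1000 cells/mL; must be positive.
#' @return Somatic cell score (unitless).
#' @examples
#' scs_from_scc(c(50, 100, 200))
#' @export
scs_from_scc <- function(scc) {
  if (any(!is.finite(scc) | scc <= 0)) stop("SCC must be positive and finite")
  log2(scc / 100) + 3
}

#' Somatic cell count from somatic cell score
#'
#' Exact inverse of [scs_from_scc()]: `SCC = 100 * 2^(SCS - 3)`.
#'
#' @param scs Somatic cell score.
#' @return SCC in x1000 cells/mL.
#' @export
scc_from_scs <- function(scs) {
  100 * 2^(scs - 3)
}

#' Default record-edit configuration
#'
#' The standard test-day edits: milk 3--75 kg, fat 1.5--8 %, protein
#' 1--7 %, SCC 1--500 (x1000 cells/mL), days in milk 5--305, age at
#' first calving 18--36 months, and at least `min_records` surviving
#' test-day records per cow.
#'
#' @param min_records Minimum number of in-range records a cow must
#'   retain to be kept at all.
#' @return A named list of `c(lo, hi)` ranges plus `min_records`.
#' @export
edit_config <- function(min_records = 5L) {
  list(
    milk = c(3, 75),
    fat_pct = c(1.5, 8),
    protein_pct = c(1, 7),
    scc = c(1, 500),
    dim = c(5, 305),
    age_at_calving = c(18, 36),
    min_records = as.integer(min_records)
  )
}

record_fields <- c(
  "cow", "herd", "test_year", "test_month", "calving_year", "calving_month",
  "age_at_calving", "dim", "milk", "fat_pct", "protein_pct", "scc"
)

#' Apply the standard test-day record edits
#'
#' Range filters are applied first, in a fixed documented order (milk,
#' fat %, protein %, SCC, DIM, age at calving); each removed record is
#' attributed to the first rule it violates. Cows left with fewer than
#' `min_records` in-range records are then removed entirely. Derived
#' traits `scs`, `fat_kg = milk * fat_pct / 100` and
#' `protein_kg = milk * protein_pct / 100` are computed on the kept
#' records. The edit is idempotent.
#'
#' @param records Tibble of raw test-day records with at least the
#'   fields `cow`, `herd`, `test_year`, `test_month`, `calving_year`,
#'   `calving_month`, `age_at_calving`, `dim`, `milk`, `fat_pct`,
#'   `protein_pct`, `scc`.
#' @param config Edit configuration from [edit_config()].
#' @return The kept records (tibble, with derived trait columns) with
#'   the edit report attached as attribute `"edit_report"`; retrieve it
#'   with [edit_report()].
#' @export
apply_edits <- function(records, config = edit_config()) {
  miss <- setdiff(record_fields, names(records))
  if (length(miss)) stop("records are missing required field(s): ", paste(miss, collapse = ", "))
  records <- tibble::as_tibble(records)
  n_in <- nrow(records)
  rules <- c("milk", "fat_pct", "protein_pct", "scc", "dim", "age_at_calving")
  removed <- stats::setNames(integer(length(rules)), rules)
  keep <- rep(TRUE, n_in)
  for (r in rules) {
    rng <- config[[r]]
    ok <- records[[r]] >= rng[1] & records[[r]] <= rng[2] & is.finite(records[[r]])
    hit <- keep & !ok
    removed[[r]] <- sum(hit)
    keep <- keep & ok
  }
  kept <- records[keep, , drop = FALSE]
  tab <- table(kept$cow)
  small <- names(tab)[tab < config$min_records]
  n_min <- sum(kept$cow %in% small)
  kept <- kept[!(kept$cow %in% small), , drop = FALSE]
  kept <- dplyr::mutate(
    kept,
    scs = scs_from_scc(.data$scc),
    fat_kg = .data$milk * .data$fat_pct / 100,
    protein_kg = .data$milk * .data$protein_pct / 100
  )
  report <- list(
    n_input = n_in,
    removed_by_range = as.list(removed),
    removed_min_records = n_min,
    cows_removed_min_records = length(small),
    n_kept = nrow(kept),
    cows_kept = length(unique(kept$cow)),
    config = config
  )
  attr(kept, "edit_report") <- report
  kept
}

#' Retrieve the edit report of an edited record table
#'
#' @param records The tibble returned by [apply_edits()].
#' @return The edit report (list of counts per rule, in application order).
#' @export
edit_report <- function(records) {
  rep <- attr(records, "edit_report")
  if (is.null(rep)) stop("no edit report attached; was apply_edits() run?")
  rep
}

#' Season-of-calving rule: calendar quarters
#'
#' Maps calving month to season 1--4 (Jan--Mar = 1, Apr--Jun = 2,
#' Jul--Sep = 3, Oct--Dec = 4). Any month-to-season map of the same
#' shape can be supplied to [assign_classes()] instead.
#'
#' @param month Calving month, 1--12.
#' @return Integer season code.
#' @export
season_quarter <- function(month) {
  (as.integer(month) - 1L) %/% 3L + 1L
}

# dense integer codes in order of first appearance (relabelling-invariant)
dense_code <- function(key) {
  f <- match(key, unique(key))
  as.integer(f)
}

#' Assign contemporary groups and fixed-regression classes
#'
#' Adds to each edited record: `hym`, the herd-within-year-month-of-test
#' contemporary group; `age_class`, one of the 19 monthly age-at-first-
#' calving classes (18, 19, ..., 36 months); `season`, the season of
#' calving; `as_class`, the age-season class (at most 19 x 4 = 76
#' levels); and `hy_class`, the herd by year-of-calving class. All codes
#' are dense integers assigned in order of first appearance.
#'
#' @param records Edited records from [apply_edits()].
#' @param season_rule Function mapping calving month to a season code;
#'   default [season_quarter()].
#' @return The records with class columns added; the level key maps are
#'   attached as attribute `"class_maps"` (see [class_maps()]).
#' @export
assign_classes <- function(records, season_rule = season_quarter) {
  if (any(records$age_at_calving < 18 | records$age_at_calving > 36)) {
    stop("age at calving outside 18-36 months; run apply_edits() first")
  }
  out <- dplyr::mutate(
    tibble::as_tibble(records),
    age_class = as.integer(floor(.data$age_at_calving)) - 17L,
    season = season_rule(.data$calving_month),
    hym = dense_code(paste(.data$herd, .data$test_year, .data$test_month, sep = "\r")),
    as_class = dense_code(paste(.data$age_class, .data$season, sep = "\r")),
    hy_class = dense_code(paste(.data$herd, .data$calving_year, sep = "\r"))
  )
  maps <- list(
    hym = dplyr::distinct(out, .data$herd, .data$test_year, .data$test_month, .data$hym),
    as_class = dplyr::distinct(out, .data$age_class, .data$season, .data$as_class),
    hy_class = dplyr::distinct(out, .data$herd, .data$calving_year, .data$hy_class)
  )
  attr(out, "class_maps") <- maps
  attr(out, "edit_report") <- attr(records, "edit_report")
  out
}

#' Retrieve class-code maps
#'
#' @param records The tibble returned by [assign_classes()].
#' @return List of tibbles mapping class keys to dense codes.
#' @export
class_maps <- function(records) {
  maps <- attr(records, "class_maps")
  if (is.null(maps)) stop("no class maps attached; was assign_classes() run?")
  maps
}

#' Normalized Legendre covariates of days in milk
#'
#' Days in milk are mapped to `x = 2 (dim - 5) / (305 - 5) - 1` on
#' \[-1, 1\] and the first `order` normalized Legendre polynomials are
#' evaluated: `phi_0 = sqrt(1/2)`, `phi_1 = sqrt(3/2) x`, and
#' `phi_k = sqrt((2k+1)/2) P_k(x)` by the Bonnet recurrence. The basis
#' is orthonormal on \[-1, 1\].
#'
#' @param dim Days in milk, within \[`t_min`, `t_max`\].
#' @param order Number of coefficients (columns); 6 for age-season
#'   curves, 5 for herd-year curves.
#' @param t_min,t_max DIM standardization range (global, 5--305).
#' @return Matrix `length(dim) x order` of covariates.
#' @export
legendre_covariates <- function(dim, order, t_min = 5, t_max = 305) {
  if (any(dim < t_min | dim > t_max)) {
    stop("days in milk outside [", t_min, ", ", t_max, "]")
  }
  if (order < 1) stop("order must be >= 1")
  x <- 2 * (dim - t_min) / (t_max - t_min) - 1
  n <- length(x)
  P <- matrix(0, n, order)
  P[, 1] <- 1
  if (order >= 2) P[, 2] <- x
  if (order >= 3) {
    for (k in 2:(order - 1)) {
      # P_k = ((2k-1) x P_{k-1} - (k-1) P_{k-2}) / k
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  sweep(P, 2, sqrt((2 * seq_len(order) - 1) / 2), `*`)
}
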
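trait_names <- c("scs", "milk", "fat", "protein")

# build a covariance matrix from sd vector and correlation entries
cov_from_corr <- function(vars, corr) {
  sds <- sqrt(vars)
  S <- corr * (sds %o% sds)
  diag(S) <- vars
  dimnames(S) <- list(trait_names, trait_names)
  S
}

corr_mat <- function(scs_milk, scs_fat, scs_protein, milk_fat, milk_protein, fat_protein) {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- scs_milk
  C[1, 3] <- C[3, 1] <- scs_fat
  C[1, 4] <- C[4, 1] <- scs_protein
  C[2, 3] <- C[3, 2] <- milk_fat
  C[2, 4] <- C[4, 2] <- milk_protein
  C[3, 4] <- C[4, 3] <- fat_protein
  C
}

#' Simulation truth: trait covariance matrices and fixed-effect scales
#'
#' Default (co)variance structure of the generator, in trait order SCS,
#' milk (kg), fat (kg), protein (kg). Genetic variances 0.031 / 7.471 /
#' 0.007 / 0.005, permanent-environment 0.233 / 12.633 / 0.014 / 0.010
#' and residual 0.761 / 16.592 / 0.056 / 0.021 give heritabilities of
#' about 0.03 (SCS), 0.204 (milk), 0.10 (fat) and 0.14 (protein).
#' Genetic correlations default to milk-fat 0.62, milk-protein 0.90,
#' fat-protein 0.76 and SCS-milk/fat/protein 0.07 / 0.01 / 0.11. The
#' environmental correlations (SCS-yield -0.177 / -0.165 / -0.152;
#' production pairs 0.85 / 0.97 / 0.90) are placed identically in both
#' the permanent-environment and residual matrices, so the pooled
#' (P0 + R0) correlation is close to (slightly attenuated from) the
#' stated values.
#'
#' All three matrices are validated positive definite and the implied
#' heritabilities checked to lie in (0, 1).
#'
#' @param G0,P0,R0 Optional 4x4 covariance overrides (trait order SCS,
#'   milk, fat, protein).
#' @param trait_means Phenotypic means added through the contemporary-
#'   group effect; defaults SCS 2.433, milk 32.82 kg, fat 1.075 kg,
#'   protein 1.006 kg.
#' @param hym_sd Between-contemporary-group SD per trait (default about
#'   30 % of the phenotypic SD).
#' @param curve_sd Per-order SD multipliers (relative to phenotypic SD)
#'   for the fixed lactation-curve coefficients; recycled/truncated to
#'   the basis order.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(G0 = NULL, P0 = NULL, R0 = NULL,
                             trait_means = c(scs = 2.433, milk = 32.82,
                                             fat = 1.075, protein = 1.006),
                             hym_sd = NULL,
                             curve_sd = c(0.15, 0.10, 0.05, 0.03, 0.02, 0.02)) {
  g_var <- c(0.031, 7.471, 0.007, 0.005)
  p_var <- c(0.233, 12.633, 0.014, 0.010)
  r_var <- c(0.761, 16.592, 0.056, 0.021)
  g_corr <- corr_mat(0.07, 0.01, 0.11, 0.62, 0.90, 0.76)
  e_corr <- corr_mat(-0.177, -0.165, -0.152, 0.85, 0.97, 0.90)
  if (is.null(G0)) G0 <- cov_from_corr(g_var, g_corr)
  if (is.null(P0)) P0 <- cov_from_corr(p_var, e_corr)
  if (is.null(R0)) R0 <- cov_from_corr(r_var, e_corr)
  for (nm in c("G0", "P0", "R0")) {
    M <- get(nm)
    if (!isTRUE(all.equal(M, t(M))) || any(eigen(M, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      stop(nm, " is not symmetric positive definite")
    }
  }
  h2 <- diag(G0) / (diag(G0) + diag(P0) + diag(R0))
  if (any(h2 <= 0 | h2 >= 1)) stop("implied heritabilities must lie in (0, 1)")
  if (is.null(hym_sd)) hym_sd <- 0.3 * sqrt(diag(G0) + diag(P0) + diag(R0))
  structure(
    list(G0 = G0, P0 = P0, R0 = R0,
         trait_means = trait_means, hym_sd = hym_sd, curve_sd = curve_sd,
         h2 = stats::setNames(h2, trait_names),
         rg = stats::cov2cor(G0)),
    class = "simulation_truth"
  )
}

#' @method print simulation_truth
#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth> h2 =", paste(signif(x$h2, 3), collapse = " / "),
      "(scs/milk/fat/protein)\n")
  invisible(x)
}

#' Simulation design: population and recording structure
#'
#' Defaults emulate a first-lactation test-day recording scheme at
#' reduced scale: unrelated founder sires and dams, recorded cows as
#' their offspring by random mating, cows spread over herds, monthly
#' tests starting at a random DIM in \[5, 35\].
#'
#' @param n_cows Number of recorded cows.
#' @param n_sires,n_dams Founder sires and founder dams. The defaults
#'   (100 sires, 250 founder dams at the default cow count) are chosen
#'   for parameter identifiability at desk scale: the sampling error of
#'   a recovered genetic variance is governed by the number and size of
#'   families (half-sib family sizes near `4 W / sigma2_g`, with W the
#'   within-family variance of cow means, minimize it), not by the
#'   record count per cow.
#' @param frac_founder_gen Fraction of recorded cows whose dam is a
#'   founder; the remainder are daughters of earlier recorded cows,
#'   calving in later years. First-lactation recording schemes span
#'   many years, so dams of later cows are themselves recorded —
#'   mother-daughter pairs contribute parent-offspring information that
#'   substantially tightens the genetic variance.
#' @param n_herds Herds; cows are assigned uniformly.
#' @param records_per_cow Test-day records per cow (monthly; 8 keeps all
#'   DIM within 5--245).
#' @param calving_years Calendar years of first calving (uniform).
#' @param test_interval Days between consecutive tests.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_cows = 1000L, n_sires = 100L, n_dams = 250L,
                              n_herds = 10L, records_per_cow = 8L,
                              frac_founder_gen = 0.4,
                              calving_years = c(2009L, 2012L),
                              test_interval = 30L) {
  if (n_cows < 1) stop("n_cows must be at least 1")
  if (n_sires < 1 || n_dams < 1) stop("need at least one sire and one dam")
  structure(
    list(n_cows = as.integer(n_cows), n_sires = as.integer(n_sires),
         n_dams = as.integer(n_dams), n_herds = as.integer(n_herds),
         records_per_cow = as.integer(records_per_cow),
         frac_founder_gen = frac_founder_gen,
         calving_years = as.integer(calving_years),
         test_interval = as.integer(test_interval)),
    class = "simulation_design"
  )
}

#' Simulate a pedigree of founder parents and recorded cows
#'
#' Sires and dams are unrelated founders; each recorded cow draws a
#' sire and a dam uniformly at random (random mating, half-sib family
#' structure through shared sires).
#'
#' @param design A [simulation_design()].
#' @return A closed pedigree tibble (`animal`, `sire`, `dam`); cows are
#'   ids `"C1"..."Cn"`, sires `"S*"`, dams `"D*"`.
#' @export
simulate_pedigree <- function(design = simulation_design()) {
  sires <- paste0("S", seq_len(design$n_sires))
  dams <- paste0("D", seq_len(design$n_dams))
  cows <- paste0("C", seq_len(design$n_cows))
  n1 <- max(1L, round(design$frac_founder_gen * design$n_cows))
  n2 <- design$n_cows - n1
  cow_sire <- sample(sires, design$n_cows, replace = TRUE)
  cow_dam <- c(sample(dams, n1, replace = TRUE),
               if (n2 > 0) sample(cows[seq_len(n1)], n2, replace = TRUE))
  # a cow cannot be mated to her own sire's daughter issue does not
  # arise (sires and dams are disjoint); generation flags drive later
  # calving years for daughters of recorded cows
  ped <- tibble::tibble(
    animal = c(sires, dams, cows),
    sire = c(rep(NA_character_, design$n_sires + design$n_dams), cow_sire),
    dam = c(rep(NA_character_, design$n_sires + design$n_dams), cow_dam)
  )
  attr(ped, "cow_generation") <- rep(c(1L, 2L), c(n1, n2))
  ped
}

#' Simulate breeding values down a pedigree
#'
#' Founders draw from MVN(0, G0); non-founders are the parent average
#' plus a Mendelian-sampling deviation MVN(0, d G0), with d = 0.5 -
#' 0.25 (F_sire + F_dam) for two known parents, 0.75 - 0.25 F_parent
#' for one, and 1 for none.
#'
#' @param ped A closed pedigree tibble.
#' @param G0 4x4 additive genetic covariance matrix (positive
#'   semi-definite; the zero matrix gives all-zero breeding values).
#' @return Matrix `n_animals x 4` of breeding values, rownames = animal
#'   ids, rows in the order of `ped$animal`.
#' @export
simulate_breeding_values <- function(ped, G0) {
  ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("G0 must be positive semi-definite")
  rc <- recode_pedigree(ped)
  n <- nrow(rc$ped)
  s <- rc$sire
  d_ <- rc$dam
  Fv <- inbreeding_ml(s, d_)
  Lg <- chol_psd(G0)
  bv <- matrix(0, n, 4)
  Z <- matrix(stats::rnorm(n * 4), n, 4)
  for (i in seq_len(n)) {
    pa <- numeric(4)
    dmend <- 1
    if (!is.na(s[i]) && !is.na(d_[i])) {
      pa <- (bv[s[i], ] + bv[d_[i], ]) / 2
      dmend <- 0.5 - 0.25 * (Fv[s[i]] + Fv[d_[i]])
    } else if (!is.na(s[i])) {
      pa <- bv[s[i], ] / 2
      dmend <- 0.75 - 0.25 * Fv[s[i]]
    } else if (!is.na(d_[i])) {
      pa <- bv[d_[i], ] / 2
      dmend <- 0.75 - 0.25 * Fv[d_[i]]
    }
    bv[i, ] <- pa + sqrt(dmend) * drop(Z[i, ] %*% Lg)
  }
  rownames(bv) <- rc$ped$animal
  colnames(bv) <- trait_names
  bv[match(ped$animal, rc$ped$animal), , drop = FALSE]
}

# upper Cholesky factor allowing positive semi-definite input
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (sqrt(v) * t(e$vectors)))  # symmetric square root, used as right factor
}

#' Simulate test-day records under the fixed-regression animal model
#'
#' Each record is the sum of a herd-year-month contemporary-group
#' effect, an age-season fixed lactation curve (6 Legendre
#' coefficients), a herd-year-of-calving curve (5 coefficients), the
#' cow's additive genetic value, a permanent-environment effect drawn
#' once per cow from MVN(0, P0), and a residual MVN(0, R0) per record.
#' The SCS channel is emitted as SCC via the inverse score transform.
#'
#' With `edit_stress = FALSE` (default) record-level draws are redrawn
#' until all emitted fields fall inside the standard edit ranges, so
#' the table passes [apply_edits()] losslessly; with `edit_stress =
#' TRUE` no redrawing occurs, SCC is clipped into \[1, 500\] and a
#' small fraction of out-of-range records is injected to exercise the
#' edit rules.
#'
#' @param ped Pedigree from [simulate_pedigree()] (or any closed
#'   pedigree whose cow ids match `"C*"` ids in the design).
#' @param bv Breeding values from [simulate_breeding_values()].
#' @param truth A [simulation_truth()].
#' @param design A [simulation_design()].
#' @param edit_stress Emit out-of-range records (see above).
#' @return A list with `records` (test-day tibble in the input format
#'   of [apply_edits()]) and `truth` (the truth file: all simulated
#'   effects, matrices and design, suitable for parameter-recovery
#'   checks).
#' @export
simulate_records <- function(ped, bv, truth = simulation_truth(),
                             design = simulation_design(),
                             edit_stress = FALSE) {
  n_cows <- design$n_cows
  cows <- paste0("C", seq_len(n_cows))
  if (!all(cows %in% ped$animal)) stop("pedigree does not contain all recorded cows")
  herd <- sample.int(design$n_herds, n_cows, replace = TRUE)
  gen <- attr(ped, "cow_generation")
  yrs <- design$calving_years
  if (!is.null(gen) && length(yrs) >= 2) {
    # daughters of recorded cows calve in the later years
    calv_year <- ifelse(gen == 1L,
                        sample(yrs[1]:(yrs[1] + 1L), n_cows, replace = TRUE),
                        sample((yrs[2]):(yrs[2] + 1L), n_cows, replace = TRUE))
  } else {
    calv_year <- sample(yrs, n_cows, replace = TRUE)
  }
  calv_month <- sample.int(12L, n_cows, replace = TRUE)
  age <- sample(18:36, n_cows, replace = TRUE)
  t0 <- sample(5:35, n_cows, replace = TRUE)
  k <- design$records_per_cow
  dim_mat <- outer(t0, (seq_len(k) - 1L) * design$test_interval, `+`)
  if (any(dim_mat < 5 | dim_mat > 305)) stop("DIM schedule outside [5, 305]")

  # permanent environment, once per cow
  Lp <- chol_psd(truth$P0)
  rho <- matrix(stats::rnorm(n_cows * 4), n_cows, 4) %*% Lp
  Lr <- chol_psd(truth$R0)

  # expand to record level
  rec <- tibble::tibble(
    cow = rep(cows, each = k),
    herd = rep(herd, each = k),
    calving_year = rep(calv_year, each = k),
    calving_month = rep(calv_month, each = k),
    age_at_calving = rep(age, each = k),
    dim = as.vector(t(dim_mat))
  )
  calv_date <- as.Date(sprintf("%d-%02d-15", rec$calving_year, rec$calving_month))
  test_date <- calv_date + rec$dim
  rec$test_year <- as.integer(format(test_date, "%Y"))
  rec$test_month <- as.integer(format(test_date, "%m"))

  # fixed-effect structure (same class construction as assign_classes)
  season <- season_quarter(rec$calving_month)
  as_key <- paste(as.integer(rec$age_at_calving) - 17L, season)
  hy_key <- paste(rec$herd, rec$calving_year)
  hym_key <- paste(rec$herd, rec$test_year, rec$test_month)
  as_lev <- unique(as_key)
  hy_lev <- unique(hy_key)
  hym_lev <- unique(hym_key)

  sd_p <- sqrt(diag(truth$G0) + diag(truth$P0) + diag(truth$R0))
  # HYM effects carry the trait means
  hym_eff <- matrix(stats::rnorm(length(hym_lev) * 4), ncol = 4) %*% diag(truth$hym_sd) +
    matrix(truth$trait_means, length(hym_lev), 4, byrow = TRUE)
  s_as <- truth$curve_sd[pmin(seq_len(6), length(truth$curve_sd))]
  s_hy <- truth$curve_sd[pmin(seq_len(5), length(truth$curve_sd))]
  beta <- array(stats::rnorm(length(as_lev) * 6 * 4), c(length(as_lev), 6, 4))
  delta <- array(stats::rnorm(length(hy_lev) * 5 * 4), c(length(hy_lev), 5, 4))
  for (tr in 1:4) {
    beta[, , tr] <- beta[, , tr] * rep(s_as * sd_p[tr], each = length(as_lev))
    delta[, , tr] <- delta[, , tr] * rep(s_hy * sd_p[tr], each = length(hy_lev))
  }

  Z6 <- legendre_covariates(rec$dim, 6)
  Z5 <- Z6[, 1:5, drop = FALSE]
  ai <- match(as_key, as_lev)
  hi <- match(hy_key, hy_lev)
  mi <- match(hym_key, hym_lev)
  ci <- match(rec$cow, cows)
  bv_cow <- bv[match(cows, rownames(bv)), , drop = FALSE]

  mu <- hym_eff[mi, , drop = FALSE] + bv_cow[ci, , drop = FALSE] + rho[ci, , drop = FALSE]
  for (tr in 1:4) {
    mu[, tr] <- mu[, tr] +
      rowSums(Z6 * beta[ai, , tr, drop = FALSE][, , 1]) +
      rowSums(Z5 * delta[hi, , tr, drop = FALSE][, , 1])
  }

  nrec <- nrow(rec)
  draw_y <- function(rows) mu[rows, , drop = FALSE] +
    matrix(stats::rnorm(length(rows) * 4), ncol = 4) %*% Lr
  y <- draw_y(seq_len(nrec))
  in_range <- function(y) {
    scc <- scc_from_scs(y[, 1])
    fat_pct <- 100 * y[, 3] / y[, 2]
    protein_pct <- 100 * y[, 4] / y[, 2]
    y[, 2] >= 3 & y[, 2] <= 75 & fat_pct >= 1.5 & fat_pct <= 8 &
      protein_pct >= 1 & protein_pct <= 7 & scc >= 1 & scc <= 500
  }
  if (!edit_stress) {
    # redraw record residuals until all emitted fields pass the edits
    bad <- which(!in_range(y))
    tries <- 0L
    while (length(bad) && tries < 1000L) {
      y[bad, ] <- draw_y(bad)
      bad <- bad[!in_range(y[bad, , drop = FALSE])]
      tries <- tries + 1L
    }
    if (length(bad)) stop("could not draw in-range records; check truth scales")
  }
  scc <- scc_from_scs(y[, 1])
  if (edit_stress) scc <- pmin(pmax(scc, 1), 500)
  rec$milk <- y[, 2]
  rec$fat_pct <- 100 * y[, 3] / rec$milk
  rec$protein_pct <- 100 * y[, 4] / rec$milk
  rec$scc <- scc
  if (edit_stress) {
    # push ~1% of records out of range to exercise the edit rules
    n_bad <- max(1L, nrec %/% 100L)
    hit <- sample.int(nrec, n_bad)
    rec$milk[hit] <- 80
  }
  rec <- rec[, record_fields]
  truth_file <- list(
    truth = truth, design = design,
    breeding_values = bv_cow,
    pe = structure(rho, dimnames = list(cows, trait_names)),
    hym_effects = structure(hym_eff, dimnames = list(hym_lev, trait_names)),
    as_coefficients = structure(beta, dimnames = list(as_lev, NULL, trait_names)),
    hy_coefficients = structure(delta, dimnames = list(hy_lev, NULL, trait_names))
  )
  list(records = rec, truth = truth_file)
}

#' One-call synthetic data set with truth
#'
#' Convenience wrapper: pedigree, breeding values and records in one
#' call under the current RNG state.
#'
#' @inheritParams simulate_records
#' @param design A [simulation_design()].
#' @param truth A [simulation_truth()].
#' @return List with `records`, `pedigree`, `truth`.
#' @export
simulate_dataset <- function(design = simulation_design(),
                             truth = simulation_truth(),
                             edit_stress = FALSE) {
  ped <- simulate_pedigree(design)
  bv <- simulate_breeding_values(ped, truth$G0)
  sim <- simulate_records(ped, bv, truth, design, edit_stress = edit_stress)
  list(records = sim$records, pedigree = ped, truth = sim$truth)
}

#' Write a simulated data set to plain-text files
#'
#' Emits the record table and pedigree in the exact delimited formats
#' consumed by [apply_edits()] and [read_pedigree()], and the truth
#' (matrices, scales, design) as JSON.
#'
#' @param sim List from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    records = file.path(dir, "records.csv"),
    pedigree = file.path(dir, "pedigree.txt"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(sim$records, paths[["records"]])
  ped_out <- sim$pedigree
  ped_out$sire[is.na(ped_out$sire)] <- "0"
  ped_out$dam[is.na(ped_out$dam)] <- "0"
  readr::write_delim(ped_out, paths[["pedigree"]], delim = " ")
  tr <- sim$truth
  jsonlite::write_json(
    list(G0 = tr$truth$G0, P0 = tr$truth$P0, R0 = tr$truth$R0,
         trait_means = tr$truth$trait_means, hym_sd = tr$truth$hym_sd,
         h2 = tr$truth$h2, design = unclass(tr$design)),
    paths[["truth"]], digits = NA
  )
  invisible(paths)
}
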
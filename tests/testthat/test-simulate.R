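test_that("simulation truth validates structure and implied parameters", {
  tr <- simulation_truth()
  for (M in list(tr$G0, tr$P0, tr$R0)) {
    expect_true(all(eigen(M, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
  expect_equal(unname(tr$h2["milk"]), 7.471 / (7.471 + 12.633 + 16.592))
  expect_equal(tr$rg["milk", "protein"], 0.90)
  expect_equal(tr$rg["scs", "milk"], 0.07)
  expect_true(all(tr$h2 > 0 & tr$h2 < 1))
  # a non-PD override is rejected
  bad <- diag(c(1, 1, 1, -1))
  expect_error(simulation_truth(G0 = bad), "positive definite")
})

test_that("simulated pedigree has the requested structure", {
  set.seed(1)
  des <- simulation_design(n_cows = 200, n_sires = 10, n_dams = 100)
  ped <- simulate_pedigree(des)
  expect_equal(nrow(ped), 310)
  cows <- ped[grepl("^C", ped$animal), ]
  expect_true(all(!is.na(cows$sire) & !is.na(cows$dam)))
  expect_true(all(grepl("^S", cows$sire)))

  # paternal half sibs have additive relationship 0.25 (checked on
  # founder-generation cows, whose dams are unrelated founders)
  A <- relationship_matrix(ped)
  cows <- cows[grepl("^D", cows$dam), ]
  hs <- which(outer(cows$sire, cows$sire, "==") &
              outer(cows$dam, cows$dam, "!="), arr.ind = TRUE)
  pair <- hs[hs[, 1] < hs[, 2], , drop = FALSE][1, ]
  expect_equal(A[cows$animal[pair[1]], cows$animal[pair[2]]], 0.25)
  # cows with neither parent shared are unrelated
  un <- which(outer(cows$sire, cows$sire, "!=") &
              outer(cows$dam, cows$dam, "!="), arr.ind = TRUE)[1, ]
  expect_equal(A[cows$animal[un[1]], cows$animal[un[2]]], 0)
  expect_error(simulate_pedigree(simulation_design(n_cows = 0)), "n_cows")
})

test_that("breeding values follow the pedigree covariance structure", {
  tr <- simulation_truth()
  # founder covariance: many unrelated founders ~ MVN(0, G0)
  set.seed(2)
  big <- tibble::tibble(animal = paste0("F", 1:1e5),
                        sire = NA_character_, dam = NA_character_)
  bv <- simulate_breeding_values(big, tr$G0)
  expect_lt(norm(stats::cov(bv) - tr$G0, "F") / norm(tr$G0, "F"), 0.02)

  # offspring mean equals parent average over replicate offspring
  set.seed(3)
  reps <- 4000
  ped <- tibble::tibble(
    animal = c("S", "D", paste0("O", seq_len(reps))),
    sire = c(NA, NA, rep("S", reps)),
    dam = c(NA, NA, rep("D", reps))
  )
  bv <- simulate_breeding_values(ped, tr$G0)
  pa <- (bv["S", ] + bv["D", ]) / 2
  mend_se <- sqrt(0.5 * diag(tr$G0) / reps)
  off <- bv[grepl("^O", rownames(bv)), ]
  expect_true(all(abs(colMeans(off) - pa) < 3 * mend_se))
  # Mendelian variance about the parent average is G0/2
  expect_lt(norm(stats::cov(off) - 0.5 * tr$G0, "F") / norm(0.5 * tr$G0, "F"), 0.1)

  # zero genetic covariance -> all breeding values exactly zero
  bv0 <- simulate_breeding_values(ped, matrix(0, 4, 4))
  expect_true(all(bv0 == 0))
})

test_that("records decompose into the simulated variance components", {
  # all cow-level and group-level variance off -> record variance = diag(R0)
  tr0 <- simulation_truth(G0 = diag(1e-12, 4), P0 = diag(1e-12, 4),
                          hym_sd = rep(1e-9, 4), curve_sd = rep(1e-12, 6))
  set.seed(4)
  des <- simulation_design(n_cows = 1500, n_sires = 5, n_dams = 100,
                           records_per_cow = 5)
  sim <- simulate_dataset(des, tr0)
  ed <- dplyr::mutate(sim$records, scs = scs_from_scc(scc),
                      fat_kg = milk * fat_pct / 100,
                      protein_kg = milk * protein_pct / 100)
  y <- cbind(ed$scs, ed$milk, ed$fat_kg, ed$protein_kg)
  v <- apply(y, 2, stats::var)
  expect_true(all(abs(v / diag(tr0$R0) - 1) < 0.1))

  # repeatability: two records of one cow covary through P0 (milk trait)
  tr1 <- simulation_truth(G0 = diag(1e-12, 4), hym_sd = rep(1e-9, 4),
                          curve_sd = rep(1e-12, 6))
  set.seed(5)
  des2 <- simulation_design(n_cows = 8000, n_sires = 5, n_dams = 100,
                            records_per_cow = 2)
  sim2 <- simulate_dataset(des2, tr1)
  m <- matrix(sim2$records$milk, ncol = 2, byrow = TRUE)
  expect_lt(abs(stats::cov(m[, 1], m[, 2]) - tr1$P0[2, 2]) / tr1$P0[2, 2], 0.1)
})

test_that("default simulation passes the edits losslessly; stress mode does not", {
  set.seed(6)
  des <- simulation_design(n_cows = 150, n_sires = 8, n_dams = 100)
  sim <- simulate_dataset(des)
  kept <- apply_edits(sim$records)
  expect_equal(nrow(kept), nrow(sim$records))
  expect_equal(edit_report(kept)$removed_min_records, 0)
  expect_true(all(table(sim$records$cow) == 8))   # >= 5 by construction

  set.seed(6)
  stress <- simulate_dataset(des, edit_stress = TRUE)
  keps <- apply_edits(stress$records)
  expect_lt(nrow(keps), nrow(stress$records))
})

test_that("truth file records effects consistent with the emitted records", {
  set.seed(7)
  des <- simulation_design(n_cows = 50, n_sires = 4, n_dams = 30)
  sim <- simulate_dataset(des)
  tf <- sim$truth
  expect_equal(dim(tf$breeding_values), c(50, 4))
  expect_equal(dim(tf$pe), c(50, 4))
  expect_equal(dim(tf$as_coefficients)[2], 6)
  expect_equal(dim(tf$hy_coefficients)[2], 5)
  # DIM schedule: monthly tests from a start in [5, 35]
  d <- matrix(sim$records$dim, ncol = 8, byrow = TRUE)
  expect_true(all(d[, 1] >= 5 & d[, 1] <= 35))
  expect_true(all(diff(t(d)) == 30))
})

test_that("datasets round-trip through the plain-text formats", {
  set.seed(8)
  sim <- simulate_dataset(simulation_design(n_cows = 30, n_sires = 3, n_dams = 20))
  dir <- withr::local_tempdir()
  paths <- write_dataset(sim, dir)
  rec <- readr::read_csv(paths[["records"]], show_col_types = FALSE)
  expect_equal(as.data.frame(rec), as.data.frame(sim$records), tolerance = 1e-12)
  ped <- read_pedigree(paths[["pedigree"]])
  expect_equal(dplyr::arrange(as.data.frame(ped), animal),
               dplyr::arrange(as.data.frame(sim$pedigree), animal),
               ignore_attr = TRUE)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(matrix(unlist(truth$G0), 4, 4), unname(sim$truth$truth$G0),
               tolerance = 1e-12)
})
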
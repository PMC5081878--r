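# a minimal frame with one fixed level (intercept-like) built directly
intercept_frame <- function(y, ped, cow_ids) {
  rec <- tibble::tibble(
    cow = cow_ids, herd = 1, test_year = 2012, test_month = 1,
    calving_year = 2012, calving_month = 1, age_at_calving = 24, dim = 155,
    scs = y[, 1], milk = y[, 2], fat_kg = y[, 3], protein_kg = y[, 4],
    hym = 1L, as_class = 1L, hy_class = 1L
  )
  build_model_frame(rec, ped, as_order = 1L, hy_order = 1L)
}

test_that("model frame counts levels, covariates and effect dimensions", {
  set.seed(12)
  sim <- small_dataset()
  cl <- assign_classes(apply_edits(sim$records))
  fr <- build_model_frame(cl, sim$pedigree)
  expect_equal(fr$n_records, nrow(cl))
  expect_equal(fr$n_hym, length(unique(paste(cl$herd, cl$test_year, cl$test_month))))
  expect_equal(ncol(fr$Z_as), 6)
  expect_equal(ncol(fr$Z_hy), 5)
  expect_equal(fr$n_animals, nrow(sim$pedigree))
  expect_equal(fr$n_cows, length(unique(cl$cow)))
  expect_lt(fr$n_cows, fr$n_animals)   # ancestors enter only the additive effect

  # two herds, one test month -> 2 HYM levels
  r <- make_records(10, cow = rep(paste0("c", 1:2), each = 5),
                    herd = rep(1:2, each = 5))
  r <- dplyr::mutate(r, scs = 3, fat_kg = 1, protein_kg = 1)
  ped <- ped_tbl("c1", "0", "0", "c2", "0", "0")
  fr2 <- build_model_frame(assign_classes(r), ped)
  expect_equal(fr2$n_hym, 2)

  # recorded cow missing from the pedigree is a hard error naming it
  expect_error(build_model_frame(assign_classes(r), ped_tbl("c1", "0", "0")),
               "absent from pedigree.*c2")
})

test_that("chain bookkeeping follows (length - burn-in) / thin", {
  cfg <- gibbs_config(chain_length = 200000, burn_in = 10000, thin = 10)
  expect_equal(n_retained(cfg), 19000)
  expect_error(gibbs_config(chain_length = 100, burn_in = 100), "burn_in")
  expect_error(gibbs_config(thin = 0), "thin")

  set.seed(5)
  sim <- small_dataset(n_cows = 30, n_sires = 3, n_dams = 20)
  cl <- assign_classes(apply_edits(sim$records))
  fit <- fit_gibbs(cl, sim$pedigree,
                   gibbs_config(chain_length = 230, burn_in = 30, thin = 4, seed = 2))
  expect_equal(nrow(fit$samples), 50)
  expect_equal(fit$samples$cycle[1], 34)
  expect_equal(glance(fit)$n_stored, 50)
})

test_that("identical seeds give bit-identical chains; different seeds differ", {
  set.seed(5)
  sim <- small_dataset(n_cows = 30, n_sires = 3, n_dams = 20)
  cl <- assign_classes(apply_edits(sim$records))
  fr <- build_model_frame(cl, sim$pedigree)
  cfg <- gibbs_config(chain_length = 120, burn_in = 20, thin = 2, seed = 9)
  f1 <- run_chain(fr, cfg)
  f2 <- run_chain(fr, cfg)
  expect_identical(f1$samples, f2$samples)
  f3 <- run_chain(fr, gibbs_config(chain_length = 120, burn_in = 20, thin = 2, seed = 10))
  expect_false(identical(f3$samples, f1$samples))
})

test_that("chains are resumable from checkpoints with identical continuation", {
  set.seed(6)
  sim <- small_dataset(n_cows = 25, n_sires = 3, n_dams = 15)
  cl <- assign_classes(apply_edits(sim$records))
  fr <- build_model_frame(cl, sim$pedigree)
  cfg <- gibbs_config(chain_length = 300, burn_in = 50, thin = 5, seed = 4,
                      checkpoint_every = 100)
  full <- run_chain(fr, cfg)

  ck <- withr::local_tempfile(fileext = ".rds")
  # interrupted run: only the first two segments complete
  half_cfg <- cfg
  half_cfg$chain_length <- 200L
  run_chain(fr, half_cfg, checkpoint_path = ck)
  resumed <- run_chain(fr, cfg, checkpoint_path = ck)
  expect_identical(resumed$samples, full$samples)
})

test_that("every stored covariance sample is symmetric positive definite", {
  set.seed(7)
  sim <- small_dataset(n_cows = 40, n_sires = 4, n_dams = 25)
  cl <- assign_classes(apply_edits(sim$records))
  fit <- fit_gibbs(cl, sim$pedigree,
                   gibbs_config(chain_length = 150, burn_in = 50, thin = 5, seed = 3))
  for (i in seq_len(nrow(fit$samples))) {
    cov <- sample_covariances(fit, i)
    for (M in cov) {
      expect_true(all(eigen(M, symmetric = TRUE, only.values = TRUE)$values > 0))
    }
  }
})

test_that("location sampler matches the closed-form conjugate posterior", {
  # one fixed intercept level, known covariances: posterior of the level
  # mean is N(ybar, R0 / n); compare moments of the Gibbs draws
  set.seed(11)
  n <- 40
  R0 <- diag(c(1, 4, 0.3, 0.2))
  R0[2, 4] <- R0[4, 2] <- 0.5
  mu_true <- c(3, 30, 1, 1)
  y <- matrix(stats::rnorm(n * 4), n, 4) %*% chol(R0) +
    matrix(mu_true, n, 4, byrow = TRUE)
  ped <- ped_tbl("c1", "0", "0")   # one animal so the frame is valid
  fr <- intercept_frame(y, ped, rep("c1", n))
  # zero out the nested-regression covariates so the HYM level is the
  # only fixed effect, and pin animal/PE near zero with tiny G0/P0
  fr$Z_as <- matrix(0, n, 1)
  fr$Z_hy <- matrix(0, n, 1)
  tiny <- diag(4) * 1e-8
  fit <- run_chain(fr, gibbs_config(chain_length = 22000, burn_in = 2000,
                                    thin = 2, seed = 13),
                   update_cov = FALSE,
                   init_cov = list(G0 = tiny, P0 = tiny, R0 = R0),
                   trace_location = c(1, 1))
  draws <- as.matrix(fit$location_trace)
  gls <- colMeans(y)
  post_cov <- R0 / n
  for (t in 1:4) {
    mcse <- mcse_batch_means(draws[, t])
    expect_lt(abs(mean(draws[, t]) - gls[t]), 3 * mcse + 1e-9)
    expect_lt(abs(stats::var(draws[, t]) / post_cov[t, t] - 1), 0.05)
  }
  # cross-trait posterior correlation of the draws follows R0
  expect_lt(abs(stats::cor(draws[, 2], draws[, 4]) -
                post_cov[2, 4] / sqrt(post_cov[2, 2] * post_cov[4, 4])), 0.1)
})

test_that("relabelling herds and cows leaves covariance samples unchanged", {
  set.seed(8)
  sim <- small_dataset(n_cows = 30, n_sires = 3, n_dams = 20)
  cl <- assign_classes(apply_edits(sim$records))
  fr1 <- build_model_frame(cl, sim$pedigree)
  cfg <- gibbs_config(chain_length = 100, burn_in = 20, thin = 2, seed = 21)
  f1 <- run_chain(fr1, cfg)

  rec2 <- sim$records
  rec2$herd <- rec2$herd + 100L                      # relabel herds
  rec2$cow <- sub("^C", "KUH", rec2$cow)             # relabel cows
  ped2 <- sim$pedigree
  ped2$animal <- sub("^C", "KUH", ped2$animal)
  ped2$sire <- sub("^C", "KUH", ped2$sire)
  ped2$dam <- sub("^C", "KUH", ped2$dam)
  cl2 <- assign_classes(apply_edits(rec2))
  fr2 <- build_model_frame(cl2, ped2)
  f2 <- run_chain(fr2, cfg)
  expect_identical(f1$samples, f2$samples)
})

test_that("degrees-of-freedom guard rejects impossible Wishart draws", {
  set.seed(9)
  y <- matrix(stats::rnorm(8), 2, 4)
  ped <- ped_tbl("c1", "0", "0")
  fr <- intercept_frame(y, ped, rep("c1", 2))
  cfg <- gibbs_config(chain_length = 10, burn_in = 1, thin = 1, seed = 1, nu = 0)
  expect_error(run_chain(fr, cfg), "degrees of freedom")
})

test_that("covariance draws concentrate on the cross-product scale of fixed effects", {
  # effects held fixed at simulated truth; the inverted-Wishart draws of
  # G0 must then average to the alpha cross-product scale (large-n)
  set.seed(31)
  n_anim <- 4e4
  ped <- tibble::tibble(animal = paste0("A", seq_len(n_anim)),
                        sire = NA_character_, dam = NA_character_)
  tr <- simulation_truth()
  bv <- simulate_breeding_values(ped, tr$G0)
  cows <- paste0("A", 1:100)
  y <- bv[1:100, ][rep(1:100, each = 4), ] + matrix(stats::rnorm(1600), 400, 4)
  rec <- tibble::tibble(
    cow = rep(cows, each = 4), herd = 1, test_year = 2012, test_month = 1,
    calving_year = 2012, calving_month = 1, age_at_calving = 24, dim = 155,
    scs = y[, 1], milk = y[, 2], fat_kg = y[, 3], protein_kg = y[, 4],
    hym = 1L, as_class = 1L, hy_class = 1L)
  fr <- build_model_frame(rec, ped, as_order = 1L, hy_order = 1L)
  terms_n <- c(fr$n_hym, rep(fr$n_as, 1), rep(fr$n_hy, 1), fr$n_animals, fr$n_cows)
  init_eff <- lapply(terms_n, function(nl) matrix(0, nl, 4))
  ord <- match(paste0("A", seq_len(n_anim)), fr$relationship$order)
  init_eff[[4]][ord, ] <- bv   # animal term holds the true breeding values
  fit <- run_chain(fr, gibbs_config(chain_length = 250, burn_in = 50, thin = 1,
                                    seed = 5),
                   update_location = FALSE, init_effects = init_eff)
  g_mean <- colMeans(fit$samples[paste0("g_", c("scs_scs", "milk_milk",
                                               "fat_fat", "protein_protein"))])
  Sa_scale <- colMeans(bv^2)   # founder pedigree: A-inverse is the identity
  expect_true(all(abs(g_mean / Sa_scale - 1) < 0.02))
  # residual bookkeeping: Wishart df for R0 is n_records + prior df
  expect_equal(fit$n_records, 400)
})
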
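test_that("pedigree files parse, close over unlisted parents, and reject bad rows", {
  tf <- withr::local_tempfile()
  writeLines(c("A 0 0", "B 0 0", "C A B"), tf)
  ped <- read_pedigree(tf)
  expect_equal(nrow(ped), 3)
  expect_equal(ped$sire[ped$animal == "C"], "A")
  expect_equal(ped$dam[ped$animal == "C"], "B")

  writeLines("D X 0", tf)
  ped <- read_pedigree(tf)
  expect_equal(nrow(ped), 2)
  expect_true("X" %in% ped$animal)
  expect_true(is.na(ped$sire[ped$animal == "X"]))

  writeLines("E E 0", tf)
  expect_error(read_pedigree(tf), "own parent")

  writeLines(c("A 0 0", "B 0 0", "C A 0", "C B 0"), tf)
  expect_error(read_pedigree(tf), "duplicate")

  # comma-delimited and duplicate identical rows are fine
  writeLines(c("A,0,0", "B,0,0", "C,A,B", "C,A,B"), tf)
  expect_equal(nrow(read_pedigree(tf)), 3)
})

test_that("topological order puts parents first and reports cycles", {
  ped <- ped_tbl("C", "B", "0", "B", "A", "0", "A", "0", "0")
  ord <- topological_order(ped)
  pos <- match(c("A", "B", "C"), ped$animal[ord])
  expect_true(pos[1] < pos[2] && pos[2] < pos[3])

  founders <- ped_tbl("A", "0", "0", "B", "0", "0")
  expect_equal(sort(topological_order(founders)), 1:2)

  cyc <- ped_tbl("A", "B", "0", "B", "A", "0")
  expect_error(topological_order(cyc), "cycle")
})

test_that("relationship matrix reproduces textbook values", {
  expect_equal(unname(relationship_matrix(ped_tbl("A", "0", "0", "B", "0", "0"))),
               diag(2))

  trio <- ped_tbl("S", "0", "0", "D", "0", "0", "O", "S", "D")
  A <- relationship_matrix(trio)
  expect_equal(A["O", "O"], 1)
  expect_equal(A["S", "O"], 0.5)
  expect_equal(A["D", "O"], 0.5)
  expect_equal(A["S", "D"], 0)

  # full sibs: relationship 0.5; their offspring inbred F = 0.25
  fs <- ped_tbl("S", "0", "0", "D", "0", "0",
                "X", "S", "D", "Y", "S", "D", "Z", "X", "Y")
  A <- relationship_matrix(fs)
  expect_equal(A["X", "Y"], 0.5)
  expect_equal(A["Z", "Z"], 1.25)
})

test_that("relationship matrix agrees with a gene-dropping estimate", {
  ped <- random_pedigree(16, 17, 2, seed = 31)   # 50 animals, 3 generations
  A <- relationship_matrix(ped)
  ord <- topological_order(ped)
  sire <- match(ped$sire[ord], ped$animal[ord])
  dam <- match(ped$dam[ord], ped$animal[ord])
  n <- nrow(ped)
  R <- 1e5
  set.seed(99)
  a1 <- matrix(0L, n, R)
  a2 <- matrix(0L, n, R)
  for (i in seq_len(n)) {
    if (is.na(sire[i])) {
      a1[i, ] <- 2L * i
    } else {
      pick <- stats::runif(R) < 0.5
      a1[i, ] <- ifelse(pick, a1[sire[i], ], a2[sire[i], ])
    }
    if (is.na(dam[i])) {
      a2[i, ] <- 2L * i + 1L
    } else {
      pick <- stats::runif(R) < 0.5
      a2[i, ] <- ifelse(pick, a1[dam[i], ], a2[dam[i], ])
    }
  }
  A_hat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        A_hat[i, i] <- 1 + mean(a1[i, ] == a2[i, ])
      } else {
        k <- (mean(a1[i, ] == a1[j, ]) + mean(a1[i, ] == a2[j, ]) +
              mean(a2[i, ] == a1[j, ]) + mean(a2[i, ] == a2[j, ])) / 4
        A_hat[i, j] <- A_hat[j, i] <- 2 * k
      }
    }
  }
  A_ord <- A[ped$animal[ord], ped$animal[ord]]
  expect_lt(max(abs(A_ord - A_hat)), 0.02)
})

test_that("inbreeding coefficients match the tabular diagonal", {
  ped <- random_pedigree(10, 12, 3, seed = 5)
  Fv <- inbreeding_coefficients(ped)
  A <- relationship_matrix(ped)
  expect_equal(unname(Fv[rownames(A)]), unname(diag(A) - 1), tolerance = 1e-12)
  expect_gt(max(Fv), 0)   # the fixture really contains inbred animals

  # all founders -> all zero
  founders <- ped_tbl("A", "0", "0", "B", "0", "0", "C", "0", "0")
  expect_equal(unname(inbreeding_coefficients(founders)), rep(0, 3))

  # full-sib mating offspring of non-inbred parents
  fs <- ped_tbl("S", "0", "0", "D", "0", "0",
                "X", "S", "D", "Y", "S", "D", "Z", "X", "Y")
  expect_equal(unname(inbreeding_coefficients(fs)["Z"]), 0.25)

  # cutting all parent links zeroes F
  cut <- ped_tbl("S", "0", "0", "D", "0", "0", "X", "0", "0", "Y", "0", "0", "Z", "0", "0")
  expect_equal(unname(inbreeding_coefficients(cut)), rep(0, 5))
})

test_that("A-inverse follows Henderson's rules on simple pedigrees", {
  founders <- ped_tbl("A", "0", "0", "B", "0", "0")
  expect_equal(as.matrix(a_inverse(founders)$A_inverse), diag(2),
               ignore_attr = TRUE)

  trio <- ped_tbl("S", "0", "0", "D", "0", "0", "O", "S", "D")
  Ainv <- as.matrix(a_inverse(trio)$A_inverse)
  expect_equal(Ainv["O", "O"], 2)      # 1/d with d = 1/2
  expect_equal(Ainv["O", "S"], -1)
  expect_equal(Ainv["S", "D"], 0.5)
})

test_that("A-inverse inverts the tabular A for random (inbred) pedigrees", {
  sizes <- list(c(8, 6, 1), c(20, 20, 2), c(40, 53, 3))   # up to 199 animals
  for (k in seq_along(sizes)) {
    sz <- sizes[[k]]
    ped <- random_pedigree(sz[1], sz[2], sz[3], seed = 100 + k)
    A <- relationship_matrix(ped)
    rel <- a_inverse(ped, account_inbreeding = TRUE)
    Ainv <- as.matrix(rel$A_inverse)[rownames(A), rownames(A)]
    expect_lt(max(abs(Ainv %*% A - diag(nrow(A)))), 1e-8)
    expect_lte(Matrix::nnzero(rel$A_inverse), 9 * nrow(ped))
    expect_equal(unname(rel$F[rownames(A)]), unname(diag(A) - 1), tolerance = 1e-10)
  }
})

test_that("ignoring inbreeding is exact only for non-inbred pedigrees", {
  # non-inbred: single offspring generation from distinct founders
  ped <- random_pedigree(30, 40, 1, seed = 77)
  A <- relationship_matrix(ped)
  Ainv <- as.matrix(a_inverse(ped, account_inbreeding = FALSE)$A_inverse)
  Ainv <- Ainv[rownames(A), rownames(A)]
  expect_lt(max(abs(Ainv %*% A - diag(nrow(A)))), 1e-8)

  # inbred pedigree: the no-inbreeding variant must differ from the exact one
  inb <- random_pedigree(10, 12, 3, seed = 5)
  d_exact <- Matrix::diag(a_inverse(inb, TRUE)$A_inverse)
  d_plain <- Matrix::diag(a_inverse(inb, FALSE)$A_inverse)
  expect_gt(max(abs(d_exact - d_plain)), 1e-6)
})

test_that("relationship structures persist as coordinate text", {
  ped <- random_pedigree(6, 6, 1, seed = 2)
  rel <- a_inverse(ped)
  map_f <- withr::local_tempfile()
  ainv_f <- withr::local_tempfile()
  write_relationship_structure(rel, map_f, ainv_f)
  tri <- readr::read_tsv(ainv_f, show_col_types = FALSE)
  M <- Matrix::sparseMatrix(i = tri$row, j = tri$col, x = tri$value,
                            dims = dim(rel$A_inverse), symmetric = TRUE)
  expect_equal(as.matrix(M), unname(as.matrix(rel$A_inverse)))
  map <- readr::read_tsv(map_f, show_col_types = FALSE)
  expect_equal(map$id, rel$order)
})
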
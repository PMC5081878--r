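#' Read a three-column pedigree file
#'
#' Reads a whitespace- or comma-delimited text file with columns
#' animal, sire, dam. Unknown parents are coded by a sentinel value
#' (default `"0"`). Parents that never appear in the animal column are
#' appended as founders, so the returned pedigree is closed.
#'
#' @param path Path to the pedigree file. A file with a header line
#'   starting with `animal` is accepted; otherwise the first row is data.
#' @param unknown Sentinel string marking an unknown parent.
#' @return A tibble with character columns `animal`, `sire`, `dam`
#'   (`NA` for unknown parents), one row per animal.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A 0 0", "B 0 0", "C A B"), tf)
#' read_pedigree(tf)
#' @export
read_pedigree <- function(path, unknown = "0") {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^animal\\b", lines[[1]], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (!length(lines)) stop("pedigree file is empty: ", path)
  fields <- strsplit(lines, "[,[:space:]]+")
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop("pedigree line ", bad[[1]], " does not have 3 columns: '", lines[[bad[[1]]]], "'")
  }
  m <- do.call(rbind, fields)
  ped <- tibble::tibble(animal = m[, 1], sire = m[, 2], dam = m[, 3])
  as_pedigree(ped, unknown = unknown)
}

#' Validate and close a pedigree table
#'
#' Checks the pedigree invariants (no self-parenting, no conflicting
#' duplicates), replaces the unknown-parent sentinel by `NA`, drops exact
#' duplicate rows and appends parents without own entries as founders.
#'
#' @param ped A data frame with columns `animal`, `sire`, `dam`.
#' @param unknown Sentinel for unknown parents (compared after coercion
#'   to character).
#' @return A closed pedigree tibble (`animal`, `sire`, `dam`; `NA` =
#'   unknown parent).
#' @export
as_pedigree <- function(ped, unknown = "0") {
  req <- c("animal", "sire", "dam")
  miss <- setdiff(req, names(ped))
  if (length(miss)) stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  ped <- tibble::tibble(
    animal = as.character(ped$animal),
    sire   = as.character(ped$sire),
    dam    = as.character(ped$dam)
  )
  ped$sire[ped$sire == unknown] <- NA_character_
  ped$dam[ped$dam == unknown] <- NA_character_
  if (anyNA(ped$animal) || any(ped$animal == unknown)) {
    stop("animal id equal to the unknown-parent sentinel or missing")
  }
  self <- ped$animal == ped$sire | ped$animal == ped$dam
  self[is.na(self)] <- FALSE
  if (any(self)) {
    stop("animal listed as its own parent: ", ped$animal[which(self)[1]])
  }
  ped <- dplyr::distinct(ped)
  if (anyDuplicated(ped$animal)) {
    dup <- ped$animal[duplicated(ped$animal)][[1]]
    stop("duplicate animal with conflicting parents: ", dup)
  }
  parents <- unique(stats::na.omit(c(ped$sire, ped$dam)))
  orphans <- setdiff(parents, ped$animal)
  if (length(orphans)) {
    ped <- dplyr::bind_rows(
      ped,
      tibble::tibble(animal = orphans, sire = NA_character_, dam = NA_character_)
    )
  }
  ped
}

#' Topologically order a pedigree
#'
#' Returns a permutation of row indices such that every parent precedes
#' each of its offspring. Ties are broken by original row order, so the
#' ordering is invariant under relabelling of animal identifiers.
#'
#' @param ped A closed pedigree tibble (see [as_pedigree()]).
#' @return Integer vector of row indices into `ped`, parents first.
#' @export
topological_order <- function(ped) {
  n <- nrow(ped)
  idx <- match_parents(ped)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(idx$sire[i], idx$dam[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)   # in row order: stable under relabelling
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    on_cycle <- setdiff(seq_len(n), ord)
    stop("pedigree contains a cycle involving animal: ", ped$animal[on_cycle[[1]]])
  }
  ord
}

# integer sire/dam row indices (NA = unknown)
match_parents <- function(ped) {
  list(
    sire = match(ped$sire, ped$animal),
    dam  = match(ped$dam, ped$animal)
  )
}

# pedigree reordered parents-first with integer parent indices; the
# internal representation every downstream computation uses
recode_pedigree <- function(ped) {
  ord <- topological_order(ped)
  ped <- ped[ord, , drop = FALSE]
  idx <- match_parents(ped)
  list(ped = ped, sire = idx$sire, dam = idx$dam,
       id_map = tibble::tibble(id = ped$animal, code = seq_len(nrow(ped))))
}

#' Dense additive (numerator) relationship matrix
#'
#' Tabular method: `A[i,i] = 1 + F[i]` with `F[i] = A[sire,dam]/2`, and
#' `A[i,j] = (A[j,sire] + A[j,dam])/2` for `j` preceding `i`. Intended
#' for small pedigrees (tests, oracles); use [a_inverse()] for the model.
#'
#' @param ped A closed pedigree tibble.
#' @return Dense symmetric matrix with dimnames = animal ids, in
#'   topological order.
#' @export
relationship_matrix <- function(ped) {
  rc <- recode_pedigree(ped)
  n <- nrow(rc$ped)
  A <- matrix(0, n, n, dimnames = list(rc$ped$animal, rc$ped$animal))
  s <- rc$sire
  d <- rc$dam
  for (i in seq_len(n)) {
    Fi <- if (!is.na(s[i]) && !is.na(d[i])) A[s[i], d[i]] / 2 else 0
    A[i, i] <- 1 + Fi
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s[i])) A[j, s[i]] else rep(0, i - 1L)
      ad_ <- if (!is.na(d[i])) A[j, d[i]] else rep(0, i - 1L)
      A[j, i] <- A[i, j] <- (as_ + ad_) / 2
    }
  }
  A
}

#' Inbreeding coefficients
#'
#' `F[i]` is half the additive relationship between the parents of `i`;
#' animals with an unknown parent have `F = 0`. Computed by the tabular
#' method restricted to ancestors, which is exact.
#'
#' @param ped A closed pedigree tibble.
#' @return Named numeric vector of inbreeding coefficients in the order
#'   of `ped$animal`.
#' @export
inbreeding_coefficients <- function(ped) {
  rc <- recode_pedigree(ped)
  A <- relationship_matrix(ped)
  Fv <- diag(A) - 1
  # report in the caller's original row order
  out <- Fv[match(ped$animal, rc$ped$animal)]
  names(out) <- ped$animal
  out
}

# Meuwissen & Luo (1992) style inbreeding for larger pedigrees: O(n * anc)
inbreeding_ml <- function(sire, dam) {
  n <- length(sire)
  Fv <- numeric(n)
  L <- numeric(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- 0.5 -
      0.25 * ((if (is.na(sire[i])) -1 else Fv[sire[i]]) +
              (if (is.na(dam[i]))  -1 else Fv[dam[i]]))
    if (is.na(sire[i]) || is.na(dam[i])) {
      Fv[i] <- 0
      next
    }
    # accumulate contributions of ancestors of i through both parents,
    # visiting ancestors youngest-first (parents precede offspring in index)
    L[] <- 0
    L[i] <- 1
    Fi <- -1
    stack <- i
    seen <- logical(n)
    seen[i] <- TRUE
    order_anc <- integer(0)
    while (length(stack)) {
      top <- stack[which.max(stack)]
      stack <- stack[stack != top]
      order_anc <- c(order_anc, top)
      for (p in c(sire[top], dam[top])) {
        if (!is.na(p) && !seen[p]) {
          seen[p] <- TRUE
          stack <- c(stack, p)
        }
      }
    }
    for (a in order_anc) {
      la <- L[a]
      if (la == 0) next
      for (p in c(sire[a], dam[a])) {
        if (!is.na(p)) L[p] <- L[p] + 0.5 * la
      }
      Fi <- Fi + la * la * d[a]
      L[a] <- 0
    }
    Fv[i] <- Fi
  }
  Fv
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds the inverse of `A` directly by Henderson's rules. For each
#' animal the Mendelian-sampling variance `d` is `0.5 - 0.25 (F_s + F_d)`
#' with both parents known, `0.75 - 0.25 F_p` with one parent known, and
#' `1` with no known parent (inbreeding terms dropped when
#' `account_inbreeding = FALSE`). `1/d` is added at (a,a), `-1/(2d)` at
#' (a, parent), and `1/(4d)` at each (parent, parent) combination.
#'
#' @param ped A closed pedigree tibble.
#' @param account_inbreeding If `TRUE` (default) inbreeding coefficients
#'   enter the Mendelian-sampling variances, giving the exact inverse for
#'   inbred pedigrees.
#' @return An object of class `relationship_structure`: a list with
#'   `A_inverse` (sparse symmetric [Matrix::dsCMatrix-class]), `F`
#'   (inbreeding per animal), `order` (animals in topological order) and
#'   `id_map` (tibble `id`, `code`).
#' @export
a_inverse <- function(ped, account_inbreeding = TRUE) {
  rc <- recode_pedigree(ped)
  n <- nrow(rc$ped)
  s <- rc$sire
  d_ <- rc$dam
  Fv <- if (account_inbreeding) inbreeding_ml(s, d_) else numeric(n)
  Fs <- ifelse(is.na(s), -1, Fv[ifelse(is.na(s), 1L, s)])
  Fd <- ifelse(is.na(d_), -1, Fv[ifelse(is.na(d_), 1L, d_)])
  dvec <- 0.5 - 0.25 * (Fs + Fd)
  if (any(dvec <= 0)) {
    stop("nonpositive Mendelian-sampling variance (corrupt inbreeding) for animal ",
         rc$ped$animal[which(dvec <= 0)[1]])
  }
  # vectorized triplet assembly; duplicates are summed by sparseMatrix
  inv_d <- 1 / dvec
  a <- seq_len(n)
  ii <- a; jj <- a; xx <- inv_d
  for (pcol in list(s, d_)) {
    known <- !is.na(pcol)
    ii <- c(ii, a[known], pcol[known])
    jj <- c(jj, pcol[known], a[known])
    xx <- c(xx, rep(-0.5 * inv_d[known], 2))
  }
  for (p1 in list(s, d_)) for (p2 in list(s, d_)) {
    known <- !is.na(p1) & !is.na(p2)
    ii <- c(ii, p1[known]); jj <- c(jj, p2[known]); xx <- c(xx, 0.25 * inv_d[known])
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(rc$ped$animal, rc$ped$animal))
  Ainv <- Matrix::forceSymmetric(Ainv)
  structure(
    list(A_inverse = Ainv, F = stats::setNames(Fv, rc$ped$animal),
         order = rc$ped$animal, id_map = rc$id_map,
         account_inbreeding = account_inbreeding),
    class = "relationship_structure"
  )
}

#' @method print relationship_structure
#' @export
print.relationship_structure <- function(x, ...) {
  cat("<relationship_structure> ", length(x$order), " animals, ",
      Matrix::nnzero(x$A_inverse), " nonzeros in A-inverse, mean F = ",
      signif(mean(x$F), 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a relationship structure into coordinate triplets
#'
#' @param x A `relationship_structure` from [a_inverse()].
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `value` (upper triangle,
#'   1-based codes in topological order).
#' @export
tidy.relationship_structure <- function(x, ...) {
  tr <- Matrix::mat2triplet(Matrix::triu(x$A_inverse))
  tibble::tibble(row = tr$i, col = tr$j, value = tr$x)
}

#' Write a relationship structure to plain-text files
#'
#' Persists the recoded-id map (2-column text) and the inverse
#' relationship matrix as coordinate triplets.
#'
#' @param x A `relationship_structure`.
#' @param map_path,ainv_path Output file paths (tab-separated text).
#' @return `x`, invisibly.
#' @export
write_relationship_structure <- function(x, map_path, ainv_path) {
  readr::write_tsv(x$id_map, map_path)
  readr::write_tsv(tidy.relationship_structure(x), ainv_path)
  invisible(x)
}
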
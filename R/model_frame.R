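#' Assemble the multi-trait fixed-regression model frame
#'
#' Builds the per-record design of the test-day model: one
#' herd-year-month (HYM) contemporary-group indicator, 6 Legendre
#' covariates nested in the age-season-of-calving class, 5 nested in
#' the herd-year-of-calving class, one additive genetic (animal) index
#' into the pedigree, and one permanent-environment (cow) index, with
#' the observed 4-trait vector (SCS, milk, fat, protein yields). All
#' four traits are required on every record.
#'
#' @param records Edited records with class assignments
#'   ([apply_edits()] then [assign_classes()]).
#' @param ped A closed pedigree tibble covering every recorded cow.
#' @param as_order,hy_order Number of Legendre coefficients for the
#'   age-season and herd-year curves.
#' @param account_inbreeding Passed to [a_inverse()].
#' @return An object of class `model_frame`: record-level index
#'   vectors, covariate matrices, the phenotype matrix `y`, the
#'   relationship structure, and level counts.
#' @export
build_model_frame <- function(records, ped, as_order = 6L, hy_order = 5L,
                              account_inbreeding = TRUE) {
  need <- c("scs", "milk", "fat_kg", "protein_kg", "hym", "as_class", "hy_class", "cow", "dim")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records lack column(s) ", paste(miss, collapse = ", "),
         "; run apply_edits() and assign_classes() first")
  }
  y <- cbind(scs = records$scs, milk = records$milk,
             fat = records$fat_kg, protein = records$protein_kg)
  if (anyNA(y)) stop("all four traits are required on every record")
  rel <- a_inverse(ped, account_inbreeding = account_inbreeding)
  absent <- setdiff(unique(records$cow), rel$id_map$id)
  if (length(absent)) {
    stop("recorded cow(s) absent from pedigree: ",
         paste(utils::head(absent, 10), collapse = ", "))
  }
  animal <- rel$id_map$code[match(records$cow, rel$id_map$id)]
  cow <- dense_code(records$cow)
  cow_ids <- unique(records$cow)
  Z_as <- legendre_covariates(records$dim, as_order)
  Z_hy <- legendre_covariates(records$dim, hy_order)
  structure(
    list(
      y = y,
      hym = as.integer(records$hym),
      as_class = as.integer(records$as_class),
      hy_class = as.integer(records$hy_class),
      animal = as.integer(animal),
      cow = as.integer(cow),
      Z_as = Z_as, Z_hy = Z_hy,
      n_records = nrow(y),
      n_hym = max(records$hym),
      n_as = max(records$as_class),
      n_hy = max(records$hy_class),
      n_animals = length(rel$order),
      n_cows = length(cow_ids),
      cow_ids = cow_ids,
      cow_sire = ped$sire[match(cow_ids, ped$animal)],
      cow_dam = ped$dam[match(cow_ids, ped$animal)],
      relationship = rel
    ),
    class = "model_frame"
  )
}

#' @method print model_frame
#' @export
print.model_frame <- function(x, ...) {
  cat("<model_frame> ", x$n_records, " records x 4 traits; ",
      x$n_hym, " HYM, ", x$n_as, " AS, ", x$n_hy, " HY levels; ",
      x$n_animals, " animals (", x$n_cows, " with records)\n", sep = "")
  invisible(x)
}
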
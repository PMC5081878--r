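# Shared fixture builders.

# a pedigree tibble straight from triples
ped_tbl <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  as_pedigree(tibble::tibble(animal = m[, 1], sire = m[, 2], dam = m[, 3]))
}

# random multi-generation pedigree: founders plus `gens` generations of
# random matings (possibly inbred; parents drawn from all previous animals)
random_pedigree <- function(n_founders, n_per_gen, gens, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  animal <- paste0("F", seq_len(n_founders))
  sire <- rep("0", n_founders)
  dam <- rep("0", n_founders)
  pool_m <- animal[seq_len(ceiling(n_founders / 2))]
  pool_f <- setdiff(animal, pool_m)
  for (g in seq_len(gens)) {
    ids <- paste0("G", g, "_", seq_len(n_per_gen))
    s <- sample(pool_m, n_per_gen, replace = TRUE)
    d <- sample(pool_f, n_per_gen, replace = TRUE)
    animal <- c(animal, ids)
    sire <- c(sire, s)
    dam <- c(dam, d)
    # next generation can mate within itself -> inbreeding builds up
    pool_m <- c(pool_m, ids[seq_len(floor(n_per_gen / 2))])
    pool_f <- c(pool_f, ids[(floor(n_per_gen / 2) + 1):n_per_gen])
  }
  as_pedigree(tibble::tibble(animal = animal, sire = sire, dam = dam))
}

# minimal valid record tibble; defaults give one in-range record
make_records <- function(n = 1, cow = "c1", herd = 1, test_year = 2012,
                         test_month = 6, calving_year = 2012, calving_month = 1,
                         age_at_calving = 24, dim = 100, milk = 30,
                         fat_pct = 3.3, protein_pct = 3.1, scc = 100) {
  tibble::tibble(
    cow = rep_len(cow, n), herd = rep_len(herd, n),
    test_year = rep_len(test_year, n), test_month = rep_len(test_month, n),
    calving_year = rep_len(calving_year, n),
    calving_month = rep_len(calving_month, n),
    age_at_calving = rep_len(age_at_calving, n), dim = rep_len(dim, n),
    milk = rep_len(milk, n), fat_pct = rep_len(fat_pct, n),
    protein_pct = rep_len(protein_pct, n), scc = rep_len(scc, n)
  )
}

# small simulated data set ready for model fitting
small_dataset <- function(seed = 7, n_cows = 120, n_sires = 6, n_dams = 80,
                          n_herds = 3, ...) {
  set.seed(seed)
  simulate_dataset(simulation_design(n_cows = n_cows, n_sires = n_sires,
                                     n_dams = n_dams, n_herds = n_herds, ...))
}

raw_record_fields <- c(
  "cow", "herd", "test_year", "test_month", "calving_year", "calving_month",
  "age_at_calving", "dim", "milk", "fat_pct", "protein_pct", "scc"
)
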
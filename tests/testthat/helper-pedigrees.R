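# Pedigree fixtures built in code.

# random multi-generation pedigree with discrete generations
random_pedigree <- function(n_gens = 3, per_gen = 10, p_male = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  id <- 0L
  prev_m <- integer(0); prev_f <- integer(0)
  for (g in seq_len(n_gens) - 1L) {
    n <- per_gen
    sex <- ifelse(runif(n) < p_male, "M", "F")
    # guarantee both sexes in every generation
    sex[1] <- "M"; sex[2] <- "F"
    ids <- id + seq_len(n)
    if (g == 0L) {
      rows[[g + 1L]] <- data.frame(id = ids, sire = NA_integer_, dam = NA_integer_,
                                   sex = sex, generation = g)
    } else {
      rows[[g + 1L]] <- data.frame(id = ids,
                                   sire = sample(prev_m, n, replace = TRUE),
                                   dam = sample(prev_f, n, replace = TRUE),
                                   sex = sex, generation = g)
    }
    prev_m <- ids[sex == "M"]; prev_f <- ids[sex == "F"]
    id <- id + n
  }
  new_pedigree(do.call(rbind, rows))
}

# 6-animal pedigree: offspring of two half sibs (shared sire, unrelated
# dams), F = 0.125
half_sib_mating_pedigree <- function() {
  new_pedigree(data.frame(
    id = 1:6,
    sire = c(NA, NA, NA, 1L, 1L, 4L),
    dam = c(NA, NA, NA, 2L, 3L, 5L),
    sex = c("M", "F", "F", "M", "F", "M"),
    generation = c(0L, 0L, 0L, 1L, 1L, 2L)))
}

# full-sib mating: offspring F = 0.25
full_sib_mating_pedigree <- function() {
  new_pedigree(data.frame(
    id = 1:5,
    sire = c(NA, NA, 1L, 1L, 3L),
    dam = c(NA, NA, 2L, 2L, 4L),
    sex = c("M", "F", "M", "F", "F"),
    generation = c(0L, 0L, 1L, 1L, 2L)))
}

# build a cohort_kinship for one generation of a pedigree by cohort-wise
# propagation, tracking the given extra animals
kinship_by_propagation <- function(ped, upto_gen, track = integer(0)) {
  g0 <- ped[ped$generation == 0L, ]
  k <- founder_kinship(g0$id)
  for (g in seq_len(upto_gen)) {
    k <- track_bulls(k, intersect(track, k$ids))
    co <- ped[ped$generation == g, ]
    k <- propagate_kinship(k, co$id, co$sire, co$dam)
  }
  k
}

# small scheme configuration for fast full-engine tests; keeps the full
# scheme's 10 sires of males so line conservation and the 4 cryobank bulls
# (0.4 * 10 lines) remain well defined
tiny_cfg <- function(...) {
  scheme_config(n_males = 30, n_females = 120, n_sires_of_males = 10,
                n_dams_of_males = 12, n_sires_of_females = 20,
                n_generations = 13, stage2_start = 9, ...)
}

# fabricated cohort data frame for selection tests
fake_cohort <- function(ebva_m, ebva_f, ebvb_m = rep(0, length(ebva_m)),
                        ebvb_f = rep(0, length(ebva_f)), generation = 1L) {
  nm <- length(ebva_m); nf <- length(ebva_f)
  data.frame(id = seq_len(nm + nf), sire = NA_integer_, dam = NA_integer_,
             sex = rep(c("M", "F"), c(nm, nf)), generation = generation,
             A = 0, B = 0, F = 0,
             EBVA = c(ebva_m, ebva_f), EBVB = c(ebvb_m, ebvb_f))
}
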
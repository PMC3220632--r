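test_that("pairwise recursion reproduces textbook coancestries", {
  ped <- half_sib_mating_pedigree()
  expect_equal(kinship_pair(ped, 1, 2), 0)            # distinct founders
  expect_equal(kinship_pair(ped, 1, 1), 0.5)          # non-inbred self
  expect_equal(kinship_pair(ped, 1, 4), 0.25)         # parent-offspring
  expect_equal(kinship_pair(ped, 4, 5), 0.125)        # half sibs
  expect_equal(kinship_pair(ped, 6, 6), 0.5 * (1 + 0.125))  # half-sib mating
  expect_error(kinship_pair(ped, 1, 99), "unknown")

  fs <- full_sib_mating_pedigree()
  expect_equal(inbreeding_from_parents(kinship_pair(fs, 3, 4)), 0.25)
  expect_error(inbreeding_from_parents(1.2), "coancestry")
})

test_that("parent-offspring mating gives offspring F = 0.25", {
  ped <- new_pedigree(data.frame(id = 1:3, sire = c(NA, NA, 1L), dam = c(NA, NA, 2L),
                                 sex = c("M", "F", "F"), generation = 0:2))
  # mate sire 1 with his daughter 3
  ped2 <- new_pedigree(rbind(ped, data.frame(id = 4L, sire = 1L, dam = 3L,
                                             sex = "M", generation = 3L)))
  expect_equal(kinship_pair(ped2, 1, 3), 0.25)
  expect_equal(kinship_pair(ped2, 4, 4), 0.5 * 1.25)
})

test_that("cohort propagation agrees entrywise with the pairwise oracle", {
  for (seed in c(11, 12, 13)) {
    ped <- random_pedigree(n_gens = 4, per_gen = 12, seed = seed)
    gmax <- max(ped$generation)
    k <- kinship_by_propagation(ped, gmax)
    co <- ped[ped$generation == gmax, ]
    for (a in seq_along(co$id))
      for (b in seq_len(a))
        expect_equal(k$K[a, b], kinship_pair(ped, co$id[a], co$id[b]),
                     tolerance = 1e-12)
    # F equals the parents' coancestry
    expect_equal(k$F, mapply(function(s, d) kinship_pair(ped, s, d),
                             co$sire, co$dam),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # structural invariants
    expect_true(isSymmetric(k$K, tol = 1e-12))
    expect_true(all(k$K >= 0 & k$K <= 1))
    expect_equal(diag(k$K), 0.5 * (1 + k$F), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("tracked cross-rows agree with the pairwise oracle", {
  ped <- random_pedigree(n_gens = 4, per_gen = 10, seed = 21)
  track <- ped$id[ped$generation == 1 & ped$sex == "M"][1:2]
  gmax <- max(ped$generation)
  k <- kinship_by_propagation(ped, gmax, track = track)
  co <- ped[ped$generation == gmax, ]
  for (j in seq_along(k$bank_ids))
    for (a in seq_along(co$id))
      expect_equal(k$Ct[a, j], kinship_pair(ped, co$id[a], k$bank_ids[j]),
                   tolerance = 1e-12)
  # tracked bulls can be mated back in as parents
  extra <- data.frame(id = max(ped$id) + 1:4,
                      sire = rep(k$bank_ids[1], 4), dam = co$id[co$sex == "F"][1:4],
                      sex = "M", generation = gmax + 1L)
  ped2 <- new_pedigree(rbind(as.data.frame(ped), extra))
  k2 <- propagate_kinship(k, extra$id, extra$sire, extra$dam)
  for (a in 1:4)
    for (b in 1:4)
      expect_equal(k2$K[a, b], kinship_pair(ped2, extra$id[a], extra$id[b]),
                   tolerance = 1e-12)
})

test_that("pooled in-place propagation matches the allocating version", {
  ped <- random_pedigree(n_gens = 3, per_gen = 15, seed = 31)
  k_ref <- kinship_by_propagation(ped, 2)
  pool <- cryosire:::new_kin_pool(15)
  k <- cryosire:::founder_kinship_pooled(pool, 1L, ped$id[ped$generation == 0])
  slot <- 1L
  for (g in 1:2) {
    co <- ped[ped$generation == g, ]
    slot <- if (slot == 1L) 2L else 1L
    k <- cryosire:::propagate_kinship_pooled(pool, k, co$id, co$sire, co$dam, slot)
  }
  expect_equal(k$K, k_ref$K, tolerance = 1e-15)
  expect_equal(k$F, k_ref$F, tolerance = 1e-15)
})

test_that("average kinship summarizes distinct pairs only", {
  # three full sibs from unrelated non-inbred parents: all pairs at 0.25
  ped <- new_pedigree(data.frame(id = 1:5, sire = c(NA, NA, 1L, 1L, 1L),
                                 dam = c(NA, NA, 2L, 2L, 2L),
                                 sex = c("M", "F", "M", "M", "F"),
                                 generation = c(0L, 0L, 1L, 1L, 1L)))
  k <- kinship_by_propagation(ped, 1)
  expect_equal(average_kinship(k), 0.25)
  kf <- founder_kinship(1:6)
  expect_equal(average_kinship(kf), 0)
  expect_error(average_kinship(kf, ids = 1L), "at least two")

  # brute-force oracle on a random cohort
  ped <- random_pedigree(n_gens = 3, per_gen = 20, seed = 41)
  k <- kinship_by_propagation(ped, 2)
  ids <- k$ids
  pairs <- combn(ids, 2)
  brute <- mean(apply(pairs, 2, function(p) kinship_pair(ped, p[1], p[2])))
  expect_equal(average_kinship(k), brute, tolerance = 1e-12)
  sub <- ids[1:7]
  brute_sub <- mean(apply(combn(sub, 2), 2, function(p) kinship_pair(ped, p[1], p[2])))
  expect_equal(average_kinship(k, sub), brute_sub, tolerance = 1e-12)
})

test_that("mean kinship of a candidate with a population matches brute force", {
  ped <- random_pedigree(n_gens = 3, per_gen = 14, seed = 51)
  track <- ped$id[ped$generation == 1][1:2]
  k <- kinship_by_propagation(ped, 2, track = track)
  co_ids <- k$ids
  # candidate inside the cohort
  cand <- co_ids[3]
  brute <- mean(vapply(setdiff(co_ids, cand),
                       function(j) kinship_pair(ped, cand, j), numeric(1)))
  expect_equal(mean_kinship_to_population(k, cand), brute, tolerance = 1e-12)
  # tracked candidate outside the cohort
  brute2 <- mean(vapply(co_ids, function(j) kinship_pair(ped, track[1], j), numeric(1)))
  expect_equal(mean_kinship_to_population(k, track[1]), brute2, tolerance = 1e-12)
  # unrelated founder candidate vs any population
  kf <- founder_kinship(1:5)
  expect_equal(mean_kinship_to_population(kf, 1L), 0)
  expect_error(mean_kinship_to_population(k, 10 * max(ped$id)), "candidate")
})
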
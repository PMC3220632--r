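test_that("scheme configuration validates and scales", {
  cfg <- scheme_config()
  expect_equal(cfg$n_males, 100L)
  expect_equal(cfg$n_dams_of_females, 10000L)  # no dam-to-dam selection
  expect_error(scheme_config(rho = -2), "rho")
  expect_error(scheme_config(n_sires_of_males = 200), "n_sires_of_males")
  expect_error(scheme_config(cd_male = 0), "cd_male")
  s <- scheme_config(scale = 0.1)
  expect_equal(s$n_males, 10L)
  expect_equal(s$n_females, 1000L)
  expect_equal(s$n_sires_of_females, 2L)   # floored at 2
  expect_lte(s$n_dams_of_females, s$n_females)
})

test_that("truncation selection ranks on the criterion with deterministic ties", {
  cfg <- scheme_config(n_males = 10, n_females = 20, n_sires_of_males = 3,
                       n_dams_of_males = 5, n_sires_of_females = 4)
  co <- fake_cohort(ebva_m = c(5, 1, 9, 7, 3, 3, 8, 2, 6, 4),
                    ebva_f = seq(20, 1))
  sel <- select_parents(co, "EBVA", 1, cfg)
  expect_equal(sel$sires_of_males, c(3L, 7L, 4L))
  expect_equal(sel$sires_of_females, c(3L, 7L, 4L, 9L))
  expect_equal(length(sel$dams_of_males), 5L)
  expect_equal(sel$dams_of_females, co$id[co$sex == "F"])  # all females kept
  # tie on EBVA = 3 (ids 5 and 6) broken by ascending id at the cut
  cfg2 <- scheme_config(n_males = 10, n_females = 20, n_sires_of_males = 7,
                        n_dams_of_males = 5, n_sires_of_females = 7)
  sel2 <- select_parents(co, "EBVA", 1, cfg2)
  expect_equal(sel2$sires_of_males, c(3L, 7L, 4L, 9L, 1L, 10L, 5L))

  # TMI with w_A = 1 is EBVA selection
  co$EBVB <- rnorm(nrow(co))
  expect_identical(select_parents(co, "TMI", 1, cfg),
                   select_parents(co, "EBVA", 1, cfg))
  # w_A = 0 ranks on EBVB only
  co2 <- co; co2$EBVA <- 0
  expect_identical(select_parents(co, "TMI", 0, cfg)$sires_of_males,
                   select_parents(co2, "TMI", 0, cfg)$sires_of_males)
  expect_error(select_parents(co[1:5, ], "EBVA", 1, cfg), "too small")
})

test_that("equalized male lines give one sib group per sire", {
  expect_equal(equalize_male_lines(c(4L, 9L), 6), c(4L, 4L, 4L, 9L, 9L, 9L))
  expect_error(equalize_male_lines(c(1L, 2L, 3L), 10), "divisible")
})

test_that("within-line selection conserves every paternal line", {
  cfg <- scheme_config(n_males = 12, n_females = 30, n_sires_of_males = 3,
                       n_dams_of_males = 6, n_sires_of_females = 6)
  sires <- c(101L, 102L, 103L)
  co <- fake_cohort(ebva_m = c(1, 9, 5, 2, 8, 6, 4, 3, 2, 7, 1, 5), ebva_f = rnorm(30))
  co$sire[co$sex == "M"] <- rep(sires, each = 4)
  sel <- select_parents_conserved(co, "EBVA", 1, cfg)
  males <- co[co$sex == "M", ]
  # one head per line, the within-line EBVA maximum
  expect_equal(length(sel$sires_of_males), 3L)
  expect_equal(males$sire[match(sel$sires_of_males, males$id)], sires)
  expect_equal(sel$sires_of_males, c(2L, 5L, 10L))
  # two sires of dams per line, including the head
  expect_equal(sort(sel$sires_of_females), sort(c(2L, 3L, 5L, 6L, 10L, 12L)))
  expect_true(all(sel$sires_of_males %in% sel$sires_of_females))
  # wrong line structure is rejected
  co_bad <- co; co_bad$sire[co_bad$sex == "M"] <- c(rep(sires, each = 3), rep(104L, 3))
  expect_error(select_parents_conserved(co_bad, "EBVA", 1, cfg), "paternal lines")
})

test_that("generation construction assigns parents and inherits correctly", {
  set.seed(81)
  cfg <- scheme_config(n_males = 4, n_females = 8, n_sires_of_males = 1,
                       n_dams_of_males = 1, n_sires_of_females = 1,
                       n_dams_of_females = 8)
  f <- draw_founder_pairs(12, cfg$rho)
  prev <- data.frame(id = 1:12, sire = NA_integer_, dam = NA_integer_,
                     sex = rep(c("M", "F"), c(4, 8)), generation = 0L,
                     A = f$A, B = f$B, F = 0, EBVA = 0, EBVB = 0)
  kin <- founder_kinship(prev$id)
  gen <- make_generation(prev, kin, cfg, 1L,
                         male_sires = rep(1L, 4), male_dams = rep(5L, 4),
                         female_sires = rep(2L, 8), female_dams = rep(6L, 8),
                         id_start = 13L)
  co <- gen$cohort
  expect_equal(nrow(co), 12L)
  expect_equal(unique(co$sire[co$sex == "M"]), 1L)   # single chosen pair
  expect_equal(unique(co$dam[co$sex == "M"]), 5L)
  expect_equal(co$F, rep(0, 12))
  # full sibs share both parents: coancestry 0.25; unrelated pairs 0
  expect_equal(gen$kin$K[1, 2], 0.25)
  expect_equal(gen$kin$K[1, 5], 0)
})

test_that("a small closed scheme keeps exact cohort sizes and gains on trait A", {
  cfg <- tiny_cfg()
  res <- run_replicates(build_scenario("b1"), cfg = cfg, n_replicates = 3,
                        master_seed = 5, bank_mode = "all_young_bulls")
  for (r in res$results) {
    byg <- table(factor(r$traj$generation, levels = 0:12))
    expect_true(all(byg == 3))  # bulls / cows / all rows each generation
    allA <- r$traj$mean_A[r$traj$group == "all"]
    # truncation selection on an additive trait: strong cumulative gain
    expect_gt(allA[9], allA[1] + 1)
    phi <- r$traj$mean_phi[r$traj$group == "all"]
    expect_true(all(phi >= 0 & phi <= 1))
    f <- r$traj$mean_F[r$traj$group == "all"]
    expect_true(all(f >= 0 & f < 1))
  }
})

test_that("the engine's inbreeding and kinship agree with the pedigree oracle", {
  cfg <- scheme_config(n_males = 8, n_females = 24, n_sires_of_males = 2,
                       n_dams_of_males = 6, n_sires_of_females = 4,
                       n_generations = 5, stage2_start = 4)
  set.seed(47)
  s1 <- run_stage1(cfg, bank_mode = "all_young_bulls")
  ped <- new_pedigree(do.call(rbind, lapply(s1$cohorts, function(co)
    co[, c("id", "sire", "dam", "sex", "generation")])))
  # generation-1 animals descend from unrelated founders
  expect_equal(s1$cohorts[[2]]$F, rep(0, 32))
  # every later F and the final cohort matrix match the memoized recursion
  for (g in 2:3) {
    co <- s1$cohorts[[g + 1]]
    oracle <- mapply(function(s, d) kinship_pair(ped, s, d), co$sire, co$dam)
    expect_equal(co$F, unname(oracle), tolerance = 1e-12)
  }
  k <- s1$kin
  co <- s1$cohorts[[4]]
  idx <- seq(1, 32, by = 3)
  for (a in idx)
    for (b in idx)
      expect_equal(k$K[a, b], kinship_pair(ped, co$id[a], co$id[b]),
                   tolerance = 1e-12)
})

test_that("average kinship of a closed scheme is non-decreasing in expectation", {
  cfg <- scheme_config(n_males = 10, n_females = 40, n_sires_of_males = 3,
                       n_dams_of_males = 8, n_sires_of_females = 6,
                       n_generations = 6, stage2_start = 4)
  res <- run_replicates(build_scenario("b2"), cfg = cfg, n_replicates = 30,
                        master_seed = 17)
  phi <- sapply(res$results, function(r) r$traj$mean_phi[r$traj$group == "all"])
  expect_true(all(diff(rowMeans(phi)) > -1e-9))
})

test_that("young bulls are at least as inbred as cows on average", {
  cfg <- tiny_cfg()
  res <- run_replicates(build_scenario("b1"), cfg = cfg, n_replicates = 8,
                        master_seed = 23, bank_mode = "all_young_bulls")
  fb <- sapply(res$results, function(r)
    mean(r$traj$mean_F[r$traj$group == "bulls"][6:13]))
  fc <- sapply(res$results, function(r)
    mean(r$traj$mean_F[r$traj$group == "cows"][6:13]))
  expect_gt(mean(fb - fc), 0)
})

test_that("replicates are bitwise reproducible from the master seed", {
  cfg <- tiny_cfg()
  scens <- list(b3 = build_scenario("b3"), d2 = build_scenario("d2"))
  a <- run_replicates(scens, cfg = cfg, n_replicates = 2, master_seed = 7,
                      bank_mode = "all_young_bulls")
  b <- run_replicates(scens, cfg = cfg, n_replicates = 2, master_seed = 7,
                      bank_mode = "all_young_bulls")
  expect_identical(a$b3$results[[1]]$traj, b$b3$results[[1]]$traj)
  expect_identical(a$d2$results[[2]]$traj, b$d2$results[[2]]$traj)
  expect_identical(a$b3$results[[1]]$bank, b$b3$results[[1]]$bank)
  # different seeds diverge
  c <- run_replicates(scens, cfg = cfg, n_replicates = 1, master_seed = 8,
                      bank_mode = "all_young_bulls")
  expect_false(identical(a$b3$results[[1]]$traj, c$b3$results[[1]]$traj))
})

test_that("scenarios share identical stage-1 histories within a replicate", {
  cfg <- tiny_cfg()
  scens <- list(b1 = build_scenario("b1"), d1 = build_scenario("d1"))
  res <- run_replicates(scens, cfg = cfg, n_replicates = 2, master_seed = 31,
                        bank_mode = "all_young_bulls")
  s1 <- res$b1$results[[1]]$traj
  s2 <- res$d1$results[[1]]$traj
  expect_identical(s1[s1$generation <= 8, ], s2[s2$generation <= 8, ])
})

test_that("cryobank-free scenarios have no cryobank genes, d-scenarios use stored bulls", {
  cfg <- tiny_cfg()
  res <- run_replicates(list(b2 = build_scenario("b2"), d3 = build_scenario("d3")),
                        cfg = cfg, n_replicates = 2, master_seed = 13,
                        bank_mode = "all_young_bulls")
  for (r in res$b2$results) expect_equal(unname(r$contribution), c(0, 0))
  for (r in res$d3$results) {
    expect_equal(nrow(r$used_bulls), 4L)
    # line conservation forces cryobank genes to persist
    expect_gt(r$contribution[[2]], 0.01)
  }
})

test_that("male-line conservation equalizes sib-group sizes", {
  cfg <- tiny_cfg()
  res <- run_replicates(build_scenario("d2"), cfg = cfg, n_replicates = 2,
                        master_seed = 37, bank_mode = "all_young_bulls",
                        keep_pedigree = TRUE)
  for (r in res$results) {
    ped <- r$pedigree
    for (g in 10:12) {
      males <- ped[ped$generation == g & ped$sex == "M", ]
      expect_equal(as.integer(table(males$sire)),
                   rep(cfg$n_males %/% cfg$n_sires_of_males, cfg$n_sires_of_males))
    }
    expect_equal(r$progeny$sd_male[r$progeny$generation %in% 9:12], rep(0, 4))
  }
})
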
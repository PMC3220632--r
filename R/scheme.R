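#' Truncation selection of the four parent paths
#'
#' Ranks candidates on the chosen criterion (EBVA, or the total merit index
#' with weight `w_a` on trait A) in descending order, ties broken by
#' ascending id, and returns the four selected parent lists: sires of males,
#' sires of females, dams of males, dams of females. With the default
#' configuration the dam-to-dam path retains every female.
#'
#' @param cohort a cohort data frame (one generation of animals).
#' @param criterion `"EBVA"` or `"TMI"`.
#' @param w_a weight on trait A when `criterion = "TMI"`.
#' @param cfg a [scheme_config()].
#' @return A list of id vectors `sires_of_males`, `sires_of_females`,
#'   `dams_of_males`, `dams_of_females`, each ordered best first.
#' @export
select_parents <- function(cohort, criterion = c("EBVA", "TMI"), w_a = 1, cfg) {
  criterion <- match.arg(criterion)
  val <- if (criterion == "EBVA") cohort$EBVA
         else total_merit_index(cohort$EBVA, cohort$EBVB, w_a)
  m <- cohort$sex == "M"
  if (sum(m) < max(cfg$n_sires_of_males, cfg$n_sires_of_females) ||
      sum(!m) < max(cfg$n_dams_of_males, cfg$n_dams_of_females))
    stop("cohort too small for the configured parent counts")
  male_ids <- cohort$id[m][order(-val[m], cohort$id[m])]
  female_ids <- cohort$id[!m][order(-val[!m], cohort$id[!m])]
  list(sires_of_males = male_ids[seq_len(cfg$n_sires_of_males)],
       sires_of_females = male_ids[seq_len(cfg$n_sires_of_females)],
       dams_of_males = female_ids[seq_len(cfg$n_dams_of_males)],
       dams_of_females = female_ids[seq_len(cfg$n_dams_of_females)])
}

#' Within-line selection under male-line conservation
#'
#' When male lines are conserved, the male cohort consists of equal-sized
#' paternal sib groups. Within each line the son with the best EBVA becomes
#' the next sire of sires and the two best become sires of dams (the best
#' serving on both paths), so each paternal line keeps exactly one
#' sire-of-sires slot regardless of across-line merit. Dams of males are
#' still selected by truncation on the criterion.
#'
#' @inheritParams select_parents
#' @return The same list structure as [select_parents()].
#' @export
select_parents_conserved <- function(cohort, criterion = c("EBVA", "TMI"),
                                     w_a = 1, cfg) {
  criterion <- match.arg(criterion)
  males <- cohort[cohort$sex == "M", , drop = FALSE]
  lines <- split(seq_len(nrow(males)), males$sire)
  if (length(lines) != cfg$n_sires_of_males)
    stop("male cohort has ", length(lines), " paternal lines, expected ",
         cfg$n_sires_of_males)
  if (2L * length(lines) != cfg$n_sires_of_females)
    stop("line conservation needs n_sires_of_females = 2 * n_sires_of_males")
  heads <- integer(0); pairs <- integer(0)
  for (ln in lines) {
    ord <- ln[order(-males$EBVA[ln], males$id[ln])]
    heads <- c(heads, males$id[ord[1L]])
    pairs <- c(pairs, males$id[ord[1:2]])
  }
  val <- if (criterion == "EBVA") cohort$EBVA
         else total_merit_index(cohort$EBVA, cohort$EBVB, w_a)
  f <- cohort$sex == "F"
  female_ids <- cohort$id[f][order(-val[f], cohort$id[f])]
  list(sires_of_males = heads,
       sires_of_females = pairs,
       dams_of_males = female_ids[seq_len(cfg$n_dams_of_males)],
       dams_of_females = female_ids[seq_len(cfg$n_dams_of_females)])
}

#' Equalised sire assignment for male-line conservation
#'
#' Assigns the male calves of a generation to sires in equal-sized paternal
#' sib groups (the "conservation of male lines" option): each sire receives
#' exactly `n_offspring / length(sire_ids)` sons.
#'
#' @param sire_ids ids of the sires of males.
#' @param n_offspring number of male calves to create.
#' @return An integer vector of length `n_offspring` with the sire of each calf.
#' @export
equalize_male_lines <- function(sire_ids, n_offspring) {
  per <- n_offspring / length(sire_ids)
  if (per != as.integer(per))
    stop("male cohort size must be divisible by the number of sires of males")
  rep(as.integer(sire_ids), each = as.integer(per))
}

assign_random <- function(ids, n) ids[sample.int(length(ids), n, replace = TRUE)]

# lookup table of potential parents (previous cohort plus, at the cryobank
# generation, the stored bulls)
parent_table <- function(prev_cohort, extra = NULL) {
  tab <- prev_cohort[, c("id", "A", "B", "F")]
  if (!is.null(extra)) tab <- rbind(tab, extra[, c("id", "A", "B", "F")])
  tab
}

#' Create one offspring generation
#'
#' Builds the calves of generation `g` from fully specified per-calf parent
#' assignments: propagates the cohort kinship matrix (giving each calf's
#' inbreeding coefficient), draws true genetic values under the
#' inbreeding-adjusted bivariate infinitesimal model, and simulates EBVs at
#' the sex-specific accuracy.
#'
#' @param prev_cohort the parent cohort data frame.
#' @param kin the parent cohort's `cohort_kinship`.
#' @param cfg a [scheme_config()].
#' @param g generation index of the offspring.
#' @param male_sires,male_dams parent ids for each of the `cfg$n_males` male
#'   calves.
#' @param female_sires,female_dams parent ids for each female calf.
#' @param id_start first id to assign.
#' @param extra_parents optional data frame (`id`, `A`, `B`, `F`) of parents
#'   outside the previous cohort (cryobank bulls).
#' @return A list with the new `cohort` data frame and its `kin` object.
#' @export
make_generation <- function(prev_cohort, kin, cfg, g,
                            male_sires, male_dams, female_sires, female_dams,
                            id_start, extra_parents = NULL,
                            .pool = NULL, .out_slot = NULL) {
  nM <- cfg$n_males; nF <- cfg$n_females
  stopifnot(length(male_sires) == nM, length(male_dams) == nM,
            length(female_sires) == nF, length(female_dams) == nF)
  ids <- id_start + seq_len(nM + nF) - 1L
  sires <- c(male_sires, female_sires)
  dams <- c(male_dams, female_dams)
  kin2 <- if (is.null(.pool)) propagate_kinship(kin, ids, sires, dams)
          else propagate_kinship_pooled(.pool, kin, ids, sires, dams, .out_slot)
  tab <- parent_table(prev_cohort, extra_parents)
  si <- match(sires, tab$id); di <- match(dams, tab$id)
  if (anyNA(si) || anyNA(di)) stop("unknown parent id")
  tp <- offspring_genetic_values(tab$A[si], tab$B[si], tab$A[di], tab$B[di],
                                 tab$F[si], tab$F[di], cfg$rho)
  cd <- rep(c(cfg$cd_male, cfg$cd_female), c(nM, nF))
  ebv <- simulate_ebv(tp$A, tp$B, cd)
  cohort <- data.frame(id = ids, sire = as.integer(sires), dam = as.integer(dams),
                       sex = rep(c("M", "F"), c(nM, nF)), generation = g,
                       A = tp$A, B = tp$B, F = kin2$F,
                       EBVA = ebv$EBVA, EBVB = ebv$EBVB)
  list(cohort = cohort, kin = kin2)
}

traj_rows <- function(cohort, kin) {
  grp <- list(bulls = cohort$sex == "M", cows = cohort$sex == "F",
              all = rep(TRUE, nrow(cohort)))
  do.call(rbind, lapply(names(grp), function(gname) {
    sel <- grp[[gname]]
    data.frame(generation = cohort$generation[1L], group = gname,
               mean_A = mean(cohort$A[sel]), mean_B = mean(cohort$B[sel]),
               mean_F = mean(cohort$F[sel]),
               mean_phi = mean_offdiag_cpp(kin$K, which(sel)))
  }))
}

progeny_sd_row <- function(g, male_sires, sel_som, female_sires, sel_sof) {
  data.frame(generation = g,
             sd_male = sd(tabulate(match(male_sires, sel_som), length(sel_som))),
             sd_female = sd(tabulate(match(female_sires, sel_sof), length(sel_sof))))
}

#' Run stage 1 of the breeding scheme
#'
#' Simulates the base population and the stage-1 generations (selection on
#' EBVA only on all selected paths) while applying the cryobank sampling
#' policy: rules (i)-(ii) to every young-bull cohort up to two generations
#' before stage 2 starts, and rule (iii), with its one-generation lag, to
#' sires of sires whose assessment still falls within stage 1. With
#' `bank_mode = "all_young_bulls"` every eligible young bull is stored
#' instead.
#'
#' Consumes the R global random number stream; seed it (or use
#' [run_replicates()]) for reproducibility.
#'
#' @param cfg a [scheme_config()].
#' @param bank_mode `"french_rules"` (default) or `"all_young_bulls"`.
#' @return An object of class `breed_stage1`: cohorts, the final
#'   `cohort_kinship` (with all banked bulls tracked), the cryobank,
#'   trajectory and progeny-dispersion tables.
#' @export
run_stage1 <- function(cfg = scheme_config(), bank_mode = c("french_rules", "all_young_bulls"),
                       .pool = NULL) {
  bank_mode <- match.arg(bank_mode)
  nM <- cfg$n_males; nF <- cfg$n_females
  if (is.null(.pool)) .pool <- new_kin_pool(nM + nF)
  g_last <- cfg$stage2_start - 1L          # last stage-1 generation
  rule12_last <- g_last - 1L               # rules i-ii eligibility window
  rule3_last_birth <- g_last - 2L          # rule iii: birth generations 0..this

  tp <- draw_founder_pairs(nM + nF, cfg$rho)
  sex <- rep(c("M", "F"), c(nM, nF))
  ebv <- simulate_ebv(tp$A, tp$B, ifelse(sex == "M", cfg$cd_male, cfg$cd_female))
  cohort <- data.frame(id = seq_len(nM + nF), sire = NA_integer_, dam = NA_integer_,
                       sex = sex, generation = 0L, A = tp$A, B = tp$B, F = 0,
                       EBVA = ebv$EBVA, EBVB = ebv$EBVB)
  kin <- founder_kinship_pooled(.pool, 1L, cohort$id)
  bank <- empty_bank()
  cohorts <- vector("list", cfg$n_generations)
  cohorts[[1L]] <- cohort
  traj <- list(traj_rows(cohort, kin))
  progeny <- list()

  flag_birth_rules <- function(chort, g) {
    males <- chort[chort$sex == "M", , drop = FALSE]
    if (bank_mode == "all_young_bulls") sample_all_young_bulls(males)
    else sample_rules_i_ii(males, cfg$cryo_thresh_A, cfg$cryo_thresh_B)
  }
  if (rule12_last >= 0L) bank <- bank_add(bank, flag_birth_rules(cohort, 0L))

  last_sires_of_males <- NULL  # the sires that produced the current cohort's males
  for (g in seq_len(g_last)) {
    sel <- select_parents(cohort, "EBVA", 1, cfg)

    # rule iii: sires of sires that produced this cohort, no son selected now
    if (!is.null(last_sires_of_males) && bank_mode == "french_rules") {
      birth_g <- g - 2L
      if (birth_g >= 0L && birth_g <= rule3_last_birth) {
        prev_cohort <- cohorts[[g]]   # generation g-1 (list is 1-based)
        sires_df <- male_archive[match(last_sires_of_males, male_archive$id), , drop = FALSE]
        bank <- bank_add(bank, sample_rule_iii(
          sires_df, prev_cohort[prev_cohort$sex == "M", , drop = FALSE],
          union(sel$sires_of_males, sel$sires_of_females)))
      }
    }

    # start tracking this generation's banked bulls and sires of sires
    newly_banked <- intersect(bank$bull_id, cohort$id)
    kin <- track_bulls(kin, union(newly_banked, sel$sires_of_males))

    male_sires <- assign_random(sel$sires_of_males, nM)
    male_dams <- assign_random(sel$dams_of_males, nM)
    female_sires <- assign_random(sel$sires_of_females, nF)
    female_dams <- assign_random(sel$dams_of_females, nF)
    progeny[[g]] <- progeny_sd_row(g, male_sires, sel$sires_of_males,
                                   female_sires, sel$sires_of_females)

    gen <- make_generation(cohort, kin, cfg, g, male_sires, male_dams,
                           female_sires, female_dams,
                           id_start = cohort$id[nrow(cohort)] + 1L,
                           .pool = .pool, .out_slot = 1L + (g %% 2L))
    male_archive <- if (g == 1L) cohort[cohort$sex == "M", c("id", "generation", "EBVA", "EBVB", "A", "B", "F")]
                    else rbind(male_archive,
                               cohort[cohort$sex == "M", c("id", "generation", "EBVA", "EBVB", "A", "B", "F")])
    cohort <- gen$cohort
    kin <- gen$kin
    cohorts[[g + 1L]] <- cohort
    traj[[g + 1L]] <- traj_rows(cohort, kin)
    if (g <= rule12_last) bank <- bank_add(bank, flag_birth_rules(cohort, g))
    last_sires_of_males <- sel$sires_of_males
  }

  structure(list(cfg = cfg, bank_mode = bank_mode, cohorts = cohorts[seq_len(g_last + 1L)],
                 kin = kin, bank = bank,
                 traj = do.call(rbind, traj),
                 progeny = do.call(rbind, progeny)),
            class = "breed_stage1")
}

#' Run stage 2 of the breeding scheme under a scenario
#'
#' Extends a stage-1 state to the final generation under a scenario from the
#' grid: optional one-time use of 4 cryobank bulls (chosen by highest total
#' merit index or lowest mean kinship with the current population) to sire a
#' fraction of the first stage-2 male cohort, an optional switch of the
#' selection criterion from EBVA to the total merit index, and optional
#' conservation of male lines (equal paternal sib groups with within-line
#' selection of the sire paths).
#'
#' @param stage1 a `breed_stage1` object.
#' @param scenario a [build_scenario()] configuration.
#' @param keep_pedigree keep the full pedigree in the result (default FALSE;
#'   the expected cryobank gene contributions are always computed before the
#'   pedigree is dropped).
#' @return An object of class `breed_replicate` with the full trajectory
#'   table (generations 0 to the end), progeny dispersions, the cryobank, the
#'   bulls used and their expected gene contributions.
#' @export
run_stage2 <- function(stage1, scenario, keep_pedigree = FALSE, .pool = NULL) {
  cfg <- stage1$cfg
  nM <- cfg$n_males; nF <- cfg$n_females
  g0 <- cfg$stage2_start
  if (is.null(.pool)) .pool <- new_kin_pool(nM + nF)
  # never write into the buffer holding the incoming stage-1 matrix, so one
  # stage-1 state can branch into several stage-2 scenarios
  s1_slot <- if (is.null(stage1$kin$slot)) 0L else stage1$kin$slot
  free_slots <- setdiff(seq_along(.pool$bufs), s1_slot)[1:2]
  cohort <- stage1$cohorts[[length(stage1$cohorts)]]
  kin <- stage1$kin
  cohorts <- stage1$cohorts
  traj <- list(stage1$traj)
  progeny <- list(stage1$progeny)

  used <- NULL
  extra_parents <- NULL
  fraction <- scenario$fraction_cryobank_sons
  if (fraction > 0) {
    used <- choose_cryobank_bulls(stage1$bank, scenario$cryobank_choice, k = 4,
                                  kin = kin, w_b = scenario$w_b)
    kin <- prune_tracked_bulls(kin, used$bull_id)
    extra_parents <- data.frame(id = used$bull_id, A = used$A, B = used$B, F = used$F)
  } else {
    kin <- prune_tracked_bulls(kin, integer(0))
  }

  crit <- scenario$stage2_criterion
  w_a <- 1 - scenario$w_b
  cryo_links <- data.frame(parent = integer(), offspring = integer())

  for (g in g0:(cfg$n_generations - 1L)) {
    conserved_cohort <- scenario$male_line_conservation && g > g0
    sel <- if (conserved_cohort) select_parents_conserved(cohort, crit, w_a, cfg)
           else select_parents(cohort, crit, w_a, cfg)

    if (g == g0 && fraction > 0 && !scenario$male_line_conservation) {
      n_cryo <- as.integer(round(fraction * nM))
      male_sires <- c(assign_random(used$bull_id, n_cryo),
                      assign_random(sel$sires_of_males, nM - n_cryo))
      male_sire_list <- c(used$bull_id, sel$sires_of_males)
    } else if (g == g0 && fraction > 0 && scenario$male_line_conservation) {
      # conserve exactly n_sires_of_males lines: each cryobank bull heads one
      # line and the best regular sires head the remaining lines
      per_line <- nM %/% cfg$n_sires_of_males
      n_cryo_lines <- as.integer(round(fraction * cfg$n_sires_of_males))
      if (n_cryo_lines != nrow(used))
        stop("line conservation needs fraction * n_sires_of_males cryobank bulls")
      reg <- sel$sires_of_males[seq_len(cfg$n_sires_of_males - n_cryo_lines)]
      male_sires <- c(equalize_male_lines(used$bull_id, n_cryo_lines * per_line),
                      equalize_male_lines(reg, (cfg$n_sires_of_males - n_cryo_lines) * per_line))
      male_sire_list <- c(used$bull_id, reg)
    } else if (scenario$male_line_conservation) {
      male_sires <- equalize_male_lines(sel$sires_of_males, nM)
      male_sire_list <- sel$sires_of_males
    } else {
      male_sires <- assign_random(sel$sires_of_males, nM)
      male_sire_list <- sel$sires_of_males
    }
    male_dams <- assign_random(sel$dams_of_males, nM)
    female_sires <- assign_random(sel$sires_of_females, nF)
    female_dams <- assign_random(sel$dams_of_females, nF)
    progeny[[length(progeny) + 1L]] <-
      progeny_sd_row(g, male_sires, male_sire_list,
                     female_sires, sel$sires_of_females)

    gen <- make_generation(cohort, kin, cfg, g, male_sires, male_dams,
                           female_sires, female_dams,
                           id_start = cohort$id[nrow(cohort)] + 1L,
                           extra_parents = if (g == g0) extra_parents else NULL,
                           .pool = .pool, .out_slot = free_slots[1L + (g - g0) %% 2L])
    if (g == g0 && fraction > 0) {
      calves <- gen$cohort[gen$cohort$sire %in% used$bull_id, , drop = FALSE]
      cryo_links <- data.frame(parent = calves$sire, offspring = calves$id)
    }
    cohort <- gen$cohort
    kin <- gen$kin
    cohorts[[g + 1L]] <- cohort
    traj[[length(traj) + 1L]] <- traj_rows(cohort, kin)
  }

  ped <- new_pedigree(do.call(rbind, lapply(cohorts, function(co)
    co[, c("id", "sire", "dam", "sex", "generation")])))
  contrib <- expected_contribution(ped, cryo_links)
  gen_mean <- function(g) {
    rows <- ped$generation == g
    if (!any(rows)) NA_real_ else mean(contrib[rows])
  }
  contribution <- setNames(c(gen_mean(g0 + 1L), gen_mean(cfg$n_generations - 1L)),
                           paste0("gen", c(g0 + 1L, cfg$n_generations - 1L)))

  structure(list(scenario = scenario, cfg = cfg, bank_mode = stage1$bank_mode,
                 traj = do.call(rbind, traj),
                 progeny = do.call(rbind, progeny),
                 bank = stage1$bank, used_bulls = used,
                 contribution = contribution,
                 pedigree = if (keep_pedigree) ped else NULL),
            class = "breed_replicate")
}

#' Run the full breeding scheme once
#'
#' Convenience wrapper: seeds the RNG, runs stage 1 and then stage 2 under
#' the given scenario.
#'
#' @param scenario a [build_scenario()] configuration.
#' @param cfg a [scheme_config()].
#' @param seed integer seed for the replicate.
#' @param keep_pedigree keep the full pedigree in the result.
#' @return A `breed_replicate` object.
#' @export
run_scheme <- function(scenario, cfg = scheme_config(), seed = 1L,
                       keep_pedigree = FALSE) {
  res <- run_replicates(scenario, cfg = cfg, n_replicates = 1L,
                        master_seed = seed, bank_mode = scenario$bank_mode,
                        keep_pedigree = keep_pedigree)
  res$results[[1L]]
}
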
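#' Scenario definitions
#'
#' The six stage-2 scenarios. Scenarios "b" redirect the selection goal
#' towards the deteriorated functional trait B; scenarios "d" aim at genetic
#' diversity while trait A remains the breeding goal:
#'
#' * `b1`: 4 cryobank bulls with the highest TMI sire 40% of the first
#'   stage-2 male cohort; selection stays on EBVA.
#' * `b2`: no cryobank bulls; stage-2 selection switches to the TMI
#'   (`w_B = 0.5`).
#' * `b3`: both: cryobank bulls by highest TMI, 40% of sons, TMI selection.
#' * `d1`: 4 cryobank bulls with the lowest mean kinship with the current
#'   population sire 40% of sons; selection stays on EBVA.
#' * `d2`: no cryobank bulls; male lines are conserved (equal paternal sib
#'   groups, within-line selection of the sire paths).
#' * `d3`: both: minimum-kinship cryobank bulls and male-line conservation.
#'
#' @param code scenario code, one of `"b1"`, `"b2"`, `"b3"`, `"d1"`, `"d2"`,
#'   `"d3"`.
#' @param w_b weight of trait B in the total merit index wherever the TMI is
#'   used (selection criterion and/or cryobank-bull choice); default 0.5.
#' @param fraction override of the fraction of first-stage-2 male calves
#'   sired by cryobank bulls (0, 0.4 or 0.8).
#' @param bank_mode `"french_rules"` (default) or `"all_young_bulls"`.
#' @return A `scenario_config` object.
#' @export
build_scenario <- function(code, w_b = NULL, fraction = NULL, bank_mode = NULL) {
  grid <- list(
    b1 = list(cryobank_choice = "best_TMI", fraction_cryobank_sons = 0.4,
              stage2_criterion = "EBVA", male_line_conservation = FALSE),
    b2 = list(cryobank_choice = "none", fraction_cryobank_sons = 0,
              stage2_criterion = "TMI", male_line_conservation = FALSE),
    b3 = list(cryobank_choice = "best_TMI", fraction_cryobank_sons = 0.4,
              stage2_criterion = "TMI", male_line_conservation = FALSE),
    d1 = list(cryobank_choice = "min_mean_kinship", fraction_cryobank_sons = 0.4,
              stage2_criterion = "EBVA", male_line_conservation = FALSE),
    d2 = list(cryobank_choice = "none", fraction_cryobank_sons = 0,
              stage2_criterion = "EBVA", male_line_conservation = TRUE),
    d3 = list(cryobank_choice = "min_mean_kinship", fraction_cryobank_sons = 0.4,
              stage2_criterion = "EBVA", male_line_conservation = TRUE))
  if (!code %in% names(grid)) stop("unknown scenario code: ", code)
  sc <- grid[[code]]
  sc$code <- code
  sc$w_b <- if (is.null(w_b)) 0.5 else w_b
  if (sc$w_b < 0 || sc$w_b > 1) stop("invalid 'w_b': must lie in [0, 1]")
  if (!is.null(fraction)) {
    if (fraction < 0 || fraction > 1) stop("invalid 'fraction': must lie in [0, 1]")
    sc$fraction_cryobank_sons <- fraction
    if (fraction == 0) sc$cryobank_choice <- "none"
  }
  sc$bank_mode <- if (is.null(bank_mode)) "french_rules" else
    match.arg(bank_mode, c("french_rules", "all_young_bulls"))
  structure(sc, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario %s> cryobank: %s (%d%% of sons), stage-2 criterion: %s%s, w_B = %g\n",
              x$code, x$cryobank_choice,
              round(100 * x$fraction_cryobank_sons), x$stage2_criterion,
              if (x$male_line_conservation) " + male-line conservation" else "",
              x$w_b))
  invisible(x)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  expr
}

#' Run replicates of one or several scenarios
#'
#' Runs `n_replicates` independent replicates. Each replicate receives its
#' own L'Ecuyer-CMRG random stream derived from `master_seed`, so results are
#' reproducible and independent of the number of replicates run before them.
#' When several scenarios are given, every replicate runs stage 1 once and
#' branches into each scenario's stage 2 on separate sub-streams, so the
#' scenarios share identical stage-1 histories within a replicate (as in the
#' study design, where scenarios do not differ over the stage-1 generations).
#'
#' @param scenarios a `scenario_config` or a list of them.
#' @param cfg a [scheme_config()].
#' @param n_replicates number of replicates (>= 1).
#' @param master_seed integer master seed.
#' @param bank_mode cryobank sampling mode for stage 1; defaults to the mode
#'   of the first scenario.
#' @param keep_pedigree keep full pedigrees in the results.
#' @return For a single scenario, a `breed_replicates` object (fields
#'   `scenario`, `cfg`, `results`, `master_seed`); for a list, a named list
#'   of such objects sharing stage-1 histories.
#' @export
run_replicates <- function(scenarios, cfg = scheme_config(), n_replicates = 20L,
                           master_seed = 1L, bank_mode = NULL,
                           keep_pedigree = FALSE) {
  single <- inherits(scenarios, "scenario_config")
  if (single) scenarios <- list(scenarios)
  if (!length(scenarios)) stop("no scenarios given")
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, "", "code")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  if (is.null(bank_mode)) bank_mode <- scenarios[[1L]]$bank_mode

  out <- lapply(scenarios, function(s) vector("list", n_replicates))
  pool <- new_kin_pool(cfg$n_males + cfg$n_females)
  with_preserved_rng({
    old_kind <- RNGkind("L'Ecuyer-CMRG")
    on.exit(RNGkind(old_kind[1L]), add = TRUE)
    set.seed(as.integer(master_seed))
    stream <- get(".Random.seed", globalenv())
    for (r in seq_len(n_replicates)) {
      stream <- parallel::nextRNGStream(stream)
      assign(".Random.seed", stream, globalenv())
      stage1 <- run_stage1(cfg, bank_mode, .pool = pool)
      sub <- stream
      for (j in seq_along(scenarios)) {
        sub <- parallel::nextRNGSubStream(sub)
        assign(".Random.seed", sub, globalenv())
        rep_res <- run_stage2(stage1, scenarios[[j]], keep_pedigree = keep_pedigree,
                              .pool = pool)
        rep_res$replicate <- r
        out[[j]][[r]] <- rep_res
      }
    }
  })
  wrap <- function(j) structure(list(scenario = scenarios[[j]], cfg = cfg,
                                     bank_mode = bank_mode,
                                     master_seed = as.integer(master_seed),
                                     results = out[[j]]),
                                class = "breed_replicates")
  res <- lapply(seq_along(scenarios), wrap)
  names(res) <- names(scenarios)
  if (single) res[[1L]] else res
}

#' Aggregate replicate results
#'
#' Across-replicate means and standard deviations of every trajectory point,
#' the cryobank composition table (per sampling rule: bulls per replicate,
#' share of the bank, mean birth generation), the usage table (share of used
#' bulls per sampling rule, their birth generation, and the expected cryobank
#' gene contributions), and the progeny-count dispersions.
#'
#' @param x a `breed_replicates` object.
#' @return A `breed_summary` object.
#' @export
aggregate_replicates <- function(x) {
  if (!inherits(x, "breed_replicates")) stop("need a 'breed_replicates' object")
  reps <- x$results
  if (!length(reps)) stop("no replicates to aggregate")
  n <- length(reps)
  sd0 <- function(v) if (length(v) > 1L) sd(v) else 0

  tr0 <- reps[[1L]]$traj
  vals <- vapply(reps, function(r) as.matrix(r$traj[, c("mean_A", "mean_B", "mean_F", "mean_phi")]),
                 matrix(0, nrow(tr0), 4L))
  traj <- data.frame(tr0[, c("generation", "group")],
                     apply(vals, c(1, 2), mean),
                     sd = apply(vals, c(1, 2), sd0))
  names(traj) <- c("generation", "group", "mean_A", "mean_B", "mean_F", "mean_phi",
                   "sd_A", "sd_B", "sd_F", "sd_phi")

  rules <- c("high_EBVA", "low_EBVA", "high_EBVB", "unused_sire_of_sires")
  per_rep <- function(f) vapply(reps, f, numeric(1))
  bank_stats <- lapply(rules, function(rl) {
    cnt <- per_rep(function(r) sum(r$bank[[rl]]))
    tot <- per_rep(function(r) nrow(r$bank))
    bg <- per_rep(function(r) {
      b <- r$bank$birth_generation[r$bank[[rl]]]
      if (length(b)) mean(b) else NA_real_
    })
    data.frame(rule = rl, n_bulls = mean(cnt), n_bulls_sd = sd0(cnt),
               pct_of_bank = 100 * mean(cnt / pmax(tot, 1)),
               birth_generation = mean(bg, na.rm = TRUE),
               birth_generation_sd = sd0(bg[!is.na(bg)]))
  })
  bank_total <- per_rep(function(r) nrow(r$bank))
  bank_table <- do.call(rbind, bank_stats)

  has_use <- !is.null(reps[[1L]]$used_bulls)
  usage_table <- NULL
  if (has_use) {
    use_stats <- lapply(rules, function(rl) {
      pct <- per_rep(function(r) 100 * mean(r$used_bulls[[rl]]))
      data.frame(rule = rl, pct_used = mean(pct), pct_used_sd = sd0(pct))
    })
    bg <- per_rep(function(r) mean(r$used_bulls$birth_generation))
    usage_table <- list(by_rule = do.call(rbind, use_stats),
                        birth_generation = mean(bg),
                        birth_generation_sd = sd0(bg))
  }
  c10 <- per_rep(function(r) r$contribution[[1L]])
  c12 <- per_rep(function(r) r$contribution[[2L]])
  pg <- lapply(reps, function(r) r$progeny)
  stage1_gens <- seq_len(x$cfg$stage2_start - 1L)
  sd_male <- vapply(pg, function(p) mean(p$sd_male[p$generation %in% stage1_gens]), numeric(1))
  sd_female <- vapply(pg, function(p) mean(p$sd_female[p$generation %in% stage1_gens]), numeric(1))

  structure(list(scenario = x$scenario, cfg = x$cfg, n_replicates = n,
                 traj = traj,
                 bank_table = bank_table,
                 bank_total = c(mean = mean(bank_total), sd = sd0(bank_total)),
                 usage_table = usage_table,
                 contribution = data.frame(
                   generation = c(x$cfg$stage2_start + 1L, x$cfg$n_generations - 1L),
                   mean = 100 * c(mean(c10), mean(c12)),
                   sd = 100 * c(sd0(c10), sd0(c12))),
                 progeny = c(sd_male = mean(sd_male), sd_female = mean(sd_female))),
            class = "breed_summary")
}

#' Extract a per-replicate metric
#'
#' Metric strings:
#' * `"traj:<stat>:<generation>:<group>"`, e.g. `"traj:mean_A:12:all"` with
#'   stat one of `mean_A`, `mean_B`, `mean_F`, `mean_phi` and group one of
#'   `bulls`, `cows`, `all`;
#' * `"contribution:<generation>"` (the two recorded generations);
#' * `"bank:total"` or `"bank:<rule>"` (rule column name).
#'
#' @param x a `breed_replicates` object.
#' @param metric metric string.
#' @return Numeric vector with one value per replicate.
#' @export
extract_metric <- function(x, metric) {
  parts <- strsplit(metric, ":", fixed = TRUE)[[1L]]
  f <- switch(parts[1L],
    traj = {
      stat <- parts[2L]; g <- as.integer(parts[3L]); grp <- parts[4L]
      function(r) {
        row <- r$traj$generation == g & r$traj$group == grp
        if (!any(row)) stop("no trajectory point for generation ", g, " group ", grp)
        r$traj[[stat]][row]
      }
    },
    contribution = {
      key <- paste0("gen", parts[2L])
      function(r) r$contribution[[key]]
    },
    bank = {
      if (parts[2L] == "total") function(r) nrow(r$bank)
      else function(r) sum(r$bank[[parts[2L]]])
    },
    stop("unknown metric: ", metric))
  vapply(x$results, f, numeric(1))
}

#' Welch contrast between two scenarios
#'
#' Two-sample Welch comparison of a replicate-level metric between two sets
#' of replicate results.
#'
#' @param a,b `breed_replicates` objects.
#' @param metric metric string (see [extract_metric()]).
#' @return A list with the signed `difference` (mean of `a` minus mean of
#'   `b`), the two-sided `p_value`, and the per-set means.
#' @export
contrast_replicates <- function(a, b, metric) {
  va <- extract_metric(a, metric)
  vb <- extract_metric(b, metric)
  if (length(va) < 2 || length(vb) < 2)
    stop("need at least 2 replicates on each side")
  diff <- mean(va) - mean(vb)
  p <- if (isTRUE(all.equal(va, vb))) 1 else t.test(va, vb)$p.value
  list(difference = diff, p_value = p, mean_a = mean(va), mean_b = mean(vb),
       n_a = length(va), n_b = length(vb))
}
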
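#' Breeding scheme configuration
#'
#' Parameters of the simulated closed dairy cattle breed: 13 discrete
#' generations of 100 male and 10,000 female calves; in each generation 10
#' bulls and 50 cows are selected as parents of the male progeny and 20 bulls
#' and all 10,000 cows as parents of the female progeny (no selection on the
#' dam-to-dam path). Both traits have unit initial genetic standard deviation,
#' genetic correlation `rho = -0.3`, and EBV accuracies (squared correlation
#' between EBV and true value) of 0.6 for bulls and 0.4 for cows. Cryobank
#' sampling thresholds are 3 s.d. on EBVA (either side) and +2 s.d. on EBVB.
#'
#' `scale` shrinks cohort and selected-parent counts proportionally (minimum
#' of 2 per selected list) for fast exploratory runs; scaled runs change the
#' selection intensities and do not reproduce full-scale magnitudes.
#'
#' @param n_males,n_females calves born per generation.
#' @param n_sires_of_males,n_dams_of_males parents of the male progeny.
#' @param n_sires_of_females,n_dams_of_females parents of the female progeny;
#'   `n_dams_of_females` defaults to `n_females` (no dam-to-dam selection).
#' @param rho genetic correlation between traits A and B.
#' @param cd_male,cd_female EBV accuracies by sex.
#' @param n_generations total number of generations (0-based, default 13,
#'   i.e. generations 0-12).
#' @param stage2_start first generation of stage 2 (default 9).
#' @param cryo_thresh_A,cryo_thresh_B cryobank sampling thresholds in
#'   within-cohort standard deviations of EBVA and EBVB.
#' @param scale proportional scaling factor applied to all counts.
#' @return A validated `scheme_config` object (a list).
#' @export
scheme_config <- function(n_males = 100, n_females = 10000,
                          n_sires_of_males = 10, n_dams_of_males = 50,
                          n_sires_of_females = 20, n_dams_of_females = NULL,
                          rho = -0.3, cd_male = 0.6, cd_female = 0.4,
                          n_generations = 13, stage2_start = 9,
                          cryo_thresh_A = 3, cryo_thresh_B = 2,
                          scale = 1) {
  if (is.null(n_dams_of_females)) n_dams_of_females <- n_females
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1)
    stop("'scale' must be in (0, 1]")
  if (scale < 1) {
    shrink <- function(x) max(2L, as.integer(round(x * scale)))
    n_males <- shrink(n_males); n_females <- shrink(n_females)
    n_sires_of_males <- shrink(n_sires_of_males)
    n_dams_of_males <- shrink(n_dams_of_males)
    n_sires_of_females <- shrink(n_sires_of_females)
    n_dams_of_females <- min(shrink(n_dams_of_females), n_females)
  }
  cfg <- list(n_males = as.integer(n_males), n_females = as.integer(n_females),
              n_sires_of_males = as.integer(n_sires_of_males),
              n_dams_of_males = as.integer(n_dams_of_males),
              n_sires_of_females = as.integer(n_sires_of_females),
              n_dams_of_females = as.integer(n_dams_of_females),
              rho = rho, cd_male = cd_male, cd_female = cd_female,
              n_generations = as.integer(n_generations),
              stage2_start = as.integer(stage2_start),
              cryo_thresh_A = cryo_thresh_A, cryo_thresh_B = cryo_thresh_B)
  validate_scheme_config(cfg)
  structure(cfg, class = "scheme_config")
}

validate_scheme_config <- function(cfg) {
  chk <- function(ok, field, msg) if (!ok) stop(sprintf("invalid '%s': %s", field, msg))
  chk(cfg$n_males >= 2, "n_males", "need at least 2 male calves")
  chk(cfg$n_females >= 2, "n_females", "need at least 2 female calves")
  chk(cfg$n_sires_of_males <= cfg$n_males, "n_sires_of_males", "exceeds male cohort size")
  chk(cfg$n_sires_of_females <= cfg$n_males, "n_sires_of_females", "exceeds male cohort size")
  chk(cfg$n_dams_of_males <= cfg$n_females, "n_dams_of_males", "exceeds female cohort size")
  chk(cfg$n_dams_of_females <= cfg$n_females, "n_dams_of_females", "exceeds female cohort size")
  chk(abs(cfg$rho) <= 1, "rho", "must lie in [-1, 1]")
  chk(cfg$cd_male > 0 && cfg$cd_male <= 1, "cd_male", "must lie in (0, 1]")
  chk(cfg$cd_female > 0 && cfg$cd_female <= 1, "cd_female", "must lie in (0, 1]")
  chk(cfg$n_generations >= 2, "n_generations", "need at least 2 generations")
  chk(cfg$stage2_start >= 2 && cfg$stage2_start < cfg$n_generations,
      "stage2_start", "must lie between 2 and n_generations - 1")
  chk(cfg$cryo_thresh_A > 0, "cryo_thresh_A", "must be positive")
  chk(cfg$cryo_thresh_B > 0, "cryo_thresh_B", "must be positive")
  invisible(cfg)
}

#' @export
print.scheme_config <- function(x, ...) {
  cat(sprintf("<scheme_config> %d M + %d F per generation, generations 0-%d (stage 2 from %d)\n",
              x$n_males, x$n_females, x$n_generations - 1L, x$stage2_start))
  cat(sprintf("  parents: %d/%d (male path), %d/%d (female path); rho = %g; CD = %g/%g\n",
              x$n_sires_of_males, x$n_dams_of_males, x$n_sires_of_females,
              x$n_dams_of_females, x$rho, x$cd_male, x$cd_female))
  invisible(x)
}

#' Read or write a run configuration file
#'
#' YAML document with three blocks: `scheme` (fields of [scheme_config()]),
#' `scenario` (`code` plus optional `w_b`, `fraction`, `bank_mode`) and `run`
#' (`replicates`, `seed`, `out_dir`). Overrides supplied as a list replace
#' file values field by field; an empty or absent file yields the full-scale
#' defaults with scenario b1.
#'
#' @param path path to a YAML configuration file, or `NULL` for defaults.
#' @param overrides named list with any of the blocks `scheme`, `scenario`,
#'   `run` overriding file values.
#' @return `parse_config()` returns a list with elements `scheme`
#'   (a `scheme_config`), `scenario` (a `scenario_config`) and `run`;
#'   `write_config()` returns `path` invisibly.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  for (block in names(overrides))
    raw[[block]] <- modifyList(if (is.null(raw[[block]])) list() else raw[[block]],
                               overrides[[block]])
  scheme <- do.call(scheme_config, if (is.null(raw$scheme)) list() else raw$scheme)
  sc <- if (is.null(raw$scenario)) list(code = "b1") else raw$scenario
  if (is.null(sc$code)) sc$code <- "b1"
  scenario <- build_scenario(sc$code, w_b = sc$w_b, fraction = sc$fraction,
                             bank_mode = sc$bank_mode)
  run <- modifyList(list(replicates = 20L, seed = 1L, out_dir = "."),
                    if (is.null(raw$run)) list() else raw$run)
  run$replicates <- as.integer(run$replicates)
  run$seed <- as.integer(run$seed)
  list(scheme = scheme, scenario = scenario, run = run)
}

#' @rdname parse_config
#' @param config a list as returned by `parse_config()`.
#' @export
write_config <- function(config, path) {
  scheme <- unclass(config$scheme)
  scenario <- list(code = config$scenario$code, w_b = config$scenario$w_b,
                   fraction = config$scenario$fraction_cryobank_sons,
                   bank_mode = config$scenario$bank_mode)
  yaml::write_yaml(list(scheme = scheme, scenario = scenario, run = config$run), path)
  invisible(path)
}
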
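#' @export
print.breed_stage1 <- function(x, ...) {
  g <- max(x$traj$generation)
  last <- x$traj[x$traj$generation == g & x$traj$group == "all", ]
  cat(sprintf("<breed_stage1> generations 0-%d, bank: %d bulls (%s)\n",
              g, nrow(x$bank), x$bank_mode))
  cat(sprintf("  generation %d (whole population): mean A = %.2f, mean B = %.2f, F = %.3f, phi = %.3f\n",
              g, last$mean_A, last$mean_B, last$mean_F, last$mean_phi))
  invisible(x)
}

#' @export
print.breed_replicate <- function(x, ...) {
  g <- max(x$traj$generation)
  last <- x$traj[x$traj$generation == g & x$traj$group == "all", ]
  cat(sprintf("<breed_replicate> scenario %s, generations 0-%d\n", x$scenario$code, g))
  cat(sprintf("  generation %d (whole population): mean A = %.2f, mean B = %.2f, F = %.3f, phi = %.3f\n",
              g, last$mean_A, last$mean_B, last$mean_F, last$mean_phi))
  if (!is.null(x$used_bulls))
    cat(sprintf("  cryobank bulls used: %s (birth generations %s); gene contribution %s\n",
                paste(x$used_bulls$bull_id, collapse = ", "),
                paste(x$used_bulls$birth_generation, collapse = ", "),
                paste(sprintf("%s = %.1f%%", names(x$contribution),
                              100 * x$contribution), collapse = ", ")))
  invisible(x)
}

#' @export
print.breed_replicates <- function(x, ...) {
  cat(sprintf("<breed_replicates> scenario %s, %d replicates (master seed %d)\n",
              x$scenario$code, length(x$results), x$master_seed))
  invisible(x)
}

#' @export
summary.breed_replicates <- function(object, ...) aggregate_replicates(object)

#' @export
print.breed_summary <- function(x, ...) {
  cat(sprintf("Scenario %s: %d replicates, %d M + %d F per generation\n",
              x$scenario$code, x$n_replicates, x$cfg$n_males, x$cfg$n_females))
  g <- max(x$traj$generation)
  for (gg in unique(c(x$cfg$stage2_start - 1L, g))) {
    row <- x$traj[x$traj$generation == gg & x$traj$group == "all", ]
    cat(sprintf("  generation %2d (whole population): A = %5.2f, B = %5.2f, F = %5.1f%%, phi = %5.1f%%\n",
                gg, row$mean_A, row$mean_B, 100 * row$mean_F, 100 * row$mean_phi))
  }
  cat(sprintf("  cryobank: %.1f bulls per replicate\n", x$bank_total[["mean"]]))
  rl <- x$bank_table
  for (i in seq_len(nrow(rl)))
    cat(sprintf("    %-22s %5.1f bulls (%4.1f%% of bank), birth generation %.2f\n",
                rl$rule[i], rl$n_bulls[i], rl$pct_of_bank[i], rl$birth_generation[i]))
  if (!is.null(x$usage_table))
    cat(sprintf("  bulls used: birth generation %.1f; contribution: %s\n",
                x$usage_table$birth_generation,
                paste(sprintf("generation %d = %.1f%%", x$contribution$generation,
                              x$contribution$mean), collapse = ", ")))
  cat(sprintf("  progeny-count dispersion (stage 1): %.2f (male path), %.2f (female path)\n",
              x$progeny[["sd_male"]], x$progeny[["sd_female"]]))
  invisible(x)
}

#' Plot trajectory summaries
#'
#' Base-graphics view of the across-replicate mean trajectories: genetic
#' means of both traits (left axis, s.d. units of the base population) and
#' inbreeding/average kinship (right panel, percent), for the whole
#' population and the young-bull cohorts.
#'
#' @param x a `breed_summary` object.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.breed_summary <- function(x, ...) {
  tr <- x$traj
  gens <- sort(unique(tr$generation))
  pick <- function(stat, grp) tr[[stat]][tr$group == grp][order(tr$generation[tr$group == grp])]
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(gens, cbind(pick("mean_A", "all"), pick("mean_B", "all"),
                                pick("mean_A", "bulls"), pick("mean_B", "bulls")),
                    type = "l", lty = c(1, 1, 3, 3), col = c(2, 4, 2, 4),
                    xlab = "generation", ylab = "genetic mean (initial s.d.)", ...)
  graphics::legend("topleft", bty = "n", lty = c(1, 1, 3), col = c(2, 4, 1),
                   legend = c("trait A", "trait B", "young bulls"))
  graphics::matplot(gens, 100 * cbind(pick("mean_F", "all"), pick("mean_phi", "all"),
                                      pick("mean_phi", "bulls")),
                    type = "l", lty = c(1, 1, 3), col = c(6, "magenta4", "magenta4"),
                    xlab = "generation", ylab = "F / kinship (%)", ...)
  graphics::legend("topleft", bty = "n", lty = c(1, 1, 3), col = c(6, "magenta4", "magenta4"),
                   legend = c("inbreeding F", "kinship (population)", "kinship (young bulls)"))
  invisible(x)
}
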
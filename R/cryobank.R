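#' Cryobank sampling rules for young bulls
#'
#' French-style sampling of "original" bulls from each young-bull cohort:
#' rule (i) flags bulls whose EBVA lies more than `thresh_a` within-cohort
#' standard deviations above or below the cohort mean; rule (ii) flags bulls
#' whose EBVB lies more than `thresh_b` standard deviations above the cohort
#' mean (trait B is a functional trait, so only the upper tail is stored).
#' Means and standard deviations are the empirical statistics of the cohort's
#' EBVs, and the inequalities are strict.
#'
#' @param males data frame of one generation's male cohort with columns
#'   `id`, `generation`, `EBVA`, `EBVB`, `A`, `B`, `F`.
#' @param thresh_a,thresh_b thresholds in within-cohort standard deviations.
#' @return A bank-entry data frame (possibly empty) with the sampling reasons
#'   as logical columns.
#' @export
sample_rules_i_ii <- function(males, thresh_a = 3, thresh_b = 2) {
  if (nrow(males) < 2) stop("need a cohort of at least 2 bulls")
  ma <- mean(males$EBVA); sa <- sd(males$EBVA)
  mb <- mean(males$EBVB); sb <- sd(males$EBVB)
  hi_a <- males$EBVA > ma + thresh_a * sa
  lo_a <- males$EBVA < ma - thresh_a * sa
  hi_b <- males$EBVB > mb + thresh_b * sb
  keep <- hi_a | lo_a | hi_b
  bank_entries(males[keep, , drop = FALSE],
               high_EBVA = hi_a[keep], low_EBVA = lo_a[keep],
               high_EBVB = hi_b[keep],
               unused_sire_of_sires = rep(FALSE, sum(keep)),
               sampling_generation = males$generation[keep])
}

#' Cryobank sampling of sires of sires with no selected male offspring
#'
#' Rule (iii): a sire of sires none of whose sons appears in the next round's
#' selected sire lists (sires of males or sires of females) enters the bank,
#' with a one-generation lag relative to rules (i)-(ii).
#'
#' @param sires data frame of the sires of sires to assess (bank-entry
#'   columns as in [sample_rules_i_ii()]).
#' @param sons data frame of their male offspring cohort (columns `id`,
#'   `sire`).
#' @param selected_ids ids selected as sires (of males or females) from the
#'   sons' cohort.
#' @return A bank-entry data frame for the unused sires.
#' @export
sample_rule_iii <- function(sires, sons, selected_ids) {
  unused <- vapply(sires$id, function(b) {
    !any(sons$id[sons$sire == b] %in% selected_ids)
  }, logical(1))
  keep <- sires[unused, , drop = FALSE]
  bank_entries(keep,
               high_EBVA = rep(FALSE, nrow(keep)),
               low_EBVA = rep(FALSE, nrow(keep)),
               high_EBVB = rep(FALSE, nrow(keep)),
               unused_sire_of_sires = rep(TRUE, nrow(keep)),
               sampling_generation = keep$generation + 1L)
}

#' Store the whole young-bull cohort (store-all sampling variant)
#'
#' Simpler sampling policy in which the semen of every young bull is kept;
#' used to check that the rule-based sampling does not discard useful bulls.
#'
#' @inheritParams sample_rules_i_ii
#' @return A bank-entry data frame with one row per bull.
#' @export
sample_all_young_bulls <- function(males) {
  n <- nrow(males)
  bank_entries(males,
               high_EBVA = rep(FALSE, n), low_EBVA = rep(FALSE, n),
               high_EBVB = rep(FALSE, n),
               unused_sire_of_sires = rep(FALSE, n),
               sampling_generation = males$generation)
}

bank_entries <- function(rows, high_EBVA, low_EBVA, high_EBVB,
                         unused_sire_of_sires, sampling_generation) {
  data.frame(bull_id = as.integer(rows$id),
             birth_generation = as.integer(rows$generation),
             sampling_generation = as.integer(sampling_generation),
             high_EBVA = high_EBVA, low_EBVA = low_EBVA, high_EBVB = high_EBVB,
             unused_sire_of_sires = unused_sire_of_sires,
             EBVA = rows$EBVA, EBVB = rows$EBVB,
             A = rows$A, B = rows$B, F = rows$F)
}

empty_bank <- function() {
  bank_entries(data.frame(id = integer(), generation = integer(),
                          EBVA = numeric(), EBVB = numeric(),
                          A = numeric(), B = numeric(), F = numeric()),
               logical(0), logical(0), logical(0), logical(0), integer(0))
}

# merge new entries into the bank: one row per bull, reasons ORed,
# earliest sampling generation kept
bank_add <- function(bank, entries) {
  if (!nrow(entries)) return(bank)
  dup <- match(entries$bull_id, bank$bull_id)
  hit <- !is.na(dup)
  if (any(hit)) {
    at <- dup[hit]
    for (fl in c("high_EBVA", "low_EBVA", "high_EBVB", "unused_sire_of_sires"))
      bank[[fl]][at] <- bank[[fl]][at] | entries[[fl]][hit]
    bank$sampling_generation[at] <-
      pmin(bank$sampling_generation[at], entries$sampling_generation[hit])
  }
  rbind(bank, entries[!hit, , drop = FALSE])
}

#' Choose the cryobank bulls to use at the introduction generation
#'
#' Either the `k` stored bulls with the highest total merit index (computed
#' among banked bulls from their archived EBVs with weight `w_b` on trait B),
#' or the `k` stored bulls with the lowest average kinship with the current
#' population (males and females taken together). Ties are broken by
#' ascending bull id.
#'
#' @param bank the cryobank data frame accumulated during stage 1.
#' @param method `"best_TMI"` or `"min_mean_kinship"`.
#' @param k number of bulls to use (default 4).
#' @param kin the current `cohort_kinship` object; required for
#'   `"min_mean_kinship"`, where every banked bull must be a tracked row.
#' @param w_b weight of trait B in the index (default 0.5).
#' @return The selected bank rows, best first, with an extra column
#'   `mean_kinship` when chosen by kinship.
#' @export
choose_cryobank_bulls <- function(bank, method = c("best_TMI", "min_mean_kinship"),
                                  k = 4, kin = NULL, w_b = 0.5) {
  method <- match.arg(method)
  if (nrow(bank) < k) stop("cryobank holds fewer than ", k, " bulls")
  if (method == "best_TMI") {
    val <- total_merit_index(bank$EBVA, bank$EBVB, 1 - w_b)
    ord <- order(-val, bank$bull_id)
    return(bank[ord[seq_len(k)], , drop = FALSE])
  }
  if (is.null(kin)) stop("'kin' is required for min_mean_kinship")
  idx <- match(bank$bull_id, kin$bank_ids)
  if (anyNA(idx)) stop("all banked bulls must be tracked in 'kin'")
  mk <- colMeans(kin$Ct[, idx, drop = FALSE])
  ord <- order(mk, bank$bull_id)
  out <- bank[ord[seq_len(k)], , drop = FALSE]
  out$mean_kinship <- mk[ord[seq_len(k)]]
  out
}
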
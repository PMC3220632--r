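#' Cohort kinship objects
#'
#' The breeding scheme only ever mates animals of the previous cohort (plus,
#' at the cryobank-introduction generation, a handful of stored bulls), so
#' pairwise coancestries are carried generation by generation as a dense
#' cohort matrix instead of a relationship matrix over the whole pedigree.
#' A `cohort_kinship` object holds:
#'
#' * `ids` and `K`: the cohort's animal ids and their symmetric coancestry
#'   matrix (diagonal `0.5 * (1 + F)`),
#' * `F`: the cohort's inbreeding coefficients,
#' * `bank_ids`, `Ct`, `Bb`, `bank_F`: coancestries of explicitly tracked
#'   bulls (cryobank candidates) with the cohort (`Ct`, cohort x bank), among
#'   themselves (`Bb`) and their inbreeding.
#'
#' @param ids integer ids of the cohort animals.
#' @param f inbreeding coefficients of unrelated base animals (default 0).
#' @return A `cohort_kinship` object over mutually unrelated animals.
#' @export
founder_kinship <- function(ids, f = 0) {
  n <- length(ids)
  K <- matrix(0, n, n)
  K[seq.int(1L, by = n + 1L, length.out = n)] <- 0.5 * (1 + f)  # in-place diagonal
  new_cohort_kinship(ids, K, rep(f, length.out = n))
}

new_cohort_kinship <- function(ids, K, F,
                               bank_ids = integer(0),
                               Ct = matrix(0, length(ids), 0),
                               Bb = matrix(0, 0, 0),
                               bank_F = numeric(0)) {
  structure(list(ids = as.integer(ids), K = K, F = F,
                 bank_ids = as.integer(bank_ids), Ct = Ct, Bb = Bb,
                 bank_F = bank_F),
            class = "cohort_kinship")
}

#' @export
print.cohort_kinship <- function(x, ...) {
  cat(sprintf("<cohort_kinship> %d animals, %d tracked bulls\n",
              length(x$ids), length(x$bank_ids)))
  cat(sprintf("  mean F = %.4f, mean pairwise kinship = %.4f\n",
              mean(x$F), average_kinship(x)))
  invisible(x)
}

#' Track bulls across subsequent cohort propagations
#'
#' Copies the kinship rows of the given cohort members into the tracked-bull
#' block so their coancestry with all later cohorts keeps being propagated
#' (needed for cryobank candidates, which may be mated generations after
#' their birth cohort's matrix has been discarded).
#'
#' @param k a `cohort_kinship` object.
#' @param ids ids of current cohort members to start tracking.
#' @return The updated `cohort_kinship` object.
#' @export
track_bulls <- function(k, ids) {
  ids <- setdiff(as.integer(ids), k$bank_ids)
  if (!length(ids)) return(k)
  idx <- match(ids, k$ids)
  if (anyNA(idx)) stop("tracked ids must belong to the current cohort")
  Csub <- k$Ct[idx, , drop = FALSE]              # new bulls x old bank
  k$Bb <- rbind(cbind(k$Bb, t(Csub)),
                cbind(Csub, k$K[idx, idx, drop = FALSE]))
  k$Ct <- cbind(k$Ct, k$K[, idx, drop = FALSE])
  k$bank_ids <- c(k$bank_ids, ids)
  k$bank_F <- c(k$bank_F, k$F[idx])
  k
}

#' Keep only a subset of tracked bulls
#' @param k a `cohort_kinship` object.
#' @param ids tracked bull ids to retain.
#' @return The pruned object.
#' @export
prune_tracked_bulls <- function(k, ids) {
  keep <- match(as.integer(ids), k$bank_ids)
  if (anyNA(keep)) stop("ids must be tracked bulls")
  k$Ct <- k$Ct[, keep, drop = FALSE]
  k$Bb <- k$Bb[keep, keep, drop = FALSE]
  k$bank_ids <- k$bank_ids[keep]
  k$bank_F <- k$bank_F[keep]
  k
}

#' Propagate cohort kinship to an offspring cohort
#'
#' Applies the coancestry recursion in vectorised form:
#' `phi(o1, o2) = (phi(s1,s2) + phi(s1,d2) + phi(d1,s2) + phi(d1,d2)) / 4`
#' for distinct offspring, `phi(o, o) = (1 + phi(s, d)) / 2` on the diagonal,
#' and `phi(bull, o) = (phi(bull, s) + phi(bull, d)) / 2` for tracked bulls.
#' Parents may be cohort members or tracked bulls.
#'
#' @param k a `cohort_kinship` object over the parent cohort.
#' @param offspring_ids ids of the offspring cohort.
#' @param sire_ids,dam_ids parent ids per offspring (cohort or tracked-bull
#'   ids).
#' @return A `cohort_kinship` object over the offspring cohort; the tracked
#'   bulls and their mutual block are carried over unchanged.
#' @export
propagate_kinship <- function(k, offspring_ids, sire_ids, dam_ids) {
  ext <- c(k$ids, k$bank_ids)
  s <- match(as.integer(sire_ids), ext)
  d <- match(as.integer(dam_ids), ext)
  if (anyNA(s) || anyNA(d))
    stop("every sire and dam must be in the parent cohort or tracked bulls")
  out <- propagate_kinship_cpp(k$K, k$Ct, k$Bb, s, d)
  new_cohort_kinship(offspring_ids, out$K, out$F,
                     bank_ids = k$bank_ids, Ct = out$Ct, Bb = k$Bb,
                     bank_F = k$bank_F)
}

#' Average pairwise kinship within a group
#'
#' Mean coancestry over all unordered pairs of distinct animals (self-pairs
#' excluded, so the statistic is not conflated with inbreeding).
#'
#' @param k a `cohort_kinship` object.
#' @param ids subset of cohort ids (default: whole cohort).
#' @return Mean pairwise coancestry.
#' @export
average_kinship <- function(k, ids = NULL) {
  idx <- if (is.null(ids)) seq_along(k$ids) else match(as.integer(ids), k$ids)
  if (anyNA(idx)) stop("ids must belong to the cohort")
  if (length(idx) < 2) stop("need at least two animals")
  mean_offdiag_cpp(k$K, as.integer(idx))
}

#' Mean kinship of a candidate with a population
#'
#' Used to pick cryobank bulls with the lowest average kinship with the
#' current population (males and females taken together). The candidate is
#' excluded from the population if present.
#'
#' @param k a `cohort_kinship` object.
#' @param candidate a cohort or tracked-bull id.
#' @param population_ids cohort ids (default: whole cohort).
#' @return Mean coancestry of the candidate with the population.
#' @export
mean_kinship_to_population <- function(k, candidate, population_ids = NULL) {
  pop <- if (is.null(population_ids)) k$ids else as.integer(population_ids)
  pop <- setdiff(pop, as.integer(candidate))
  pidx <- match(pop, k$ids)
  if (anyNA(pidx)) stop("population ids must belong to the cohort")
  ci <- match(as.integer(candidate), k$ids)
  if (!is.na(ci)) return(mean(k$K[pidx, ci]))
  bi <- match(as.integer(candidate), k$bank_ids)
  if (is.na(bi)) stop("candidate is neither a cohort member nor a tracked bull")
  mean(k$Ct[pidx, bi])
}

# --- internal large-matrix buffer pool --------------------------------------
# Cohort matrices at full scale are ~0.8 GB; repeatedly allocating and
# releasing them is far more expensive than the propagation itself, so one
# run keeps a small pool of fixed buffers and the C++ kernels write into
# them in place. Pool buffers must never be modified by R-level assignment.

new_kin_pool <- function(n, slots = 3L) {
  e <- new.env(parent = emptyenv())
  e$n <- as.integer(n)
  e$bufs <- vector("list", slots)
  e
}

pool_buf <- function(pool, slot) {
  if (is.null(pool$bufs[[slot]])) pool$bufs[[slot]] <- matrix(0, pool$n, pool$n)
  pool$bufs[[slot]]
}

founder_kinship_pooled <- function(pool, slot, ids, f = 0) {
  Fv <- rep(f, length.out = length(ids))
  K <- pool_buf(pool, slot)
  founder_fill_cpp(K, 0.5 * (1 + Fv))
  k <- new_cohort_kinship(ids, K, Fv)
  k$slot <- slot
  k
}

propagate_kinship_pooled <- function(pool, k, offspring_ids, sire_ids, dam_ids,
                                     out_slot) {
  ext <- c(k$ids, k$bank_ids)
  s <- match(as.integer(sire_ids), ext)
  d <- match(as.integer(dam_ids), ext)
  if (anyNA(s) || anyNA(d))
    stop("every sire and dam must be in the parent cohort or tracked bulls")
  Kout <- pool_buf(pool, out_slot)
  out <- propagate_kinship_buf_cpp(k$K, k$Ct, k$Bb, s, d, Kout)
  k2 <- new_cohort_kinship(offspring_ids, Kout, out$F,
                           bank_ids = k$bank_ids, Ct = out$Ct, Bb = k$Bb,
                           bank_F = k$bank_F)
  k2$slot <- out_slot
  k2
}

#' Pairwise coancestry by memoized pedigree recursion
#'
#' Reference implementation of the coancestry coefficient on an explicit
#' pedigree: `phi(i, i) = (1 + phi(sire_i, dam_i)) / 2`, and for `i` younger
#' than `j`, `phi(i, j) = (phi(sire_i, j) + phi(dam_i, j)) / 2`; distinct
#' founders are unrelated. Quadratic-time and memoized; intended for small
#' pedigrees and as the independent oracle for [propagate_kinship()].
#'
#' @param ped a pedigree data frame (see [new_pedigree()]); rows must be
#'   topologically ordered with ids `1..n` in row order.
#' @param i,j animal ids.
#' @return The coancestry coefficient `phi(i, j)`.
#' @export
kinship_pair <- function(ped, i, j) {
  sire <- ped$sire
  dam <- ped$dam
  n <- nrow(ped)
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) stop("unknown animal id")
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(a, b) {
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    key <- paste(a, b)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (a == b) {
      if (is.na(sire[a])) 0.5 else 0.5 * (1 + phi(sire[a], dam[a]))
    } else {
      # b is the younger animal (ids are topological)
      if (is.na(sire[b])) 0 else 0.5 * (phi(sire[b], a) + phi(dam[b], a))
    }
    memo[[key]] <- val
    val
  }
  phi(as.integer(i), as.integer(j))
}

#' Inbreeding coefficient of an offspring from its parents' coancestry
#'
#' The offspring's inbreeding coefficient equals the coancestry of its
#' parents.
#'
#' @param phi_parents coancestry of sire and dam, in `[0, 1]`.
#' @return `F` of the offspring.
#' @export
inbreeding_from_parents <- function(phi_parents) {
  if (any(phi_parents < 0 | phi_parents > 1))
    stop("coancestry must lie in [0, 1]")
  phi_parents
}
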
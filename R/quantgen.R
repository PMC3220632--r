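#' Draw founder genetic values for two correlated traits
#'
#' Founders carry true genetic values for a production trait A and a
#' functional trait B, both on the scale of the initial genetic standard
#' deviation (set to 1). A is standard normal; B is built from A as
#' `B = rho * A + sqrt(1 - rho^2) * beta` with `beta` an independent standard
#' normal, so that both marginals are N(0, 1) and `cor(A, B) = rho`.
#'
#' @param n number of founders to draw.
#' @param rho genetic correlation between the traits, in `[-1, 1]`.
#' @return A list with numeric vectors `A` and `B` of length `n`.
#' @examples
#' set.seed(1)
#' f <- draw_founder_pairs(1000, -0.3)
#' cor(f$A, f$B)
#' @export
draw_founder_pairs <- function(n, rho) {
  check_rho(rho)
  if (!is.numeric(n) || length(n) != 1L || n < 0) stop("'n' must be a single non-negative number")
  A <- rnorm(n)
  beta <- rnorm(n)
  list(A = A, B = rho * A + sqrt(1 - rho^2) * beta)
}

#' Simulate offspring genetic values under the infinitesimal model
#'
#' Each offspring receives the mid-parent mean plus a Mendelian sampling
#' deviation whose standard deviation shrinks with parental inbreeding:
#' `A = (A_sire + A_dam)/2 + gamma * sqrt(0.5 * (1 - (F_sire + F_dam)/2))`,
#' and the same for trait B with `delta`. The pair `(gamma, delta)` is
#' bivariate standard normal with correlation `rho`, so the negative genetic
#' correlation is maintained within families.
#'
#' All arguments are vectorised over offspring; parent values must be aligned
#' (element i of each vector describes the parents of offspring i).
#'
#' @param sire_A,sire_B,dam_A,dam_B parental true genetic values.
#' @param F_sire,F_dam parental inbreeding coefficients in `[0, 1]`.
#' @param rho genetic correlation between traits.
#' @return A list with numeric vectors `A` and `B`.
#' @export
offspring_genetic_values <- function(sire_A, sire_B, dam_A, dam_B,
                                     F_sire, F_dam, rho) {
  check_rho(rho)
  if (any(F_sire < 0 | F_sire > 1) || any(F_dam < 0 | F_dam > 1))
    stop("inbreeding coefficients must lie in [0, 1]")
  n <- length(sire_A)
  gamma <- rnorm(n)
  delta <- rho * gamma + sqrt(1 - rho^2) * rnorm(n)
  ms_sd <- sqrt(0.5 * (1 - (F_sire + F_dam) / 2))
  list(A = (sire_A + dam_A) / 2 + gamma * ms_sd,
       B = (sire_B + dam_B) / 2 + delta * ms_sd)
}

#' Simulate estimated breeding values at a fixed accuracy
#'
#' EBVs are simulated directly from the true genetic values rather than
#' derived from a genetic evaluation: `EBV = CD * g + e * sqrt(CD * (1 - CD))`
#' with `e` standard normal, where `CD` is the squared correlation between the
#' EBV and the true value (0.6 for bulls and 0.4 for cows in the default
#' scheme). The noise terms for the two traits are independent of each other
#' and of the true values.
#'
#' @param A,B true genetic values (vectors of equal length).
#' @param cd accuracy, a scalar or per-animal vector with values in `(0, 1]`.
#' @return A list with numeric vectors `EBVA` and `EBVB`.
#' @export
simulate_ebv <- function(A, B, cd) {
  if (any(cd <= 0 | cd > 1)) stop("'cd' must lie in (0, 1]")
  n <- length(A)
  noise_sd <- sqrt(cd * (1 - cd))
  list(EBVA = cd * A + rnorm(n) * noise_sd,
       EBVB = cd * B + rnorm(n) * noise_sd)
}

#' Total merit index
#'
#' Linear combination of the two EBVs used as a selection criterion:
#' `TMI = w_A * EBVA + (1 - w_A) * EBVB`.
#'
#' @param ebva,ebvb estimated breeding values for traits A and B.
#' @param w_a weight given to trait A, in `[0, 1]`; trait B receives
#'   `w_B = 1 - w_A`.
#' @return Numeric vector of index values.
#' @export
total_merit_index <- function(ebva, ebvb, w_a) {
  if (!is.numeric(w_a) || length(w_a) != 1L || w_a < 0 || w_a > 1)
    stop("'w_a' must be a single weight in [0, 1]")
  w_a * ebva + (1 - w_a) * ebvb
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) > 1)
    stop("'rho' must be a single correlation in [-1, 1]")
  invisible(rho)
}
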
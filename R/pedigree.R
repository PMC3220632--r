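#' Pedigree construction and validation
#'
#' A pedigree is a plain data frame with one row per animal and columns
#' `id` (dense 1-based integers in topological order), `sire`, `dam`
#' (`NA` for founders), `sex` (`"M"`/`"F"`) and `generation` (0-based birth
#' generation). Parents must precede their offspring and founders have no
#' parents.
#'
#' @param df a data frame with the columns above.
#' @return The validated data frame with class `c("breed_pedigree", "data.frame")`.
#' @export
new_pedigree <- function(df) {
  need <- c("id", "sire", "dam", "sex", "generation")
  if (!all(need %in% names(df))) stop("pedigree needs columns ", paste(need, collapse = ", "))
  df <- df[need]
  df$id <- as.integer(df$id)
  df$sire <- as.integer(df$sire)
  df$dam <- as.integer(df$dam)
  df$generation <- as.integer(df$generation)
  n <- nrow(df)
  if (!identical(df$id, seq_len(n)))
    stop("ids must be dense 1..n in topological (row) order")
  founder <- is.na(df$sire) & is.na(df$dam)
  if (any(is.na(df$sire) != is.na(df$dam)))
    stop("animals must have both parents or neither")
  kid <- which(!founder)
  if (length(kid)) {
    if (any(df$sire[kid] >= df$id[kid] | df$dam[kid] >= df$id[kid]))
      stop("parents must precede offspring")
    if (any(df$sex[df$sire[kid]] != "M") || any(df$sex[df$dam[kid]] != "F"))
      stop("sires must be male and dams female")
    if (any(df$generation[df$sire[kid]] >= df$generation[kid]) ||
        any(df$generation[df$dam[kid]] >= df$generation[kid]))
      stop("parents must be born in an earlier generation")
  }
  class(df) <- c("breed_pedigree", "data.frame")
  df
}

#' Read or write a pedigree as delimited text
#'
#' Tab-delimited columns `id`, `sire`, `dam`, `sex`, `generation` with `0`
#' encoding an unknown (founder) parent; round-trips exactly.
#'
#' @param ped a pedigree data frame.
#' @param path file path.
#' @return `read_pedigree()` returns a validated pedigree;
#'   `write_pedigree()` returns `path` invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- 0L
  out$dam[is.na(out$dam)] <- 0L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$sire[df$sire == 0L] <- NA_integer_
  df$dam[df$dam == 0L] <- NA_integer_
  new_pedigree(df)
}

link_keys <- function(parent, offspring) paste(parent, offspring, sep = ":")

#' Exact expected gene contribution through designated mating links
#'
#' Computes, for every animal, the expected proportion of its genome that
#' descends through a set of labelled parent-offspring transmissions (e.g.
#' the matings of cryobank bulls at the introduction generation). This is the
#' infinite-run limit of the gene-dropping procedure: an offspring on a
#' labelled link receives a fully labelled gamete from that parent, so
#' `p(i) = (s_sire + s_dam) / 2` with `s_parent = 1` on a labelled link and
#' `s_parent = p(parent)` otherwise; unlinked founders have `p = 0`.
#'
#' @param ped a pedigree data frame.
#' @param source_links data frame with columns `parent` and `offspring`
#'   identifying the labelled transmissions.
#' @return Numeric vector of expected proportions, one per pedigree row.
#' @export
expected_contribution <- function(ped, source_links) {
  n <- nrow(ped)
  p <- numeric(n)
  keys <- if (nrow(source_links))
    link_keys(source_links$parent, source_links$offspring) else character(0)
  kid <- which(!is.na(ped$sire))
  if (!length(kid)) return(p)
  s_linked <- link_keys(ped$sire[kid], ped$id[kid]) %in% keys
  d_linked <- link_keys(ped$dam[kid], ped$id[kid]) %in% keys
  # rows are topological, and contributions only depend on earlier rows,
  # so one pass per generation is exact
  gens <- split(seq_along(kid), ped$generation[kid])
  for (rows in gens) {
    i <- kid[rows]
    ps <- ifelse(s_linked[rows], 1, p[ped$sire[i]])
    pd <- ifelse(d_linked[rows], 1, p[ped$dam[i]])
    p[i] <- (ps + pd) / 2
  }
  p
}

#' Gene dropping through a pedigree
#'
#' Monte-Carlo counterpart of [expected_contribution()]: in each run a single
#' biallelic locus is dropped through the pedigree, each offspring inheriting
#' one uniformly chosen allele from each parent; alleles transmitted across a
#' source link are labelled, and the per-animal labelled-allele fraction is
#' averaged over runs.
#'
#' @inheritParams expected_contribution
#' @param runs number of independent gene-dropping runs (>= 1).
#' @return Numeric vector of estimated proportions, one per pedigree row.
#' @export
gene_drop <- function(ped, source_links, runs = 1000) {
  if (runs < 1) stop("'runs' must be >= 1")
  n <- nrow(ped)
  keys <- if (nrow(source_links))
    link_keys(source_links$parent, source_links$offspring) else character(0)
  pat <- matrix(0, n, runs)  # label of the paternal allele, per run
  mat <- matrix(0, n, runs)
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    if (is.na(s)) next
    d <- ped$dam[i]
    if (link_keys(s, i) %in% keys) {
      pat[i, ] <- 1
    } else {
      pick <- runif(runs) < 0.5
      pat[i, ] <- ifelse(pick, pat[s, ], mat[s, ])
    }
    if (link_keys(d, i) %in% keys) {
      mat[i, ] <- 1
    } else {
      pick <- runif(runs) < 0.5
      mat[i, ] <- ifelse(pick, pat[d, ], mat[d, ])
    }
  }
  rowMeans(pat + mat) / 2
}
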
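#' Validate a tidy microsatellite genotype table
#'
#' The package's genotype container is a long tibble with one row per
#' individual and locus: columns `pop` (population label), `ind` (individual
#' id, unique within its population), `locus`, and the two allele sizes `a1`,
#' `a2` in repeat units (integers; `NA` on both = missing genotype).
#'
#' @param x A data frame with columns `pop`, `ind`, `locus`, `a1`, `a2`.
#' @return A validated tibble with `pop` as a factor (levels in order of
#'   first appearance unless already a factor).
#' @examples
#' df <- tibble::tibble(
#'   pop = "A", ind = c("i1", "i2"), locus = "L01",
#'   a1 = c(30L, 31L), a2 = c(30L, 32L)
#' )
#' as_msat_data(df)
#' @export
as_msat_data <- function(x) {
  need <- c("pop", "ind", "locus", "a1", "a2")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    abort_msat(paste0("genotype table is missing column(s): ",
                      paste(miss, collapse = ", ")))
  x <- tibble::as_tibble(x)
  if (!is.factor(x$pop)) x$pop <- factor(x$pop, levels = unique(x$pop))
  x$a1 <- as.integer(x$a1)
  x$a2 <- as.integer(x$a2)
  half <- xor(is.na(x$a1), is.na(x$a2))
  if (any(half)) {
    # a half-called genotype carries no usable diploid information here
    x$a1[half] <- NA_integer_
    x$a2[half] <- NA_integer_
  }
  dup <- x |>
    dplyr::count(.data$pop, .data$ind, .data$locus) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort_msat(paste0("duplicated (pop, ind, locus) rows, e.g. ",
                      dup$pop[1], "/", dup$ind[1], "/", dup$locus[1]))
  x
}

# Convert the tidy table to the per-locus array layout the C++ kernels use:
# a list of 2 x n_ind integer matrices plus an integer population index per
# individual. Locus order = order of first appearance (or factor levels).
genotype_arrays <- function(x) {
  x <- as_msat_data(x)
  pops <- levels(x$pop)
  loci <- if (is.factor(x$locus)) levels(x$locus) else unique(x$locus)
  key <- paste(as.integer(x$pop), x$ind, sep = "\r")
  inds <- unique(key[order(as.integer(x$pop))])
  idx <- match(key, inds)
  lix <- match(x$locus, loci)
  nind <- length(inds)
  gmats <- lapply(seq_along(loci), function(l) {
    m <- matrix(NA_integer_, 2, nind)
    rows <- which(lix == l)
    m[1, idx[rows]] <- x$a1[rows]
    m[2, idx[rows]] <- x$a2[rows]
    m
  })
  names(gmats) <- loci
  pop_of_ind <- as.integer(sub("\r.*$", "", inds))
  ind_ids <- sub("^.*\r", "", inds)
  list(gmats = gmats, pop = pop_of_ind, pop_levels = pops,
       loci = loci, ind = ind_ids)
}

# Inverse of genotype_arrays(), used by the simulator.
arrays_to_tibble <- function(gmats, pop, pop_levels, ind = NULL) {
  nind <- length(pop)
  loci <- names(gmats)
  if (is.null(ind))
    ind <- paste0(pop_levels[pop], "_",
                  stats::ave(seq_len(nind), pop, FUN = seq_along))
  out <- tidyr::expand_grid(
    i = seq_len(nind),
    locus = loci
  )
  out$pop <- factor(pop_levels[pop[out$i]], levels = pop_levels)
  out$ind <- ind[out$i]
  out$a1 <- NA_integer_
  out$a2 <- NA_integer_
  for (l in seq_along(loci)) {
    rows <- which(out$locus == loci[l])
    out$a1[rows] <- gmats[[l]][1, out$i[rows]]
    out$a2[rows] <- gmats[[l]][2, out$i[rows]]
  }
  dplyr::select(out, "pop", "ind", "locus", "a1", "a2")
}

#' Default locus panel for simulation
#'
#' A panel of dinucleotide-like microsatellite loci with a common ancestral
#' repeat count and a 40-state allele window (reflecting boundaries), the
#' usual ABC convention that keeps the Garza-Williamson ratio well defined.
#'
#' @param n Number of loci.
#' @param ancestral Ancestral repeat count shared by all loci.
#' @param states Number of contiguous allelic states allowed per locus.
#' @return A tibble with columns `locus`, `ancestral`, `states`, `motif`.
#' @export
default_loci <- function(n = 9, ancestral = 30L, states = 40L) {
  if (states < 2) abort_msat("a locus needs at least 2 allelic states")
  tibble::tibble(
    locus = sprintf("L%02d", seq_len(n)),
    ancestral = as.integer(ancestral),
    states = as.integer(states),
    motif = 2L
  )
}

locus_window <- function(ancestral, states) {
  lo <- ancestral - (states %/% 2 - 1L)
  c(lo = lo, hi = lo + states - 1L)
}
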
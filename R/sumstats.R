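# The ABC feature vector: the classic DIYABC microsatellite battery.
# For n populations the vector has 4n one-sample features (NAL, HET, VAR,
# MGW), 6 * C(n,2) pooled/pairwise features (NAL2, HET2, VAR2, FST, DAS,
# DM2), n(n-1) directed assignment likelihoods (LIK) and n * C(n-1,2)
# admixture coefficients (AML) -- 130 features for five populations.

stat_names <- function(pop_levels) {
  n <- length(pop_levels)
  pl <- pop_levels
  pr <- pop_pairs(n)
  pair_lab <- if (nrow(pr)) paste(pl[pr[, 1]], pl[pr[, 2]], sep = ".") else character(0)
  nm <- c(
    paste0("NAL_", pl), paste0("HET_", pl), paste0("VAR_", pl), paste0("MGW_", pl),
    paste0("NAL2_", pair_lab), paste0("HET2_", pair_lab), paste0("VAR2_", pair_lab),
    paste0("FST_", pair_lab), paste0("DAS_", pair_lab), paste0("DM2_", pair_lab)
  )
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) nm <- c(nm, paste0("LIK_", pl[i], ".", pl[j]))
  if (n >= 3)
    for (t in seq_len(n)) for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      if (i != t && j != t && j <= n)
        nm <- c(nm, paste0("AML_", pl[t], "_", pl[i], ".", pl[j]))
  nm
}

#' Number of summary statistics for a population count
#'
#' @param n_pops Number of populations.
#' @return Length of the feature vector: `4n + 6*C(n,2) + n(n-1) + n*C(n-1,2)`.
#' @examples
#' n_sumstats(5)  # 130
#' @export
n_sumstats <- function(n_pops) {
  n <- n_pops
  as.integer(4 * n + 6 * choose(n, 2) + n * (n - 1) + n * choose(n - 1, 2))
}

#' Summarize a genotype dataset into the ABC feature vector
#'
#' @param data A tidy genotype tibble (see [as_msat_data()]) with at least
#'   two populations.
#' @return A one-row tibble of named summary statistics; 130 columns for
#'   five populations. Features whose every locus is degenerate are `NA`.
#' @export
summarize_dataset <- function(data) {
  arr <- genotype_arrays(data)
  npop <- length(arr$pop_levels)
  if (npop < 2) abort_msat("summary statistics need at least 2 populations")
  v <- sumstats_cpp(arr$gmats, arr$pop, npop)
  nm <- stat_names(arr$pop_levels)
  stopifnot(length(v) == length(nm))
  tibble::as_tibble(as.list(stats::setNames(v, nm)))
}

# ---- plain-R reference implementations --------------------------------
# These are the user-facing per-operation functions. They are written
# directly from the definitions (independently of the C++ batch kernel) and
# the test suite checks the two routes agree.

allele_counts <- function(gmat, keep) {
  g <- gmat[, keep, drop = FALSE]
  g <- g[, !is.na(g[1, ]) & !is.na(g[2, ]), drop = FALSE]
  table(as.vector(g))
}

#' One-sample summary statistics for a single population
#'
#' Per-locus values averaged over the loci with at least two genotyped gene
#' copies: mean allele number (`nal`), unbiased genic diversity (`het`),
#' allele-size variance (`var`), and the Garza-Williamson ratio
#' `k / (range + 1)` (`mgw`).
#'
#' @param data Tidy genotype tibble; only rows of `pop` are used.
#' @param pop Population label (default: the single population present).
#' @return One-row tibble with columns `nal`, `het`, `var`, `mgw`.
#' @export
one_sample_stats <- function(data, pop = NULL) {
  data <- as_msat_data(data)
  if (is.null(pop)) {
    if (nlevels(data$pop) != 1)
      abort_msat("several populations present; say which with `pop`")
    pop <- levels(data$pop)[1]
  }
  arr <- genotype_arrays(data)
  keep <- arr$pop == match(pop, arr$pop_levels)
  per_locus <- purrr::map(arr$gmats, function(m) {
    cnt <- allele_counts(m, keep)
    n <- sum(cnt)
    if (n < 2) return(NULL)
    p <- as.numeric(cnt) / n
    sizes <- as.integer(names(cnt))
    tibble::tibble(
      nal = length(cnt),
      het = n / (n - 1) * (1 - sum(p^2)),
      var = sum(cnt * (sizes - sum(p * sizes))^2) / (n - 1),
      mgw = length(cnt) / (diff(range(sizes)) + 1)
    )
  })
  per_locus <- purrr::compact(per_locus)
  if (length(per_locus) == 0)
    abort_msat(paste0("all loci degenerate for population ", pop))
  dplyr::summarise(dplyr::bind_rows(per_locus),
                   dplyr::across(dplyr::everything(), mean))
}

#' Two-sample summary statistics for a pair of populations
#'
#' Pooled one-sample statistics (`nal2`, `het2`, `var2`), the
#' Weir-Cockerham \eqn{F_{ST}} (ratio of variance components summed over
#' loci and alleles), the shared-allele distance `das`, the
#' \eqn{(\delta\mu)^2} distance `dm2`, and the directed mean assignment
#' log-likelihoods `lik_ab` (individuals of A scored against B's allele
#' frequencies) and `lik_ba`.
#'
#' @param data Tidy genotype tibble.
#' @param pop_a,pop_b Population labels.
#' @return One-row tibble with columns `nal2`, `het2`, `var2`, `fst`,
#'   `das`, `dm2`, `lik_ab`, `lik_ba`.
#' @export
two_sample_stats <- function(data, pop_a, pop_b) {
  data <- as_msat_data(data)
  sub <- droplevels(dplyr::filter(data, .data$pop %in% c(pop_a, pop_b)))
  if (nlevels(sub$pop) != 2)
    abort_msat("both populations must be present and non-empty")
  sub$pop <- factor(sub$pop, levels = c(pop_a, pop_b))
  s <- summarize_dataset(sub)
  lab <- paste(pop_a, pop_b, sep = ".")
  tibble::tibble(
    nal2 = s[[paste0("NAL2_", lab)]],
    het2 = s[[paste0("HET2_", lab)]],
    var2 = s[[paste0("VAR2_", lab)]],
    fst = s[[paste0("FST_", lab)]],
    das = s[[paste0("DAS_", lab)]],
    dm2 = s[[paste0("DM2_", lab)]],
    lik_ab = s[[paste0("LIK_", pop_a, ".", pop_b)]],
    lik_ba = s[[paste0("LIK_", pop_b, ".", pop_a)]]
  )
}

#' Maximum-likelihood admixture coefficient for a population triple
#'
#' Finds the mixture weight `a` maximizing the multinomial likelihood of
#' the target population's allele counts under frequencies
#' `a * p1 + (1 - a) * p2`, where `p1`, `p2` are the parents' observed
#' allele frequencies; the log-likelihood is summed over loci and maximized
#' by golden-section search (tolerance 1e-4). When the parents' frequencies
#' are indistinguishable the coefficient is undefined and 0.5 is returned
#' with a warning.
#'
#' @param data Tidy genotype tibble.
#' @param target,parent1,parent2 Distinct population labels.
#' @return The estimated admixture proportion from `parent1`, in `[0, 1]`.
#' @export
three_sample_admixture <- function(data, target, parent1, parent2) {
  data <- as_msat_data(data)
  labs <- c(target, parent1, parent2)
  if (anyDuplicated(labs)) abort_msat("the three populations must be distinct")
  arr <- genotype_arrays(data)
  pid <- match(labs, arr$pop_levels)
  if (anyNA(pid)) abort_msat("population label not present in the data")
  ll <- function(a) {
    tot <- 0
    for (m in arr$gmats) {
      ct <- allele_counts(m, arr$pop == pid[1])
      c1 <- allele_counts(m, arr$pop == pid[2])
      c2 <- allele_counts(m, arr$pop == pid[3])
      if (sum(ct) == 0 || sum(c1) == 0 || sum(c2) == 0) next
      alle <- sort(unique(c(names(ct), names(c1), names(c2))))
      nt <- as.numeric(ct[alle]); nt[is.na(nt)] <- 0
      p1 <- as.numeric(c1[alle]) / sum(c1); p1[is.na(p1)] <- 0
      p2 <- as.numeric(c2[alle]) / sum(c2); p2[is.na(p2)] <- 0
      mix <- pmax(a * p1 + (1 - a) * p2, 1e-12)
      tot <- tot + sum(nt * log(mix))
    }
    tot
  }
  if (abs(ll(0) - ll(1)) < 1e-12 && abs(ll(0.5) - ll(0)) < 1e-12) {
    warning("parent populations indistinguishable; admixture coefficient undefined, returning 0.5")
    return(0.5)
  }
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE, tol = 1e-5)
  # the optimum may sit on a boundary
  cand <- c(0, opt$maximum, 1)
  cand[which.max(vapply(cand, ll, 0))]
}
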
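#' Simulate one microsatellite locus under a demographic scenario
#'
#' Runs the backward-time structured coalescent for the sampled gene copies
#' (two per diploid individual), then drops mutations on the genealogy under
#' the generalized stepwise model: mutation events arrive as a Poisson
#' process at the locus rate, each changes the repeat count by a geometric
#' number of units (strict stepwise when `P = 0`), with equiprobable sign
#' and reflection at the allele-window boundaries.
#'
#' @param scenario An `msat_scenario`.
#' @param draw An `msat_draw` for that scenario (see [sample_draw()]).
#' @param locus One row of a locus panel, see [default_loci()].
#' @param locus_index Which entry of `draw$mu` / `draw$P` to use.
#' @param seed Optional integer seed (set just before simulation).
#' @param log_steps Keep the per-mutation step sizes (for diagnostics).
#' @return A list: `alleles` (integer repeat counts for all gene copies,
#'   population-major order), `pop` (population index per copy), `tmrca`,
#'   and `steps` when `log_steps = TRUE`.
#' @export
simulate_locus <- function(scenario, draw, locus = default_loci(1)[1, ],
                           locus_index = 1, seed = NULL, log_steps = FALSE) {
  if (!inherits(draw, "msat_draw") || draw$scenario != scenario$id)
    abort_msat("draw does not belong to this scenario")
  if (!is.null(seed)) set.seed(seed)
  copies <- 2L * scenario$lineages$n
  if (all(copies == 0))
    return(list(alleles = integer(0), pop = integer(0)))
  win <- locus_window(locus$ancestral, locus$states)
  res <- sim_locus_cpp(copies, ne_for_draw(scenario, draw),
                       events_for_draw(scenario, draw),
                       draw$mu[locus_index], draw$P[locus_index],
                       locus$ancestral, win[["lo"]], win[["hi"]],
                       log_steps)
  res$pop <- rep(seq_along(copies), copies)
  res
}

# Batch path used by the reference-table builder: all loci of one dataset,
# returned in the array layout sumstats_cpp() consumes. Per-locus RNG
# substreams are derived from `seed` so earlier loci are unchanged when the
# panel grows.
simulate_arrays <- function(scenario, draw, loci = default_loci(), seed,
                            missing_rate = 0) {
  copies <- 2L * scenario$lineages$n
  ne <- ne_for_draw(scenario, draw)
  evs <- events_for_draw(scenario, draw)
  nind <- sum(scenario$lineages$n)
  pop <- rep(seq_len(nrow(scenario$lineages)), scenario$lineages$n)
  gmats <- vector("list", nrow(loci))
  for (l in seq_len(nrow(loci))) {
    set.seed(derive_seed(seed, l))
    win <- locus_window(loci$ancestral[l], loci$states[l])
    res <- sim_locus_cpp(copies, ne, evs, draw$mu[l], draw$P[l],
                         loci$ancestral[l], win[["lo"]], win[["hi"]], FALSE)
    gmats[[l]] <- matrix(res$alleles, nrow = 2)  # consecutive copies pair up
  }
  names(gmats) <- loci$locus
  if (missing_rate > 0) {
    set.seed(derive_seed(seed, 0))
    for (l in seq_along(gmats)) {
      hit <- runif(nind) < missing_rate
      gmats[[l]][, hit] <- NA_integer_
    }
  }
  list(gmats = gmats, pop = pop,
       pop_levels = scenario$lineages$lineage)
}

#' Simulate a full diploid genotype dataset under a scenario
#'
#' Simulates every locus of the panel independently (consecutive gene copies
#' within a population are paired into diploid individuals) and returns a
#' tidy genotype table. The run is deterministic given
#' `(scenario, draw, seed)`; per-locus random substreams are derived from the
#' master seed, so adding loci to the panel never perturbs earlier loci.
#'
#' @inheritParams simulate_locus
#' @param loci Locus panel tibble, see [default_loci()].
#' @param seed Master integer seed for the dataset.
#' @param missing_rate Probability that a genotype call is masked to `NA`.
#' @return A tidy genotype tibble (see [as_msat_data()]) whose populations
#'   are the scenario's sampled lineages.
#' @examples
#' set.seed(1)
#' cfg <- scenarios_caucasus()
#' dr <- sample_draw(cfg$priors, cfg$scenarios[[1]])
#' sim <- simulate_dataset(cfg$scenarios[[1]], dr, seed = 42)
#' dplyr::count(sim, pop)
#' @export
simulate_dataset <- function(scenario, draw, loci = default_loci(), seed,
                             missing_rate = 0) {
  if (!inherits(draw, "msat_draw") || draw$scenario != scenario$id)
    abort_msat("draw does not belong to this scenario")
  if (length(draw$mu) < nrow(loci))
    abort_msat("draw has fewer per-locus rates than the locus panel")
  arr <- simulate_arrays(scenario, draw, loci, seed, missing_rate)
  out <- arrays_to_tibble(arr$gmats, arr$pop, arr$pop_levels)
  attr(out, "loci") <- loci$locus
  attr(out, "seed") <- seed
  out
}
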
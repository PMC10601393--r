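# shared builders for the test suite; everything is generated in code

# a tiny genotype tibble from a named list of per-population genotype
# matrices: each element is a list of loci, each locus a 2 x n matrix
toy_data <- function(pops) {
  rows <- list()
  for (p in names(pops)) {
    loci <- pops[[p]]
    nind <- ncol(loci[[1]])
    for (l in seq_along(loci)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        pop = p, ind = paste0(p, seq_len(nind)),
        locus = names(loci)[l] %||% paste0("L", l),
        a1 = loci[[l]][1, ], a2 = loci[[l]][2, ]
      )
    }
  }
  as_msat_data(dplyr::bind_rows(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype matrix from explicit allele pairs: gm(c(10,12), c(10,10), ...)
gm <- function(...) {
  g <- cbind(...)
  storage.mode(g) <- "integer"
  g
}

# random diploid population drawn from given allele frequencies (HWE)
hwe_pop <- function(n, alleles, freqs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(alleles, 2 * n, TRUE, prob = freqs), nrow = 2)
}

# a two-population, single-scenario configuration used by several tests
mini_cfg <- function(ne_lo = 100, ne_hi = 30000, n1 = 15, n2 = 15,
                     extra = "") {
  load_scenario_set(sprintf("
[settings]
n_loci = 3
[lineages]
A Ne=NeA n=%d
B Ne=NeB n=%d
[scenario 1]
split time=t1 derived=B ancestor=A
%s
[priors]
NeA = uniform(%g, %g)
NeB = uniform(%g, %g)
t1 = uniform(10, 5000)
mu_mean = uniform(1e-4, 1e-3)
P_mean = uniform(0.1, 0.3)
", n1, n2, extra, ne_lo, ne_hi, ne_lo, ne_hi))
}

# two-scenario toy with non-overlapping Ne priors (separable classes)
separable_cfg <- function() {
  load_scenario_set("
[settings]
n_loci = 3
[lineages]
A Ne=NeSmall n=10
B Ne=NeSmall n=10
[scenario 1]
split time=t1 derived=B ancestor=A
[scenario 2]
ne A=NeBig B=NeBig
split time=t1 derived=B ancestor=A
[priors]
NeSmall = uniform(100, 200)
NeBig = uniform(20000, 30000)
t1 = uniform(10, 1000)
mu_mean = uniform(5e-4, 1e-3)
P_mean = uniform(0.1, 0.3)
")
}
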
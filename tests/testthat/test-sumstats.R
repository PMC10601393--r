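# independent R oracle for the two-population Weir-Cockerham estimator,
# written directly from the 1984 variance-component formulas
wc_fst_oracle <- function(data, pop_a, pop_b) {
  arr <- msatabc:::genotype_arrays(data)
  ia <- which(arr$pop == match(pop_a, arr$pop_levels))
  ib <- which(arr$pop == match(pop_b, arr$pop_levels))
  num <- 0; den <- 0
  for (m in arr$gmats) {
    ga <- m[, ia, drop = FALSE]; gb <- m[, ib, drop = FALSE]
    ga <- ga[, !is.na(ga[1, ]) & !is.na(ga[2, ]), drop = FALSE]
    gb <- gb[, !is.na(gb[1, ]) & !is.na(gb[2, ]), drop = FALSE]
    n1 <- ncol(ga); n2 <- ncol(gb)
    if (n1 < 1 || n2 < 1 || n1 + n2 < 3) next
    alle <- unique(c(as.vector(ga), as.vector(gb)))
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
    for (al in alle) {
      p1 <- mean(ga == al); p2 <- mean(gb == al)
      h1 <- mean(ga[1, ] != ga[2, ] & (ga[1, ] == al | ga[2, ] == al))
      h2 <- mean(gb[1, ] != gb[2, ] & (gb[1, ] == al | gb[2, ] == al))
      pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
      hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
      inner <- pbar * (1 - pbar) - s2 / 2
      a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a; den <- den + a + b + cc
    }
  }
  num / den
}

random_dataset <- function(npop = 3, nind = 12, nloc = 4, seed = 1,
                           miss = 0.05) {
  set.seed(seed)
  pops <- lapply(seq_len(npop), function(p) {
    lapply(seq_len(nloc), function(l) {
      m <- matrix(sample(28:33, 2 * nind, TRUE), nrow = 2)
      m[, runif(nind) < miss] <- NA_integer_
      storage.mode(m) <- "integer"
      m
    })
  })
  names(pops) <- paste0("P", seq_len(npop))
  toy_data(pops)
}

test_that("one-sample statistics match hand-computed values", {
  # p = (0.5, 0.5) over 20 gene copies: unbiased het = (20/19) * 0.5
  d <- toy_data(list(A = list(L1 = gm(
    c(150, 152), c(150, 152), c(150, 152), c(150, 152), c(150, 152),
    c(150, 150), c(152, 152), c(150, 152), c(150, 152), c(152, 150)))))
  s <- one_sample_stats(d)
  expect_equal(s$het, 20 / 19 * 0.5, tolerance = 1e-12)
  expect_equal(s$nal, 2)
  # Garza-Williamson with alleles {10, 12, 14}: 3 / (4 + 1)
  d2 <- toy_data(list(A = list(L1 = gm(c(10, 12), c(12, 14), c(10, 14)))))
  expect_equal(one_sample_stats(d2)$mgw, 0.6, tolerance = 1e-12)
  # monomorphic locus
  d3 <- toy_data(list(A = list(L1 = gm(c(30, 30), c(30, 30)))))
  s3 <- one_sample_stats(d3)
  expect_equal(unlist(s3), c(nal = 1, het = 0, var = 0, mgw = 1))
})

test_that("two-sample statistics follow their definitions", {
  # identical populations: DAS and DM2 vanish, F_ST is the small
  # Weir-Cockerham duplicate-sample value, not exactly zero
  A <- list(L1 = gm(c(30, 31), c(30, 30), c(31, 32), c(32, 32), c(30, 31)))
  d <- toy_data(list(A = A, B = A))
  s <- two_sample_stats(d, "A", "B")
  # DAS oracle: mean over all inter-population individual pairs of
  # 1 - (shared alleles)/2; zero only when every individual is identical
  das_oracle <- function(ga, gb) {
    tot <- 0; n <- 0
    for (i in seq_len(ncol(ga))) for (j in seq_len(ncol(gb))) {
      x <- ga[, i]; y <- gb[, j]
      sh <- if (x[1] == x[2]) sum(y == x[1]) else
        as.integer(x[1] %in% y) + as.integer(x[2] %in% y)
      tot <- tot + 1 - sh / 2; n <- n + 1
    }
    tot / n
  }
  expect_equal(s$das, das_oracle(A$L1, A$L1), tolerance = 1e-12)
  dsame <- toy_data(list(A = list(L1 = gm(c(30, 31), c(30, 31))),
                         B = list(L1 = gm(c(30, 31), c(30, 31)))))
  expect_equal(two_sample_stats(dsame, "A", "B")$das, 0)
  expect_equal(s$dm2, 0)
  expect_equal(s$fst, wc_fst_oracle(d, "A", "B"), tolerance = 1e-12)
  expect_lt(abs(s$fst), 0.15)
  # fixed difference: F_ST = 1
  dfix <- toy_data(list(A = list(L1 = gm(c(30, 30), c(30, 30))),
                        B = list(L1 = gm(c(35, 35), c(35, 35)))))
  expect_equal(two_sample_stats(dfix, "A", "B")$fst, 1)
  # mean size 10 vs 13 at every locus: DM2 = 9
  dms <- toy_data(list(A = list(L1 = gm(c(10, 10), c(10, 10)),
                                L2 = gm(c(9, 11), c(10, 10))),
                       B = list(L1 = gm(c(13, 13), c(13, 13)),
                                L2 = gm(c(12, 14), c(13, 13)))))
  expect_equal(two_sample_stats(dms, "A", "B")$dm2, 9)
})

test_that("the C++ F_ST matches the independent oracle to 1e-10", {
  for (seed in 1:5) {
    d <- random_dataset(npop = 3, seed = seed)
    for (pr in list(c("P1", "P2"), c("P1", "P3"), c("P2", "P3"))) {
      got <- two_sample_stats(d, pr[1], pr[2])$fst
      expect_equal(got, wc_fst_oracle(d, pr[1], pr[2]), tolerance = 1e-10)
    }
  }
})

test_that("feature counts follow the battery formula", {
  expect_equal(n_sumstats(5), 130L)
  expect_equal(n_sumstats(2), 16L)
  expect_equal(n_sumstats(3), 39L)
  expect_equal(ncol(summarize_dataset(random_dataset(2))), 16)
  expect_equal(ncol(summarize_dataset(random_dataset(3))), 39)
  expect_equal(ncol(summarize_dataset(random_dataset(5, nind = 8))), 130)
})

test_that("statistics are invariant to individual order within populations", {
  d <- random_dataset(npop = 3, seed = 42)
  s1 <- summarize_dataset(d)
  set.seed(1)
  d2 <- d |>
    dplyr::group_by(pop) |>
    dplyr::group_modify(function(g, k) {
      ids <- unique(g$ind)
      ord <- sample(ids)
      g$ord <- match(g$ind, ord)
      dplyr::arrange(g, ord, locus) |> dplyr::select(-ord)
    }) |>
    dplyr::ungroup()
  s2 <- summarize_dataset(as_msat_data(d2))
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-12)
})

test_that("range constraints hold across simulated datasets", {
  cfg <- scenarios_caucasus()
  set.seed(30)
  for (k in 1:3) {
    sc <- cfg$scenarios[[sample(8, 1)]]
    dr <- sample_draw(cfg$priors, sc)
    s <- summarize_dataset(simulate_dataset(sc, dr, seed = 400 + k))
    v <- as.numeric(s)
    nm <- names(s)
    expect_true(all(v[grepl("^HET", nm)] >= 0 & v[grepl("^HET", nm)] <= 1))
    expect_true(all(v[grepl("^MGW", nm)] >= 0 & v[grepl("^MGW", nm)] <= 1))
    expect_true(all(v[grepl("^DAS", nm)] >= 0 & v[grepl("^DAS", nm)] <= 1))
    expect_true(all(v[grepl("^AML", nm)] >= 0 & v[grepl("^AML", nm)] <= 1))
    expect_true(all(v[grepl("^VAR|^DM2", nm)] >= 0))
    expect_true(all(v[grepl("^FST", nm)] <= 1 & v[grepl("^FST", nm)] > -0.2))
    expect_true(all(is.finite(v)))
  }
})

test_that("admixture coefficient recovers known mixtures", {
  make_pops <- function(a, n_target = 1000, seed = 1) {
    set.seed(seed)
    # two well-separated parents at 3 loci
    p1 <- list(c(10, 11), c(20, 21), c(30, 31))
    p2 <- list(c(15, 16), c(25, 26), c(35, 36))
    par_pop <- function(alle) lapply(alle, function(al) {
      m <- matrix(sample(al, 2 * 400, TRUE), nrow = 2)
      storage.mode(m) <- "integer"; m
    })
    tgt <- lapply(seq_len(3), function(l) {
      pool <- c(p1[[l]], p2[[l]])
      pr <- c(rep(a / 2, 2), rep((1 - a) / 2, 2))
      m <- matrix(sample(pool, 2 * n_target, TRUE, prob = pr), nrow = 2)
      storage.mode(m) <- "integer"; m
    })
    toy_data(list(T = tgt, P1 = par_pop(p1), P2 = par_pop(p2)))
  }
  # pure parent 1
  expect_gt(three_sample_admixture(make_pops(1), "T", "P1", "P2"), 0.995)
  # 50:50 and 0.71 mixtures at n = 2000 gene copies
  expect_lt(abs(three_sample_admixture(make_pops(0.5, seed = 2), "T", "P1", "P2") - 0.5), 0.05)
  expect_lt(abs(three_sample_admixture(make_pops(0.71, seed = 3), "T", "P1", "P2") - 0.71), 0.05)
  # identical parents: undefined, flagged
  same <- toy_data(list(T = list(gm(c(10, 11), c(10, 10))),
                        P1 = list(gm(c(10, 11), c(11, 11))),
                        P2 = list(gm(c(10, 11), c(11, 11)))))
  expect_warning(a0 <- three_sample_admixture(same, "T", "P1", "P2"),
                 "indistinguishable")
  expect_equal(a0, 0.5)
})

test_that("R per-operation statistics agree with the C++ batch vector", {
  d <- random_dataset(npop = 3, nind = 15, nloc = 5, seed = 99)
  s <- summarize_dataset(d)
  for (p in c("P1", "P2", "P3")) {
    os <- one_sample_stats(d, pop = p)
    expect_equal(os$nal, s[[paste0("NAL_", p)]], tolerance = 1e-12)
    expect_equal(os$het, s[[paste0("HET_", p)]], tolerance = 1e-12)
    expect_equal(os$var, s[[paste0("VAR_", p)]], tolerance = 1e-12)
    expect_equal(os$mgw, s[[paste0("MGW_", p)]], tolerance = 1e-12)
  }
  aml <- three_sample_admixture(d, "P2", "P1", "P3")
  expect_equal(aml, s[["AML_P2_P1.P3"]], tolerance = 2e-4)
})
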
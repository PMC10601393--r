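# Classical diversity and differentiation statistics on microsatellite
# genotype tables: GenAlEx-style diversity, FSTAT-style rarefied allelic
# richness and permutation tests, Weir-Cockerham F-statistics, the
# maximum-likelihood null-allele model and the "excluding null alleles"
# corrected F_ST with a bootstrap over loci.

# per-(pop, locus) tallies used throughout this file
pop_locus_tallies <- function(data) {
  arr <- genotype_arrays(data)
  out <- list()
  for (p in seq_along(arr$pop_levels)) {
    keep <- arr$pop == p
    for (l in seq_along(arr$gmats)) {
      m <- arr$gmats[[l]][, keep, drop = FALSE]
      ok <- !is.na(m[1, ]) & !is.na(m[2, ])
      g <- m[, ok, drop = FALSE]
      cnt <- table(as.vector(g))
      # heterozygous individuals carrying each allele (one count per allele)
      hetm <- g[, g[1, ] != g[2, ], drop = FALSE]
      hets <- table(c(hetm[1, ], hetm[2, ]))
      out[[paste(p, l, sep = ".")]] <- list(
        pop = arr$pop_levels[p], locus = arr$loci[l],
        cnt = cnt, hets = hets,
        n_ind = sum(ok), n_blank = sum(!ok),
        ho = if (sum(ok) > 0) mean(g[1, ] != g[2, ]) else NA_real_
      )
    }
  }
  attr(out, "pop_levels") <- arr$pop_levels
  attr(out, "loci") <- arr$loci
  out
}

#' Per-population diversity summary
#'
#' GenAlEx-style table: mean number of alleles per locus (`A`), private
#' allele count (`Pa`, alleles seen in exactly one population), observed
#' heterozygosity (`Ho`), Nei's unbiased expected heterozygosity (`uHe`,
#' `(2n/(2n-1))(1 - sum p^2)` averaged over loci) and the inbreeding
#' coefficient `Fis = 1 - Ho/uHe` (ratio of locus means). Loci with no
#' genotyped individual in a population are excluded from that
#' population's means.
#'
#' @param data Tidy genotype tibble (see [as_msat_data()]).
#' @return A tibble with one row per population and columns
#'   `pop`, `n`, `A`, `Pa`, `Ho`, `uHe`, `Fis`.
#' @export
basic_diversity <- function(data) {
  tal <- pop_locus_tallies(data)
  pops <- attr(tal, "pop_levels")
  loci <- attr(tal, "loci")
  # which populations carry each allele, per locus
  carriers <- list()
  for (t in tal)
    for (a in names(t$cnt))
      carriers[[paste(t$locus, a)]] <- union(carriers[[paste(t$locus, a)]], t$pop)
  purrr::map_dfr(pops, function(p) {
    ts <- purrr::keep(tal, function(t) t$pop == p && t$n_ind > 0)
    if (length(ts) == 0)
      abort_msat(paste0("population ", p, " has no genotyped individuals"))
    A <- mean(vapply(ts, function(t) length(t$cnt), 0))
    Ho <- mean(vapply(ts, function(t) t$ho, 0))
    uHe <- mean(vapply(ts, function(t) {
      n2 <- 2 * t$n_ind
      if (n2 < 2) return(NA_real_)
      pfr <- as.numeric(t$cnt) / n2
      n2 / (n2 - 1) * (1 - sum(pfr^2))
    }, 0), na.rm = TRUE)
    Pa <- sum(vapply(ts, function(t) {
      sum(vapply(names(t$cnt), function(a)
        identical(carriers[[paste(t$locus, a)]], p), TRUE))
    }, 0))
    tibble::tibble(
      pop = p,
      n = max(vapply(ts, function(t) t$n_ind + t$n_blank, 0)),
      A = A, Pa = as.integer(Pa), Ho = Ho, uHe = uHe,
      Fis = if (uHe > 0) 1 - Ho / uHe else NA_real_
    )
  })
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, computed hypergeometrically per locus
#' (`Ar = sum_a [1 - C(n - n_a, g) / C(n, g)]`) and averaged over loci, the
#' estimator FSTAT uses to compare samples of unequal size.
#'
#' @param data Tidy genotype tibble.
#' @param g Rarefaction size in gene copies; default: the smallest number of
#'   genotyped copies over all population-locus combinations.
#' @param per_locus Return the per-locus values instead of population means.
#' @return A tibble `pop`, `g`, `Ar` (or `pop`, `locus`, `g`, `Ar`).
#' @export
allelic_richness <- function(data, g = NULL, per_locus = FALSE) {
  tal <- pop_locus_tallies(data)
  ns <- vapply(tal, function(t) 2 * t$n_ind, 0)
  if (is.null(g)) g <- min(ns[ns > 0])
  if (g < 2) abort_msat("rarefaction size g must be at least 2")
  if (g > min(ns[ns > 0]))
    abort_msat(sprintf(
      "g = %d exceeds the smallest genotyped sample (%d gene copies)",
      g, as.integer(min(ns[ns > 0]))))
  rows <- purrr::map_dfr(tal, function(t) {
    n <- 2 * t$n_ind
    if (n < g) return(NULL)
    ar <- sum(1 - exp(lchoose(n - as.numeric(t$cnt), g) - lchoose(n, g)))
    tibble::tibble(pop = t$pop, locus = t$locus, g = g, Ar = ar)
  })
  if (per_locus) return(rows)
  rows |>
    dplyr::group_by(.data$pop) |>
    dplyr::summarise(g = g[1], Ar = mean(.data$Ar), .groups = "drop")
}

# Weir-Cockerham (1984) variance components for one locus over r
# populations. Returns per-allele sums of the a, b, c components.
wc_components <- function(cnts, hets, n_inds) {
  use <- n_inds > 0
  cnts <- cnts[use]; hets <- hets[use]; n_inds <- n_inds[use]
  r <- length(n_inds)
  if (r < 2 || sum(n_inds) < 3) return(c(a = 0, b = 0, c = 0, valid = 0))
  alle <- sort(unique(unlist(lapply(cnts, names))))
  if (length(alle) < 2) {
    # monomorphic locus: defined but contributes nothing
  }
  nbar <- mean(n_inds)
  nc <- (r * nbar - sum(n_inds^2) / (r * nbar)) / (r - 1)
  if (nbar <= 1 || nc <= 0) return(c(a = 0, b = 0, c = 0, valid = 0))
  A <- 0; B <- 0; C <- 0
  for (al in alle) {
    p_i <- vapply(seq_len(r), function(i) {
      v <- cnts[[i]][al]
      (if (is.na(v)) 0 else as.numeric(v)) / (2 * n_inds[i])
    }, 0)
    h_i <- vapply(seq_len(r), function(i) {
      v <- hets[[i]][al]
      (if (is.na(v)) 0 else as.numeric(v)) / n_inds[i]
    }, 0)
    pbar <- sum(n_inds * p_i) / (r * nbar)
    s2 <- sum(n_inds * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_inds * h_i) / (r * nbar)
    inner <- pbar * (1 - pbar) - (r - 1) / r * s2
    A <- A + nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
    B <- B + nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
    C <- C + hbar / 2
  }
  c(a = A, b = B, c = C, valid = 1)
}

tallies_by_locus <- function(tal) {
  loci <- attr(tal, "loci")
  pops <- attr(tal, "pop_levels")
  lapply(loci, function(l) {
    ts <- purrr::keep(tal, function(t) t$locus == l)
    ts <- ts[match(pops, vapply(ts, function(t) t$pop, ""))]
    list(cnts = lapply(ts, function(t) t$cnt),
         hets = lapply(ts, function(t) t$hets),
         n_inds = vapply(ts, function(t) t$n_ind, 0))
  })
}

#' Weir-Cockerham F-statistics
#'
#' Multi-locus \eqn{F_{ST}}, \eqn{F_{IT}} and \eqn{F_{IS}} as ratios of
#' variance components summed over loci and alleles, plus the pairwise
#' \eqn{F_{ST}} matrix and a per-population \eqn{F_{IS}} (the b/c component
#' ratio computed within each population alone).
#'
#' @param data Tidy genotype tibble with at least two populations.
#' @return A list of class `msat_fstats`: `global` (one-row tibble with
#'   `Fst`, `Fit`, `Fis`), `pairwise` (tibble `pop_a`, `pop_b`, `Fst`) and
#'   `fis_pop` (tibble `pop`, `Fis`). Undefined ratios (fully monomorphic
#'   data) are `NA`.
#' @export
wc_fstats <- function(data) {
  tal <- pop_locus_tallies(data)
  pops <- attr(tal, "pop_levels")
  if (length(pops) < 2) abort_msat("F_ST needs at least two populations")
  byloc <- tallies_by_locus(tal)

  comp_sum <- function(sel) {
    tot <- c(a = 0, b = 0, c = 0)
    for (bl in byloc) {
      v <- wc_components(bl$cnts[sel], bl$hets[sel], bl$n_inds[sel])
      tot <- tot + v[c("a", "b", "c")]
    }
    tot
  }
  all_idx <- seq_along(pops)
  tot <- comp_sum(all_idx)
  denom <- sum(tot)
  global <- tibble::tibble(
    Fst = if (denom != 0) tot[["a"]] / denom else NA_real_,
    Fit = if (denom != 0) 1 - tot[["c"]] / denom else NA_real_,
    Fis = if (tot[["b"]] + tot[["c"]] != 0)
      1 - tot[["c"]] / (tot[["b"]] + tot[["c"]]) else NA_real_
  )
  pw <- pop_pairs(length(pops))
  pairwise <- purrr::map_dfr(seq_len(nrow(pw)), function(k) {
    tt <- comp_sum(pw[k, ])
    d <- sum(tt)
    tibble::tibble(pop_a = pops[pw[k, 1]], pop_b = pops[pw[k, 2]],
                   Fst = if (d != 0) tt[["a"]] / d else NA_real_)
  })
  # per-population Fis from the within-population components (r = 1 has no
  # 'a' term; use b and c computed against the population itself)
  fis_pop <- purrr::map_dfr(seq_along(pops), function(i) {
    B <- 0; C <- 0
    for (bl in byloc) {
      n <- bl$n_inds[i]
      if (n < 2) next
      cnt <- bl$cnts[[i]]; hets <- bl$hets[[i]]
      for (al in names(cnt)) {
        p <- as.numeric(cnt[al]) / (2 * n)
        h <- if (!is.na(hets[al])) as.numeric(hets[al]) / n else 0
        B <- B + n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
        C <- C + h / 2
      }
    }
    tibble::tibble(pop = pops[i],
                   Fis = if (B + C != 0) 1 - C / (B + C) else NA_real_)
  })
  structure(list(global = global, pairwise = pairwise, fis_pop = fis_pop),
            class = "msat_fstats")
}

#' @export
print.msat_fstats <- function(x, ...) {
  cat("<msat_fstats> global:\n")
  print(x$global)
  cat("pairwise F_ST:\n")
  print(x$pairwise, n = 10)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.msat_fstats <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.msat_fstats <- function(x, ...) x$global

#' Maximum-likelihood null-allele frequencies (EM)
#'
#' Fits, per population and locus, the null-allele model in which apparent
#' homozygotes are a mixture of true homozygotes and heterozygotes carrying
#' one null allele, and blank genotypes are null homozygotes
#' (`blanks = "null"`, the default) or are ignored
#' (`blanks = "ignore"`, for data whose blanks are genotyping failures).
#' The EM iterates expected allele counts until the null-frequency change
#' drops below `tol`.
#'
#' @param data Tidy genotype tibble.
#' @param blanks How blank genotypes enter the model (see above).
#' @param tol Convergence tolerance on the null frequency.
#' @param max_iter Iteration cap; non-convergence is flagged, not fatal.
#' @return A tibble `pop`, `locus`, `null_freq`, `n_ind`, `converged`,
#'   `iterations`.
#' @export
null_allele_em <- function(data, blanks = c("null", "ignore"),
                           tol = 1e-8, max_iter = 1e4) {
  blanks <- match.arg(blanks)
  tal <- pop_locus_tallies(data)
  purrr::map_dfr(tal, function(t) {
    N_vis <- t$n_ind
    N_blank <- if (blanks == "null") t$n_blank else 0
    N <- N_vis + N_blank
    if (N == 0) return(NULL)
    if (N_vis == 0) {
      warning(sprintf("%s/%s: all genotypes blank; null frequency driven to 1",
                      t$pop, t$locus))
      return(tibble::tibble(pop = t$pop, locus = t$locus, null_freq = 1,
                            n_ind = N, converged = TRUE, iterations = 0L))
    }
    alle <- names(t$cnt)
    # per-allele homozygote and heterozygote-carrier counts
    het_car <- stats::setNames(rep(0, length(alle)), alle)
    het_car[names(t$hets)] <- as.numeric(t$hets)
    tot <- stats::setNames(as.numeric(t$cnt), alle)
    hom <- (tot - het_car) / 2   # individuals homozygous for each allele
    n_het_ind <- sum(het_car) / 2
    r <- max(0.5 / N, 0.01)
    p <- tot / sum(tot) * (1 - r)
    it <- 0L
    repeat {
      it <- it + 1L
      # E-step: split apparent homozygotes into true homs and a-null hets
      denom <- p^2 + 2 * p * r
      w_null <- ifelse(denom > 0, (2 * p * r) / denom, 0)
      e_anull <- hom * w_null          # individuals a/null
      # M-step: expected allele counts
      cnt_a <- 2 * (hom - e_anull) + e_anull + het_car
      cnt_null <- sum(e_anull) + 2 * N_blank
      tot_cnt <- sum(cnt_a) + cnt_null
      p_new <- cnt_a / tot_cnt
      r_new <- cnt_null / tot_cnt
      delta <- abs(r_new - r)
      p <- p_new; r <- r_new
      if (delta < tol || it >= max_iter) break
    }
    # the MLE can sit on the boundary r = 0 (no homozygote excess), where
    # plain EM converges only sublinearly; compare against the boundary fit
    loglik <- function(pp, rr) {
      hm <- sum(ifelse(hom > 0, hom * log(pmax(pp^2 + 2 * pp * rr, 1e-300)), 0))
      ht <- sum(ifelse(het_car > 0, het_car * log(pmax(pp, 1e-300)), 0)) +
        n_het_ind * log(2)
      bl <- if (N_blank > 0) N_blank * log(max(rr^2, 1e-300)) else 0
      hm + ht + bl
    }
    if (r < 1e-3 && N_blank == 0) {
      p0 <- tot / sum(tot)
      if (loglik(p0, 0) >= loglik(p, r) - 1e-9) { r <- 0; p <- p0 }
    }
    # expected a/null heterozygote counts at convergence (used by the ENA
    # correction, where the null is a real allelic state)
    denom <- p^2 + 2 * p * r
    e_anull <- ifelse(denom > 0, hom * (2 * p * r) / denom, 0)
    tibble::tibble(pop = t$pop, locus = t$locus, null_freq = r,
                   n_ind = N, converged = it < max_iter, iterations = it,
                   p_vis = list(p), e_null_het = list(e_anull))
  })
}

# ENA-corrected per-(pop, locus) tallies: the null allele is a real extra
# state -- visible alleles take the EM-corrected frequencies (summing to
# 1 - r), blanks re-enter the sample as null homozygotes, and the expected
# a/null heterozygotes are restored to each visible allele's heterozygote
# count. The null class itself is excluded from the variance-component
# sums. With r = 0 the tallies are returned untouched.
ena_adjusted <- function(bl, em_rows) {
  cnts <- bl$cnts; hets <- bl$hets; n_inds <- bl$n_inds
  for (i in seq_along(cnts)) {
    row <- em_rows[[i]]
    if (is.null(row)) next
    r <- row$null_freq
    if (is.na(r) || r <= 0) next
    n_tot <- row$n_ind          # genotyped + blank individuals
    if (n_tot == 0) next
    pv <- row$p_vis[[1]]
    alle <- names(cnts[[i]])
    if (!is.null(pv) && all(alle %in% names(pv))) {
      corr <- cnts[[i]]
      corr[] <- as.numeric(pv[alle]) * 2 * n_tot
      cnts[[i]] <- corr
      en <- row$e_null_het[[1]]
      hh <- stats::setNames(rep(0, length(alle)), alle)
      hh[names(hets[[i]])] <- as.numeric(hets[[i]])
      if (!is.null(en) && all(alle %in% names(en)))
        hh <- hh + as.numeric(en[alle])
      hets[[i]] <- hh
      n_inds[i] <- n_tot
    } else {
      cnts[[i]] <- cnts[[i]] * (1 - r)
    }
  }
  list(cnts = cnts, hets = hets, n_inds = n_inds)
}

#' Null-allele-corrected F_ST ("excluding null alleles")
#'
#' Recomputes the Weir-Cockerham \eqn{F_{ST}} with each population-locus
#' allele-frequency set augmented by a null-allele class (frequency from
#' [null_allele_em()], or supplied) whose contribution is excluded from the
#' variance-component sums, the correction FreeNA popularized for
#' microsatellites with null alleles. Confidence intervals come from a
#' percentile bootstrap over loci.
#'
#' @param data Tidy genotype tibble with at least two populations.
#' @param null_freqs Tibble `pop`, `locus`, `null_freq` (as returned by
#'   [null_allele_em()]); `NULL` estimates them first. Zeros reproduce the
#'   uncorrected estimator exactly.
#' @param n_boot Bootstrap replicates over loci (the conventional choice is
#'   `1e4`); 0 skips the CI.
#' @param level CI level.
#' @param seed Integer seed for the bootstrap.
#' @return A list of class `msat_fst_ena`: `global` (tibble with corrected
#'   and uncorrected \eqn{F_{ST}} and CIs), `pairwise`, and the
#'   `null_freqs` used.
#' @export
fst_ena <- function(data, null_freqs = NULL, n_boot = 1e4, level = 0.95,
                    seed = 1L) {
  tal <- pop_locus_tallies(data)
  pops <- attr(tal, "pop_levels")
  loci <- attr(tal, "loci")
  if (length(pops) < 2) abort_msat("F_ST needs at least two populations")
  if (is.null(null_freqs)) null_freqs <- null_allele_em(data)
  byloc <- tallies_by_locus(tal)
  em_row <- function(p, l) {
    k <- which(null_freqs$pop == p & null_freqs$locus == l)
    if (length(k) == 0) NULL else null_freqs[k[1], ]
  }

  # per-locus components, corrected and uncorrected, for a subset of pops
  locus_comps <- function(sel) {
    t(vapply(seq_along(byloc), function(l) {
      bl <- byloc[[l]]
      sub <- list(cnts = bl$cnts[sel], hets = bl$hets[sel],
                  n_inds = bl$n_inds[sel])
      raw <- wc_components(sub$cnts, sub$hets, sub$n_inds)
      rows <- lapply(pops[sel], em_row, l = loci[l])
      adj <- ena_adjusted(sub, rows)
      cor <- wc_components(adj$cnts, adj$hets, adj$n_inds)
      c(a = raw[["a"]], abc = sum(raw[c("a", "b", "c")]),
        a_c = cor[["a"]], abc_c = sum(cor[c("a", "b", "c")]))
    }, numeric(4)))
  }
  ratio <- function(m, idx = seq_len(nrow(m))) {
    s <- colSums(m[idx, , drop = FALSE])
    c(fst = if (s[["abc"]] != 0) s[["a"]] / s[["abc"]] else NA_real_,
      fst_ena = if (s[["abc_c"]] != 0) s[["a_c"]] / s[["abc_c"]] else NA_real_)
  }
  boot_ci <- function(m) {
    if (n_boot <= 0) return(NULL)
    if (length(loci) < 2)
      warning("bootstrap over a single locus gives a degenerate CI")
    reps <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot))
      reps[b, ] <- ratio(m, sample.int(nrow(m), replace = TRUE))
    alpha <- (1 - level) / 2
    list(fst = quantile(reps[, 1], c(alpha, 1 - alpha), na.rm = TRUE),
         ena = quantile(reps[, 2], c(alpha, 1 - alpha), na.rm = TRUE))
  }

  set.seed(seed)
  m_all <- locus_comps(seq_along(pops))
  r_all <- ratio(m_all)
  ci <- boot_ci(m_all)
  global <- tibble::tibble(
    Fst = r_all[["fst"]], Fst_ena = r_all[["fst_ena"]],
    ci_lo = ci$fst[[1]] %||% NA_real_, ci_hi = ci$fst[[2]] %||% NA_real_,
    ci_ena_lo = ci$ena[[1]] %||% NA_real_, ci_ena_hi = ci$ena[[2]] %||% NA_real_,
    level = level, n_boot = n_boot
  )
  pw <- pop_pairs(length(pops))
  pairwise <- purrr::map_dfr(seq_len(nrow(pw)), function(k) {
    m <- locus_comps(pw[k, ])
    rr <- ratio(m)
    tibble::tibble(pop_a = pops[pw[k, 1]], pop_b = pops[pw[k, 2]],
                   Fst = rr[["fst"]], Fst_ena = rr[["fst_ena"]])
  })
  structure(list(global = global, pairwise = pairwise,
                 null_freqs = null_freqs),
            class = "msat_fst_ena")
}

#' @export
print.msat_fst_ena <- function(x, ...) {
  g <- x$global
  cat(sprintf("<msat_fst_ena> F_ST = %.4f (%.0f%% CI %.4f-%.4f); ENA-corrected F_ST* = %.4f (%.4f-%.4f)\n",
              g$Fst, 100 * g$level, g$ci_lo, g$ci_hi,
              g$Fst_ena, g$ci_ena_lo, g$ci_ena_hi))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.msat_fst_ena <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.msat_fst_ena <- function(x, ...) x$global

# per-population value of a permutable statistic
pop_statistic <- function(data, statistic, g = NULL) {
  switch(statistic,
    He = basic_diversity(data) |> dplyr::select("pop", value = "uHe"),
    Ar = allelic_richness(data, g = g) |> dplyr::select("pop", value = "Ar"),
    Fis = wc_fstats(data)$fis_pop |> dplyr::select("pop", value = "Fis")
  )
}

#' Permutation test for a diversity contrast between population groups
#'
#' Assigns whole populations to groups, computes a per-group statistic
#' (mean `He`, `Ar` or `Fis` over the group's populations, or the
#' Weir-Cockerham `Fst` among them), and compares the observed group
#' contrast with its distribution under random reassignment of populations
#' to groups, the FSTAT group-comparison scheme. With two groups the
#' contrast is `|mean(group1) - mean(group2)|`; with more it is the variance
#' of the group values. `p = (1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param data Tidy genotype tibble.
#' @param grouping Named character vector mapping population label to group.
#' @param statistic One of `"He"`, `"Ar"`, `"Fis"`, `"Fst"`.
#' @param n_perm Number of permutations (the conventional choice is 9999).
#' @param seed Integer seed.
#' @param g Rarefaction size for `Ar` (default: data minimum).
#' @return A one-row tibble: `statistic`, `observed` (the contrast),
#'   `p_value`, `n_perm`, plus the per-group observed values nested in
#'   `groups`.
#' @export
group_permutation_test <- function(data, grouping,
                                   statistic = c("He", "Ar", "Fis", "Fst"),
                                   n_perm = 9999, seed = 1L, g = NULL) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) abort_msat("n_perm must be at least 1")
  data <- as_msat_data(data)
  pops <- levels(data$pop)
  if (!all(pops %in% names(grouping)))
    abort_msat("grouping must name every population")
  grp <- grouping[pops]
  if (any(table(grp) == 0) || length(unique(grp)) < 2)
    abort_msat("need at least two non-empty groups")

  pv <- if (statistic != "Fst") pop_statistic(data, statistic, g = g)
  group_values <- function(assign) {
    if (statistic == "Fst") {
      vapply(unique(assign), function(gg) {
        members <- pops[assign == gg]
        if (length(members) < 2) return(NA_real_)
        sub <- droplevels(dplyr::filter(data, .data$pop %in% members))
        wc_fstats(sub)$global$Fst
      }, 0)
    } else {
      vapply(unique(assign), function(gg)
        mean(pv$value[assign[match(pv$pop, pops)] == gg], na.rm = TRUE), 0)
    }
  }
  contrast <- function(vals) {
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2) return(NA_real_)
    if (length(vals) == 2) abs(vals[1] - vals[2]) else stats::var(vals)
  }
  obs_vals <- group_values(grp)
  obs <- contrast(obs_vals)
  set.seed(seed)
  perm_ge <- 0L
  for (b in seq_len(n_perm)) {
    pg <- sample(grp)
    names(pg) <- pops
    if (contrast(group_values(pg)) >= obs - 1e-15) perm_ge <- perm_ge + 1L
  }
  tibble::tibble(
    statistic = statistic,
    observed = obs,
    p_value = (1 + perm_ge) / (n_perm + 1),
    n_perm = n_perm,
    groups = list(tibble::tibble(group = unique(grp), value = obs_vals))
  )
}

#' Permutation test for pairwise differentiation
#'
#' Tests a pairwise \eqn{F_{ST}} by permuting individuals between the two
#' populations.
#'
#' @param data Tidy genotype tibble.
#' @param pop_a,pop_b Population labels.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A one-row tibble `pop_a`, `pop_b`, `Fst`, `p_value`, `n_perm`.
#' @export
fst_perm_test <- function(data, pop_a, pop_b, n_perm = 9999, seed = 1L) {
  data <- as_msat_data(data)
  sub <- droplevels(dplyr::filter(data, .data$pop %in% c(pop_a, pop_b)))
  if (nlevels(sub$pop) != 2) abort_msat("both populations must be present")
  obs <- wc_fstats(sub)$global$Fst
  inds <- dplyr::distinct(sub, .data$pop, .data$ind)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    shuf <- inds
    shuf$new_pop <- sample(inds$pop)
    ps <- dplyr::left_join(sub, shuf, by = c("pop", "ind"))
    ps$pop <- droplevels(ps$new_pop)
    ps$new_pop <- NULL
    if (wc_fstats(ps)$global$Fst >= obs - 1e-15) ge <- ge + 1L
  }
  tibble::tibble(pop_a = pop_a, pop_b = pop_b, Fst = obs,
                 p_value = (1 + ge) / (n_perm + 1), n_perm = n_perm)
}
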
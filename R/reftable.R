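#' Build a simulated reference table
#'
#' For each scenario, draws `n_per_scenario` parameter vectors from the
#' priors, simulates a genotype dataset of the design's sample sizes under
#' each, and summarizes it into the feature vector. The result is the
#' training table for the random-forest stages: one row per simulation with
#' the scenario label, the scalar parameter draw and the summary statistics.
#'
#' Rows are shuffled (permutation recorded in `attr(, "perm")`); the build
#' is deterministic given `seed`, with one substream per row.
#'
#' @param scenario_set An `msat_scenario_set` (see [load_scenario_set()]).
#' @param n_per_scenario Simulations per scenario (balanced design).
#' @param loci Locus panel, see [default_loci()].
#' @param seed Master integer seed.
#' @param scenarios Optional subset of scenario ids to simulate.
#' @param progress Print a line per 1000 rows.
#' @return A tibble of class `msat_reftable`: column `scenario` (factor),
#'   the scalar parameters (`NA` where a scenario does not use one), and
#'   the summary-statistic columns (recorded in `attr(, "stat_cols")`).
#'   Provenance (seed, priors hash, n per scenario) is in
#'   `attr(, "provenance")`.
#' @export
build_reference_table <- function(scenario_set, n_per_scenario,
                                  loci = default_loci(),
                                  seed = 1L, scenarios = NULL,
                                  progress = FALSE) {
  if (n_per_scenario < 1) abort_msat("n_per_scenario must be at least 1")
  scens <- scenario_set$scenarios
  if (!is.null(scenarios))
    scens <- scens[as.character(scenarios)]
  if (length(scens) == 0 || any(vapply(scens, is.null, TRUE)))
    abort_msat("unknown scenario id requested")
  priors <- scenario_set$priors
  pnames <- names(priors$params)
  labels <- vapply(scens, function(s) s$id, 0L)
  first <- TRUE
  nrow_tot <- length(scens) * n_per_scenario
  stats_mat <- NULL
  par_mat <- matrix(NA_real_, nrow_tot, length(pnames),
                    dimnames = list(NULL, pnames))
  scen_col <- integer(nrow_tot)
  r <- 0L
  for (s in scens) {
    scen_pars <- params_used(s)
    for (i in seq_len(n_per_scenario)) {
      r <- r + 1L
      rs <- derive_seed(seed, (match(s$id, labels) - 1L) * 1e7 + i)
      set.seed(rs)
      dr <- sample_draw(priors, s, n_loci = nrow(loci))
      arr <- simulate_arrays(s, dr, loci, seed = derive_seed(rs, 1L))
      v <- sumstats_cpp(arr$gmats, arr$pop, length(arr$pop_levels))
      if (first) {
        stats_mat <- matrix(NA_real_, nrow_tot, length(v))
        colnames(stats_mat) <- stat_names(arr$pop_levels)
        first <- FALSE
      }
      stats_mat[r, ] <- v
      par_mat[r, scen_pars] <- dr$params[scen_pars]
      scen_col[r] <- s$id
      if (progress && r %% 1000 == 0)
        message(sprintf("reference table: %d / %d rows", r, nrow_tot))
    }
  }
  set.seed(derive_seed(seed, 999983L))
  perm <- sample.int(nrow_tot)
  out <- tibble::as_tibble(cbind(as.data.frame(par_mat), as.data.frame(stats_mat)))
  out <- dplyr::bind_cols(
    tibble::tibble(scenario = factor(scen_col, levels = sort(unique(labels)))),
    out
  )[perm, ]
  attr(out, "stat_cols") <- colnames(stats_mat)
  attr(out, "param_cols") <- pnames
  attr(out, "perm") <- perm
  attr(out, "provenance") <- list(
    seed = seed, n_per_scenario = n_per_scenario,
    priors_hash = rlang::hash(priors),
    scenarios = unname(labels), n_loci = nrow(loci),
    package_version = as.character(utils::packageVersion("msatabc"))
  )
  class(out) <- c("msat_reftable", class(out))
  out
}

# scalar parameters a scenario actually uses (its Ne's, event times, ra,
# and the mutation means)
params_used <- function(scenario) {
  ps <- scenario$lineages$ne_param
  for (ev in scenario$events) {
    ps <- c(ps, ev$time_param)
    if (ev$kind == "admix") ps <- c(ps, ev$ra_param)
  }
  unique(c(ps, "mu_mean", "P_mean"))
}

#' Restrict a reference table to one scenario
#'
#' Subsetting with `[` drops the table's attributes; this keeps the feature
#' schema intact so the result feeds straight into [estimate_parameters()].
#'
#' @param table An `msat_reftable`.
#' @param scenario Scenario id (coerced to character).
#' @return The single-scenario `msat_reftable`.
#' @export
filter_scenario <- function(table, scenario) {
  out <- table[table$scenario == as.character(scenario), ]
  if (nrow(out) == 0) abort_msat("no rows for that scenario")
  for (a in c("stat_cols", "param_cols", "lda_cols", "lda_fit", "lda_keep",
              "provenance"))
    attr(out, a) <- attr(table, a)
  class(out) <- unique(c("msat_reftable", class(out)))
  out
}

reftable_stats <- function(table) {
  sc <- attr(table, "stat_cols")
  if (is.null(sc)) abort_msat("not a reference table: no stat_cols attribute")
  as.matrix(table[, sc, drop = FALSE])
}

#' Append linear discriminant axes to a reference table
#'
#' Fits an LDA of the summary statistics on the scenario label and appends
#' the `k - 1` discriminant scores as extra feature columns (`LD1`, ...).
#' The fitted projection is stored so an observed dataset is projected with
#' exactly the same axes. Near-constant statistics are dropped from the fit
#' (with a warning) to keep the within-class scatter invertible.
#'
#' @param table An `msat_reftable` with at least two scenarios.
#' @return The table with LDA score columns appended and the fitted
#'   projection in `attr(, "lda_fit")`.
#' @export
append_lda_axes <- function(table) {
  if (nlevels(droplevels(table$scenario)) < 2)
    abort_msat("LDA needs at least two scenarios")
  X <- reftable_stats(table)
  keep <- apply(X, 2, function(z) stats::var(z) > 1e-12) & !apply(X, 2, anyNA)
  if (!all(keep))
    warning(sprintf("dropping %d near-constant or incomplete statistics from the LDA",
                    sum(!keep)))
  fit <- MASS::lda(X[, keep, drop = FALSE], grouping = droplevels(table$scenario))
  sc <- predict(fit, X[, keep, drop = FALSE])$x
  colnames(sc) <- paste0("LD", seq_len(ncol(sc)))
  out <- dplyr::bind_cols(table, tibble::as_tibble(sc))
  for (a in c("stat_cols", "param_cols", "perm", "provenance"))
    attr(out, a) <- attr(table, a)
  attr(out, "lda_fit") <- fit
  attr(out, "lda_cols") <- colnames(sc)
  attr(out, "lda_keep") <- colnames(X)[keep]
  class(out) <- unique(c("msat_reftable", class(out)))
  out
}

#' Project observed summary statistics on a reference table's LDA axes
#'
#' @param table A reference table processed by [append_lda_axes()].
#' @param observed A one-row tibble of summary statistics
#'   (from [summarize_dataset()]).
#' @return A one-row tibble of `LD` scores.
#' @export
project_lda <- function(table, observed) {
  fit <- attr(table, "lda_fit")
  if (is.null(fit)) abort_msat("table has no LDA fit; run append_lda_axes() first")
  keep <- attr(table, "lda_keep")
  x <- as.matrix(observed[, keep, drop = FALSE])
  sc <- predict(fit, x)$x
  colnames(sc) <- paste0("LD", seq_len(ncol(sc)))
  tibble::as_tibble(sc)
}

#' Write / read a reference table with a provenance header
#'
#' Plain tab-separated text with `#`-prefixed header lines carrying the
#' provenance metadata, so the body stays readable by any delimited-text
#' reader.
#'
#' @param table An `msat_reftable`.
#' @param path File path.
#' @return `path` (write) or the rebuilt `msat_reftable` (read).
#' @export
write_reftable <- function(table, path) {
  prov <- attr(table, "provenance")
  hdr <- c(
    "# msatabc reference table",
    paste0("# seed: ", prov$seed),
    paste0("# n_per_scenario: ", prov$n_per_scenario),
    paste0("# priors_hash: ", prov$priors_hash),
    paste0("# scenarios: ", paste(prov$scenarios, collapse = ",")),
    paste0("# stat_cols: ", paste(attr(table, "stat_cols"), collapse = ",")),
    paste0("# param_cols: ", paste(attr(table, "param_cols"), collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_reftable
#' @export
read_reftable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, ": "), "",
                           grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                            sep = "\t", check.names = FALSE)
  out <- tibble::as_tibble(body)
  out$scenario <- factor(out$scenario)
  attr(out, "stat_cols") <- strsplit(get("stat_cols"), ",")[[1]]
  attr(out, "param_cols") <- strsplit(get("param_cols"), ",")[[1]]
  attr(out, "provenance") <- list(
    seed = as.integer(get("seed")),
    n_per_scenario = as.integer(get("n_per_scenario")),
    priors_hash = get("priors_hash"),
    scenarios = as.integer(strsplit(get("scenarios"), ",")[[1]])
  )
  class(out) <- c("msat_reftable", class(out))
  out
}
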
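#' Parameter estimation with quantile regression forests
#'
#' For each requested parameter of the (single) scenario in `table`, fits a
#' quantile regression forest on the summary statistics plus the first
#' `pls_axes` partial-least-squares components of the statistics against
#' that parameter. `n_oob` rows are held out as a test set: they provide the
#' global normalized mean absolute error (NMAE, `mean(|est - true| / true)`),
#' the coverage of the 90% interval (fraction of test rows whose true value
#' falls inside their own `[q05, q95]`), and a *local* NMAE in which test
#' rows are weighted by how often they share a terminal node with the
#' observed dataset.
#'
#' Point estimates for the observed dataset are the forest mean and the
#' weighted median; the 90% credible interval is the pair of weighted
#' quantiles `(q05, q95)`.
#'
#' @param table An `msat_reftable` restricted to a single scenario.
#' @param observed Tibble of summary statistics ([summarize_dataset()]),
#'   one row per observed dataset (typically one; several rows share the
#'   fitted forests, as in recovery studies); `NULL` for accuracy metrics
#'   only.
#' @param parameters Character vector of parameter column names to estimate.
#' @param n_trees Trees per forest.
#' @param n_oob Held-out test rows for the accuracy metrics.
#' @param pls_axes PLS components appended to the features (the usual
#'   ABC-RF setting is 5); 0 disables the PLS step.
#' @param seed Integer seed.
#' @return A tibble of class `msat_estimates`: one row per parameter (and
#'   observed dataset) with `mean`, `median`, `q05`, `q95`, `nmae_global`,
#'   `nmae_local`, `coverage_90`, `n_train`, `n_test`.
#' @export
estimate_parameters <- function(table, observed = NULL, parameters,
                                n_trees = 1000, n_oob = 1000, pls_axes = 5,
                                seed = 1L) {
  if (nlevels(droplevels(table$scenario)) != 1)
    abort_msat("restrict the reference table to the chosen scenario first")
  sc <- attr(table, "stat_cols")
  bad <- setdiff(parameters, names(table))
  if (length(bad) > 0)
    abort_msat(paste0("parameter(s) not in the reference table: ",
                      paste(bad, collapse = ", ")))
  X_all <- as.data.frame(table[, sc, drop = FALSE])
  rows <- purrr::map(parameters, function(par) {
    y_all <- table[[par]]
    use <- !is.na(y_all)
    if (!any(use))
      abort_msat(paste0("parameter '", par, "' has no draws in this table"))
    X <- X_all[use, , drop = FALSE]
    y <- y_all[use]
    n <- length(y)
    n_test <- min(n_oob, floor(n / 5))
    set.seed(derive_seed(seed, match(par, parameters)))
    test_idx <- sample.int(n, n_test)
    tr <- setdiff(seq_len(n), test_idx)

    add_pls <- pls_axes > 0
    if (add_pls) {
      keep <- vapply(X[tr, , drop = FALSE], function(z) stats::var(z) > 1e-12, TRUE)
      ncomp <- min(pls_axes, sum(keep) - 1)
      pfit <- mixOmics::pls(X[tr, keep, drop = FALSE], y[tr],
                            ncomp = ncomp, scale = TRUE, mode = "regression")
      pls_tr <- pfit$variates$X
      colnames(pls_tr) <- paste0("PLS", seq_len(ncomp))
      proj <- function(newX) {
        v <- predict(pfit, newX[, keep, drop = FALSE])$variates
        colnames(v) <- paste0("PLS", seq_len(ncomp))
        v
      }
      Xtr <- cbind(X[tr, , drop = FALSE], pls_tr)
      Xte <- cbind(X[test_idx, , drop = FALSE], proj(X[test_idx, , drop = FALSE]))
    } else {
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[test_idx, , drop = FALSE]
    }
    rf <- ranger::ranger(
      x = Xtr, y = y[tr], num.trees = n_trees,
      mtry = floor(sqrt(ncol(Xtr))), quantreg = TRUE,
      seed = derive_seed(seed, 1000 + match(par, parameters)),
      num.threads = 1
    )
    qs <- c(0.05, 0.5, 0.95)
    te_q <- predict(rf, Xte, type = "quantiles", quantiles = qs,
                    num.threads = 1)$predictions
    te_mean <- predict(rf, Xte, num.threads = 1)$predictions
    truth <- y[test_idx]
    abs_rel <- abs(te_q[, 2] - truth) / abs(truth)
    nmae_global <- mean(abs_rel)
    coverage <- mean(truth >= te_q[, 1] & truth <= te_q[, 3])

    if (is.null(observed)) {
      return(tibble::tibble(
        parameter = par, observation = NA_integer_,
        mean = NA_real_, median = NA_real_, q05 = NA_real_, q95 = NA_real_,
        nmae_global = nmae_global, nmae_local = NA_real_,
        coverage_90 = coverage, n_train = length(tr), n_test = n_test
      ))
    }
    # one or several observed datasets, predicted with the same forest
    obs <- as.data.frame(observed[, sc, drop = FALSE])
    obs_f <- if (add_pls) cbind(obs, proj(obs)) else obs
    oq <- predict(rf, obs_f, type = "quantiles", quantiles = qs,
                  num.threads = 1)$predictions
    omean <- predict(rf, obs_f, num.threads = 1)$predictions
    # local error: weight test rows by terminal-node co-membership
    tn_te <- predict(rf, Xte, type = "terminalNodes", num.threads = 1)$predictions
    tn_ob <- predict(rf, obs_f, type = "terminalNodes", num.threads = 1)$predictions
    nmae_local <- vapply(seq_len(nrow(obs)), function(k) {
      w <- rowMeans(tn_te == matrix(tn_ob[k, ], nrow(tn_te), ncol(tn_te),
                                    byrow = TRUE))
      if (sum(w) > 0) sum(w * abs_rel) / sum(w) else NA_real_
    }, 0)
    tibble::tibble(
      parameter = par, observation = seq_len(nrow(obs)),
      mean = as.numeric(omean),
      median = oq[, 2], q05 = oq[, 1], q95 = oq[, 3],
      nmae_global = nmae_global, nmae_local = nmae_local,
      coverage_90 = coverage, n_train = length(tr), n_test = n_test
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("msat_estimates", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.msat_estimates <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "msat_estimates")
  out
}

#' @exportS3Method generics::glance
glance.msat_estimates <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x),
    mean_coverage_90 = mean(x$coverage_90),
    mean_nmae_global = mean(x$nmae_global),
    n_test = x$n_test[1]
  )
}
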
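#' Random-forest scenario choice
#'
#' Trains a classification forest on the reference table's features
#' (summary statistics plus LDA axes when present) and the scenario label.
#' The out-of-bag misclassification rate is the *prior error rate*; its
#' per-scenario breakdown gives the class error rates. For an observed
#' dataset, each tree casts one vote; the selected scenario is the vote
#' winner (ties broken towards the lowest scenario id and flagged), and the
#' posterior probability is estimated as `1 - E[error | observed]` from a
#' second regression forest fitted to the out-of-bag misclassification
#' indicators, following the ABC-RF construction.
#'
#' @param table An `msat_reftable`, ideally with LDA axes appended.
#' @param observed A one-row tibble of summary statistics from
#'   [summarize_dataset()], or `NULL` for a training-only fit (prior and
#'   class errors, no votes).
#' @param n_trees Number of trees (the conventional choice is 2000).
#' @param seed Integer seed for both forests.
#' @param compute_posterior Fit the error-regression forest? (Skipping it
#'   halves the cost when only votes and prior error are needed.)
#' @param keep_forest Keep the fitted classification forest in the result
#'   so further datasets can be classified with [predict.msat_choice()].
#' @return An object of class `msat_choice`; see [tidy.msat_choice()] and
#'   [glance.msat_choice()].
#' @export
scenario_choice <- function(table, observed = NULL, n_trees = 2000,
                            seed = 1L, compute_posterior = TRUE,
                            keep_forest = FALSE) {
  if (n_trees < 50)
    warning("fewer than 50 trees gives unstable votes and error rates")
  feat_cols <- c(attr(table, "stat_cols"), attr(table, "lda_cols"))
  X <- as.data.frame(table[, feat_cols, drop = FALSE])
  if (anyNA(X))
    abort_msat("reference table features contain NA; degenerate simulations must be handled before training")
  y <- droplevels(table$scenario)
  rf <- ranger::ranger(
    x = X, y = y, num.trees = n_trees,
    mtry = floor(sqrt(ncol(X))), seed = seed, num.threads = 1
  )
  cm <- rf$confusion.matrix
  class_err <- 1 - diag(cm) / rowSums(cm)
  res <- list(
    prior_error = rf$prediction.error,
    class_errors = tibble::tibble(scenario = rownames(cm),
                                  class_error = unname(class_err),
                                  n = unname(rowSums(cm))),
    confusion = cm,
    n_trees = n_trees,
    levels = levels(y)
  )
  if (!is.null(observed)) {
    obs <- observed_features(table, observed, feat_cols)
    pred_all <- predict(rf, obs, predict.all = TRUE, num.threads = 1)$predictions
    votes <- tabulate(as.integer(pred_all), nbins = nlevels(y))
    winners <- which(votes == max(votes))
    res$votes <- tibble::tibble(scenario = levels(y), votes = votes,
                                vote_share = votes / n_trees)
    res$selected <- levels(y)[winners[1]]
    res$tie <- length(winners) > 1
    if (res$tie)
      warning("vote tie between scenarios ",
              paste(levels(y)[winners], collapse = ", "),
              "; selecting the lowest id")
    if (!is.null(attr(table, "lda_fit")))
      res$lda_observed <- project_lda(table, observed)
    if (compute_posterior) {
      oob <- rf$predictions
      usable <- !is.na(oob)
      miss <- as.numeric(oob[usable] != y[usable])
      err_rf <- ranger::ranger(
        x = X[usable, , drop = FALSE], y = miss, num.trees = n_trees,
        mtry = floor(sqrt(ncol(X))), seed = seed + 1L, num.threads = 1
      )
      local_err <- predict(err_rf, obs, num.threads = 1)$predictions
      res$local_error <- min(max(local_err, 0), 1)
      res$posterior_prob <- 1 - res$local_error
    }
  }
  if (keep_forest) {
    res$forest <- rf
    res$table_ref <- table[0, ]  # schema + lda fit travel via attributes
    for (a in c("stat_cols", "lda_cols", "lda_fit", "lda_keep"))
      attr(res$table_ref, a) <- attr(table, a)
    res$feat_cols <- feat_cols
  }
  structure(res, class = "msat_choice")
}

#' Classify further datasets with a fitted scenario-choice forest
#'
#' @param object An `msat_choice` fitted with `keep_forest = TRUE`.
#' @param observed Tibble of summary statistics, one row per dataset.
#' @param ... Unused.
#' @return Factor of predicted scenario labels.
#' @export
predict.msat_choice <- function(object, observed, ...) {
  if (is.null(object$forest))
    abort_msat("refit scenario_choice() with keep_forest = TRUE to predict")
  obs <- observed_features(object$table_ref, observed, object$feat_cols)
  p <- predict(object$forest, obs, num.threads = 1)$predictions
  factor(as.character(p), levels = object$levels)
}

observed_features <- function(table, observed, feat_cols) {
  sc <- attr(table, "stat_cols")
  miss <- setdiff(sc, names(observed))
  if (length(miss) > 0)
    abort_msat(paste0("observed vector lacks feature(s): ",
                      paste(head(miss, 3), collapse = ", "),
                      if (length(miss) > 3) ", ..."))
  obs <- observed[, sc, drop = FALSE]
  if (!is.null(attr(table, "lda_fit")))
    obs <- dplyr::bind_cols(obs, project_lda(table, observed))
  as.data.frame(obs[, feat_cols, drop = FALSE])
}

#' @export
print.msat_choice <- function(x, ...) {
  cat(sprintf("<msat_choice> %d trees, prior error %.4f\n",
              x$n_trees, x$prior_error))
  if (!is.null(x$votes)) {
    cat(sprintf("  selected scenario %s%s", x$selected,
                if (isTRUE(x$tie)) " (tie)" else ""))
    if (!is.null(x$posterior_prob))
      cat(sprintf(", posterior probability %.3f", x$posterior_prob))
    cat("\n")
  }
  invisible(x)
}

#' @describeIn scenario_choice Votes (or class errors, for training-only
#'   fits) as a tibble.
#' @param x An `msat_choice`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.msat_choice <- function(x, ...) {
  if (!is.null(x$votes))
    dplyr::left_join(x$votes, x$class_errors, by = "scenario")
  else x$class_errors
}

#' @describeIn scenario_choice One-row summary (selected scenario,
#'   posterior probability, prior and local error).
#' @exportS3Method generics::glance
glance.msat_choice <- function(x, ...) {
  tibble::tibble(
    selected = x$selected %||% NA_character_,
    posterior_prob = x$posterior_prob %||% NA_real_,
    prior_error = x$prior_error,
    local_error = x$local_error %||% NA_real_,
    n_trees = x$n_trees
  )
}

#' Replicate the forest stage of a scenario-choice analysis
#'
#' Re-runs [scenario_choice()] `n_replicates` times on the *same* reference
#' table with fresh forest seeds (the replication protocol that quantifies
#' forest noise rather than simulation noise) and summarizes votes,
#' posterior probability and error rates as mean and SD.
#'
#' @inheritParams scenario_choice
#' @param n_replicates Number of forest replicates (at least 2).
#' @return A list of class `msat_replicates` with `votes` (per-scenario
#'   mean and SD of votes) and `summary` (mean/SD of posterior probability,
#'   prior and local error, plus the modal selected scenario).
#' @export
replicate_analysis <- function(table, observed, n_replicates = 10,
                               n_trees = 2000, seed = 1L,
                               compute_posterior = TRUE) {
  if (n_replicates < 2) abort_msat("need at least 2 replicates")
  runs <- purrr::map(seq_len(n_replicates), function(r) {
    scenario_choice(table, observed, n_trees = n_trees,
                    seed = derive_seed(seed, r),
                    compute_posterior = compute_posterior)
  })
  vt <- purrr::map_dfr(runs, function(z) z$votes, .id = "replicate")
  votes <- vt |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(mean_votes = mean(.data$votes),
                     sd_votes = stats::sd(.data$votes), .groups = "drop")
  gl <- purrr::map_dfr(runs, glance)
  summary <- tibble::tibble(
    selected_modal = names(which.max(base::table(gl$selected))),
    mean_posterior_prob = mean(gl$posterior_prob),
    sd_posterior_prob = stats::sd(gl$posterior_prob),
    mean_prior_error = mean(gl$prior_error),
    sd_prior_error = stats::sd(gl$prior_error),
    mean_local_error = mean(gl$local_error),
    sd_local_error = stats::sd(gl$local_error),
    n_replicates = n_replicates
  )
  structure(list(votes = votes, summary = summary, runs = runs),
            class = "msat_replicates")
}

#' @export
print.msat_replicates <- function(x, ...) {
  cat(sprintf("<msat_replicates> %d forest replicates; modal selection: scenario %s\n",
              x$summary$n_replicates, x$summary$selected_modal))
  print(x$votes)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.msat_replicates <- function(x, ...) x$votes

#' @exportS3Method generics::glance
glance.msat_replicates <- function(x, ...) x$summary
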
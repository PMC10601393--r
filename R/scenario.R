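#' Load a demographic scenario set from structured configuration text
#'
#' The configuration is a flat sectioned text format:
#'
#' ```
#' [settings]            # optional n_loci, generation_time, locus_shape
#' [lineages]            # one line per sampled lineage: ID Ne=<param> n=<diploids>
#' [scenario <k>]        # event lines + optional constraint lines
#' [priors]              # <param> = uniform(lo, hi)
#' ```
#'
#' Event lines are either
#' `split time=<t> derived=<ids> ancestor=<id>` (backward in time, every
#' derived lineage merges into the ancestor; several derived ids give a
#' multifurcating split at one time) or
#' `admix time=<t> target=<id> source1=<id> source2=<id> ra=<param>`
#' (each gene lineage of the target joins source1 with probability `ra`,
#' otherwise source2). `constraint a < b < c` lines declare the ordering the
#' scenario's time parameters must satisfy; draws are rejected until they do.
#' An `ne <ID>=<param> ...` line inside a scenario section rebinds lineage
#' effective sizes to different prior parameters for that scenario only.
#'
#' Validation checks that every referenced lineage is declared, that each
#' lineage is removed at most once, that a lineage receiving migrants at some
#' event is provably (via the constraints) still extant at that time, and
#' that exactly one root lineage remains.
#'
#' @param x Path to a configuration file, or its contents as a string.
#' @return An object of class `msat_scenario_set`: a list with elements
#'   `scenarios` (list of `msat_scenario`), `priors` (`msat_priors`) and
#'   `settings`.
#' @seealso [scenarios_caucasus()] for the shipped five-lineage fixture.
#' @export
load_scenario_set <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines <- sub("#.*$", "", lines)
  lines <- sub("\\s+$", "", lines)

  settings <- list(n_loci = 9L, generation_time = 100, locus_shape = 2)
  lineages <- NULL
  scen_raw <- list()
  priors <- list()
  section <- ""
  cur_id <- NA_integer_

  perr <- function(i, msg)
    abort_msat(sprintf("config line %d: %s", i, msg), class = "msatabc_format_error")

  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      hdr <- trimws(gsub("\\[|\\]", "", ln))
      if (grepl("^scenario\\s+\\d+$", hdr)) {
        section <- "scenario"
        cur_id <- as.integer(sub("^scenario\\s+", "", hdr))
        scen_raw[[as.character(cur_id)]] <-
          list(id = cur_id, events = list(), constraints = list())
      } else if (hdr %in% c("settings", "lineages", "priors")) {
        section <- hdr
      } else perr(i, paste0("unknown section header '", hdr, "'"))
      next
    }
    if (section == "settings") {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) perr(i, "expected 'key = value'")
      settings[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
    } else if (section == "lineages") {
      m <- regmatches(ln, regexec(
        "^(\\S+)\\s+Ne=(\\S+)\\s+n=(\\d+)$", ln))[[1]]
      if (length(m) != 4) perr(i, "expected '<ID> Ne=<param> n=<diploids>'")
      lineages <- dplyr::bind_rows(lineages, tibble::tibble(
        lineage = m[2], ne_param = m[3], n = as.integer(m[4])))
    } else if (section == "scenario") {
      if (grepl("^constraint\\s", ln)) {
        chain <- trimws(strsplit(sub("^constraint\\s+", "", ln), "<", fixed = TRUE)[[1]])
        if (length(chain) < 2) perr(i, "constraint needs at least 'a < b'")
        scen_raw[[as.character(cur_id)]]$constraints <-
          c(scen_raw[[as.character(cur_id)]]$constraints, list(chain))
      } else if (grepl("^split\\s", ln)) {
        fld <- parse_fields(ln, i, c("time", "derived", "ancestor"), perr)
        ev <- list(kind = "split", time_param = fld$time, line = i,
                   derived = trimws(strsplit(fld$derived, ",")[[1]]),
                   ancestor = fld$ancestor)
        scen_raw[[as.character(cur_id)]]$events <-
          c(scen_raw[[as.character(cur_id)]]$events, list(ev))
      } else if (grepl("^ne\\s", ln)) {
        # per-scenario override of lineage Ne parameters: ne A=NeA1 B=NeB1
        toks <- regmatches(ln, gregexpr("(\\S+)=(\\S+)", ln))[[1]]
        kv <- strsplit(toks, "=", fixed = TRUE)
        ov <- stats::setNames(vapply(kv, function(z) z[2], ""),
                              vapply(kv, function(z) z[1], ""))
        scen_raw[[as.character(cur_id)]]$ne_override <-
          c(scen_raw[[as.character(cur_id)]]$ne_override, ov)
      } else if (grepl("^admix\\s", ln)) {
        fld <- parse_fields(ln, i, c("time", "target", "source1", "source2", "ra"), perr)
        ev <- list(kind = "admix", time_param = fld$time, line = i,
                   target = fld$target, source1 = fld$source1,
                   source2 = fld$source2, ra_param = fld$ra)
        scen_raw[[as.character(cur_id)]]$events <-
          c(scen_raw[[as.character(cur_id)]]$events, list(ev))
      } else perr(i, "expected a split/admix/constraint line")
    } else if (section == "priors") {
      m <- regmatches(ln, regexec(
        "^(\\S+)\\s*=\\s*uniform\\(\\s*([-0-9.eE+]+)\\s*,\\s*([-0-9.eE+]+)\\s*\\)$", ln))[[1]]
      if (length(m) != 4) perr(i, "expected '<param> = uniform(lo, hi)'")
      lo <- as.numeric(m[3]); hi <- as.numeric(m[4])
      if (lo > hi) perr(i, "uniform prior needs lo <= hi")
      priors[[m[2]]] <- list(dist = "uniform", lo = lo, hi = hi)
    } else if (section == "") {
      perr(i, "content before the first section header")
    }
  }

  if (is.null(lineages)) abort_msat("config declares no [lineages]")
  if (length(scen_raw) == 0) abort_msat("config declares no scenarios")
  if (length(priors) == 0) abort_msat("config declares no [priors]")

  prior_set <- structure(list(params = priors,
                              locus_shape = settings$locus_shape),
                         class = "msat_priors")
  scens <- lapply(scen_raw, function(s)
    build_scenario(s, lineages, prior_set))
  scens <- scens[order(vapply(scens, function(s) s$id, 0L))]
  names(scens) <- vapply(scens, function(s) as.character(s$id), "")
  structure(list(scenarios = scens, priors = prior_set, settings = settings),
            class = "msat_scenario_set")
}

parse_fields <- function(ln, i, need, perr) {
  toks <- regmatches(ln, gregexpr("(\\S+)=(\\S+)", ln))[[1]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  out <- stats::setNames(lapply(kv, function(z) z[2]),
                         vapply(kv, function(z) z[1], ""))
  miss <- setdiff(need, names(out))
  if (length(miss) > 0)
    perr(i, paste0("event is missing field(s): ", paste(miss, collapse = ", ")))
  out
}

# transitive closure of the 'a < b' relation declared by constraint chains
precedence_pairs <- function(constraints) {
  edges <- list()
  for (ch in constraints)
    for (k in seq_len(length(ch) - 1))
      edges <- c(edges, list(c(ch[k], ch[k + 1])))
  if (length(edges) == 0) return(matrix(character(0), ncol = 2))
  e <- unique(do.call(rbind, edges))
  repeat {
    added <- FALSE
    for (a in seq_len(nrow(e))) for (b in seq_len(nrow(e))) {
      if (e[a, 2] == e[b, 1]) {
        cand <- c(e[a, 1], e[b, 2])
        if (!any(e[, 1] == cand[1] & e[, 2] == cand[2])) {
          e <- rbind(e, cand); added <- TRUE
        }
      }
    }
    if (!added) break
  }
  e
}

build_scenario <- function(raw, lineages, priors) {
  id <- raw$id
  evs <- raw$events
  if (!is.null(raw$ne_override)) {
    bad <- setdiff(names(raw$ne_override), lineages$lineage)
    if (length(bad) > 0)
      abort_msat(sprintf("scenario %d: ne override for undeclared lineage '%s'",
                         id, bad[1]), class = "msatabc_validation_error")
    idx <- match(names(raw$ne_override), lineages$lineage)
    lineages$ne_param[idx] <- unname(raw$ne_override)
    badp <- setdiff(lineages$ne_param, names(priors$params))
    if (length(badp) > 0)
      abort_msat(sprintf("scenario %d: ne parameter '%s' has no prior",
                         id, badp[1]), class = "msatabc_validation_error")
  }
  if (length(evs) == 0)
    abort_msat(sprintf("scenario %d: no events; lineages cannot coalesce", id))
  all_params <- names(priors$params)
  lin_ids <- lineages$lineage

  verr <- function(ev, msg)
    abort_msat(sprintf("scenario %d, event at line %d: %s", id, ev$line, msg),
               class = "msatabc_validation_error")

  removed_by <- list()   # lineage -> time param of its removal
  for (ev in evs) {
    refs <- if (ev$kind == "split") c(ev$derived, ev$ancestor)
            else c(ev$target, ev$source1, ev$source2)
    bad <- setdiff(refs, lin_ids)
    if (length(bad) > 0)
      verr(ev, paste0("reference to undeclared lineage '", bad[1], "'"))
    pars <- c(ev$time_param, if (ev$kind == "admix") ev$ra_param)
    badp <- setdiff(pars, all_params)
    if (length(badp) > 0)
      verr(ev, paste0("parameter '", badp[1], "' has no prior"))
    gone <- if (ev$kind == "split") ev$derived else ev$target
    for (g in gone) {
      if (!is.null(removed_by[[g]]))
        verr(ev, paste0("lineage '", g, "' is removed twice"))
      removed_by[[g]] <- ev$time_param
    }
    if (ev$kind == "split" && ev$ancestor %in% ev$derived)
      verr(ev, "ancestor cannot be among the derived lineages")
    if (ev$kind == "admix" &&
        (ev$target %in% c(ev$source1, ev$source2) || ev$source1 == ev$source2))
      verr(ev, "admixture needs three distinct lineages")
  }
  roots <- setdiff(lin_ids, names(removed_by))
  if (length(roots) != 1)
    abort_msat(sprintf(
      "scenario %d: %d root lineage(s) remain after all events (need exactly 1)",
      id, length(roots)), class = "msatabc_validation_error")

  prec <- precedence_pairs(raw$constraints)
  provably_before <- function(a, b) {
    if (nrow(prec) == 0) return(FALSE)
    any(prec[, 1] == a & prec[, 2] == b)
  }
  for (ev in evs) {
    dests <- if (ev$kind == "split") ev$ancestor else c(ev$source1, ev$source2)
    for (d in dests) {
      rb <- removed_by[[d]]
      if (is.null(rb)) next
      if (identical(rb, ev$time_param) || !provably_before(ev$time_param, rb))
        verr(ev, paste0(
          "lineage '", d, "' receives lineages here but its own removal at '",
          rb, "' is not constrained to be later (lineage not extant)"))
    }
  }

  structure(list(id = id, lineages = lineages, events = evs,
                 constraints = raw$constraints, root = roots),
            class = "msat_scenario")
}

#' @export
print.msat_scenario <- function(x, ...) {
  cat(sprintf("<msat_scenario %d> %d lineages (%s), root %s\n", x$id,
              nrow(x$lineages), paste(x$lineages$lineage, collapse = ", "),
              x$root))
  for (ev in x$events) {
    if (ev$kind == "split")
      cat(sprintf("  split  t=%s  %s -> %s\n", ev$time_param,
                  paste(ev$derived, collapse = "+"), ev$ancestor))
    else
      cat(sprintf("  admix  t=%s  %s <- %s (ra=%s) + %s\n", ev$time_param,
                  ev$target, ev$source1, ev$ra_param, ev$source2))
  }
  for (ch in x$constraints)
    cat("  constraint ", paste(ch, collapse = " < "), "\n")
  invisible(x)
}

#' @export
print.msat_scenario_set <- function(x, ...) {
  cat(sprintf("<msat_scenario_set> %d scenarios, %d lineages, %d priors\n",
              length(x$scenarios), nrow(x$scenarios[[1]]$lineages),
              length(x$priors$params)))
  invisible(x)
}

#' The shipped Caucasian sweet-chestnut scenario set
#'
#' Loads the package's default fixture: five sampled lineages (62, 72, 65,
#' 40 and 27 diploid individuals at 9 SSR loci) and eight divergence /
#' admixture scenarios with uniform priors on effective sizes and event
#' times. Scenarios 1 and 2 contain an admixture event producing Lineage III
#' from Lineages II and IV; Scenarios 3-8 are pure divergence hierarchies,
#' Scenario 8 rooting all Caucasian lineages in Lineage IV.
#'
#' @return An `msat_scenario_set`.
#' @export
scenarios_caucasus <- function() {
  load_scenario_set(system.file("extdata", "scenarios_caucasus.cfg",
                                package = "msatabc", mustWork = TRUE))
}

#' Draw one parameter vector from the priors for a scenario
#'
#' Scalar parameters are drawn from their uniform priors; draws violating
#' the scenario's ordering constraints are rejected and redrawn, so accepted
#' draws satisfy every constraint by construction while unconstrained
#' marginals are untouched. Per-locus mutation parameters are then drawn
#' from gamma distributions with the drawn means (`mu_mean`, `P_mean`) and
#' shape `priors$locus_shape`; the geometric-step parameter is truncated at
#' 0.95 so the step distribution keeps a finite mean.
#'
#' @param priors An `msat_priors` object.
#' @param scenario An `msat_scenario`.
#' @param n_loci Number of loci to draw per-locus rates for.
#' @param max_tries Rejection cap before aborting with a diagnostic.
#' @return An object of class `msat_draw`: list with `scenario`, `params`
#'   (named numeric), `mu` and `P` (per-locus vectors).
#' @export
sample_draw <- function(priors, scenario, n_loci = 9, max_tries = 1e6) {
  pnames <- names(priors$params)
  draw1 <- function() {
    vapply(priors$params, function(sp) runif(1, sp$lo, sp$hi), 0)
  }
  ok <- function(v) {
    for (ch in scenario$constraints) {
      vals <- v[ch]
      if (any(diff(vals) <= 0)) return(FALSE)
    }
    TRUE
  }
  tries <- 0
  repeat {
    tries <- tries + 1
    if (tries > max_tries)
      abort_msat(sprintf(
        "scenario %d: no draw satisfied the ordering constraints after %d tries; check the priors for disjoint or incompatible ranges",
        scenario$id, max_tries))
    v <- stats::setNames(draw1(), pnames)
    if (ok(v)) break
  }
  shape <- priors$locus_shape
  mu <- if ("mu_mean" %in% pnames)
    rgamma(n_loci, shape = shape, rate = shape / v[["mu_mean"]]) else rep(5e-4, n_loci)
  P <- if ("P_mean" %in% pnames)
    pmin(rgamma(n_loci, shape = shape, rate = shape / v[["P_mean"]]), 0.95) else rep(0, n_loci)
  structure(list(scenario = scenario$id, params = v, mu = mu, P = P),
            class = "msat_draw")
}

# Resolve a scenario + draw into the concrete, time-ordered event list the
# C++ coalescent consumes (1-based population indices in lineage order).
events_for_draw <- function(scenario, draw) {
  lin <- scenario$lineages$lineage
  idx <- function(l) match(l, lin)
  evs <- lapply(scenario$events, function(ev) {
    tt <- draw$params[[ev$time_param]]
    if (is.null(tt) || is.na(tt))
      abort_msat(paste0("draw lacks parameter '", ev$time_param, "'"))
    if (ev$kind == "split") {
      list(kind = 0L, time = tt, from = vapply(ev$derived, idx, 0L),
           dest = idx(ev$ancestor), dest2 = NA_integer_, ra = 1.0)
    } else {
      ra <- draw$params[[ev$ra_param]]
      list(kind = 1L, time = tt, from = idx(ev$target),
           dest = idx(ev$source1), dest2 = idx(ev$source2),
           ra = min(max(ra, 0), 1))
    }
  })
  evs <- evs[order(vapply(evs, function(e) e$time, 0))]
  # concrete extancy check for this draw's time ordering
  alive <- rep(TRUE, length(lin))
  for (e in evs) {
    if (any(!alive[e$from]))
      abort_msat(sprintf(
        "scenario %d: event at t=%g references an already-merged lineage",
        scenario$id, e$time))
    dst <- c(e$dest, if (!is.na(e$dest2)) e$dest2)
    if (any(!alive[dst]))
      abort_msat(sprintf(
        "scenario %d: event at t=%g sends lineages to a non-extant lineage",
        scenario$id, e$time))
    alive[e$from] <- FALSE
  }
  if (sum(alive) != 1)
    abort_msat(sprintf("scenario %d: %d lineages remain after all events",
                       scenario$id, sum(alive)))
  evs
}

ne_for_draw <- function(scenario, draw) {
  ne <- vapply(scenario$lineages$ne_param, function(p) {
    v <- draw$params[[p]]
    if (is.null(v)) abort_msat(paste0("draw lacks parameter '", p, "'"))
    v
  }, 0)
  if (any(ne <= 0)) abort_msat("effective sizes must be positive")
  unname(ne)
}

#' Convert generations to calendar years
#'
#' Event times from the coalescent machinery are in generations before
#' present; dating them against external records needs the species'
#' generation time. For long-lived trees such as sweet chestnut a
#' generation time of 100 years is the conventional choice.
#'
#' @param t Time(s) in generations, non-negative.
#' @param generation_time Years per generation, positive.
#' @return `t * generation_time`, in years.
#' @examples
#' generations_to_years(4973, 100)  # 497300
#' @export
generations_to_years <- function(t, generation_time = 100) {
  if (any(t < 0)) abort_msat("time in generations must be non-negative")
  if (any(generation_time <= 0)) abort_msat("generation time must be positive")
  t * generation_time
}
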
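# Multinomial survey simulator and parameter-recovery harness.
#
# Selection acts multiplicatively on availability: the probability that a
# capture falls in habitat i is pi_i = w_i p_i / sum_j w_j p_j, where w is
# the per-unit-area attractiveness. Under this model Manly's alpha is the
# natural estimator of the normalised weights, so recovery of alpha is a
# meaningful end-to-end check of the pipeline.

#' Simulation configuration
#'
#' @param habitats a [habitat_set()].
#' @param weights selection weights per unit area (all > 0). Either a
#'   single numeric vector of length k (used for every group-season) or a
#'   named list with entries `"<stage>.<season>"` (e.g. `"larva.wet"`);
#'   missing entries fall back to an optional `"default"` entry or to
#'   uniform weights.
#' @param totals stage-by-season matrix of total captures N (rows
#'   larva/nymph/female/male, columns dry/wet); zero rows are allowed and
#'   yield all-zero slices.
#' @param trap_fraction probability q that a capture is taken by a CO2 trap
#'   rather than a drag transect; the split is selection-neutral.
#' @param seed optional integer seed giving bit-reproducible surveys.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(habitats, weights, totals, trap_fraction = 0.7,
                       seed = NULL) {
  stopifnot(inherits(habitats, "habitat_set"))
  if (is.numeric(weights)) weights <- list(default = weights)
  for (w in weights) {
    if (length(w) != habitats$k) stop("each weight vector must have length k")
    if (any(w <= 0)) stop("selection weights must be > 0")
  }
  totals <- as.matrix(totals)
  if (!all(rownames(totals) %in% tick_stages) ||
      !all(colnames(totals) %in% tick_seasons))
    stop("`totals` must be a stage x season matrix")
  if (any(totals < 0) || any(totals != floor(totals)))
    stop("season totals must be non-negative integers")
  if (trap_fraction < 0 || trap_fraction > 1)
    stop("trap_fraction must be in [0, 1]")
  structure(list(habitats = habitats, weights = weights, totals = totals,
                 trap_fraction = trap_fraction, seed = seed),
            class = "sim_config")
}

weights_for <- function(config, stage, season) {
  key <- paste(stage, season, sep = ".")
  w <- config$weights[[key]]
  if (is.null(w)) w <- config$weights[["default"]]
  if (is.null(w)) w <- rep(1, config$habitats$k)
  w
}

#' Selection-adjusted capture probabilities
#'
#' `pi_i = w_i p_i / sum_j w_j p_j`. With uniform weights this is the
#' availability vector itself (no selection).
#'
#' @param w positive selection weights.
#' @param p availability proportions.
#' @return A probability vector over habitats.
#' @export
selection_probs <- function(w, p) {
  wp <- as.numeric(w) * as.numeric(p)
  out <- wp / sum(wp)
  names(out) <- names(p)
  out
}

#' Simulate one seasonal capture survey
#'
#' For each stage and season, allocates the configured total N across
#' habitats as `Multinomial(N, pi)` with `pi` from [selection_probs()],
#' then splits each habitat count `Binomial(O_i, q)` into trap vs transect
#' captures. Identical seed and configuration give identical output.
#'
#' @param config a [sim_config()].
#' @return A [count_matrix()] in the standard layout.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  hs <- config$habitats
  p <- availability(hs)
  rows <- list()
  for (stage in rownames(config$totals)) {
    for (season in colnames(config$totals)) {
      N <- config$totals[stage, season]
      if (N == 0) next
      pi <- selection_probs(weights_for(config, stage, season), p)
      O <- as.integer(stats::rmultinom(1, N, pi))
      trap <- stats::rbinom(hs$k, O, config$trap_fraction)
      rows[[length(rows) + 1L]] <- data.frame(
        group = stage, habitat = rep(hs$names, 2),
        season = season,
        method = rep(tick_methods, each = hs$k),
        count = c(trap, O - trap), stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(group = character(), habitat = character(),
                        season = character(), method = character(),
                        count = integer())
  count_matrix(df, hs)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates surveys and re-estimates Manly's alpha for one
#' group-season, comparing against the generating truth
#' `alpha* = (w_i p_i / p_i) / sum = w_i / sum_j w_j`. Also reports how
#' often the consensus habitat call on simulated data matches the call the
#' expected (noise-free) profile would receive.
#'
#' @param config a [sim_config()].
#' @param reps number of replicates (>= 2; >= 100 for a serious run).
#' @param group,season the profile to estimate on.
#' @return A list with `alpha_truth`, `alpha_mean`, `alpha_sd` (named
#'   vectors over habitats), `consensus_truth` (labels) and
#'   `consensus_match` (fraction of replicates whose full consensus label
#'   vector equals the truth-at-expectation call).
#' @export
recovery_experiment <- function(config, reps, group = "all",
                                season = "dry") {
  stopifnot(inherits(config, "sim_config"), reps >= 2)
  hs <- config$habitats
  p <- availability(hs)
  stages <- resolve_group(group)
  # expectation-level truth: pool expected counts over the selected stages
  E_pool <- rep(0, hs$k)
  for (stage in stages) {
    N <- config$totals[stage, season]
    if (N > 0)
      E_pool <- E_pool + N * selection_probs(weights_for(config, stage,
                                                         season), p)
  }
  if (sum(E_pool) == 0) stop("no captures configured for this group-season")
  r_star <- E_pool / sum(E_pool)
  alpha_star <- manly_alpha(r_star, p)
  truth_profile <- structure(list(group = group, season = season,
                                  O = round(E_pool), N = sum(round(E_pool)),
                                  r = r_star),
                             class = "use_profile")
  truth_call <- consensus(preference_report(truth_profile, p))$label
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL  # one stream across replicates, seeded once above
  A <- matrix(NA_real_, reps, hs$k, dimnames = list(NULL, hs$names))
  match_call <- logical(reps)
  for (b in seq_len(reps)) {
    cm <- simulate_survey(cfg)
    prof <- use_profile(cm, group, season)
    A[b, ] <- manly_alpha(prof$r, p)
    match_call[b] <- identical(
      consensus(preference_report(prof, p))$label, truth_call)
  }
  list(alpha_truth = alpha_star,
       alpha_mean = colMeans(A),
       alpha_sd = apply(A, 2, stats::sd),
       consensus_truth = truth_call,
       consensus_match = mean(match_call))
}

#' Read / write a flat simulation-configuration file
#'
#' A plain `key: value` document with comma-separated vectors. Keys:
#' `habitats`, `areas`, `trap_fraction`, optional `seed`, and one
#' `weights.<stage>.<season>` and `totals.<stage>.<season>` entry per
#' configured group-season (a `weights.default` entry is honoured).
#'
#' @param path file path.
#' @return For `read_sim_config`, a [sim_config()]; for
#'   `write_sim_config`, `path` invisibly.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  get <- function(key) vals[match(key, keys)]
  split_c <- function(x) trimws(strsplit(x, ",")[[1]])
  if (is.na(get("habitats")) || is.na(get("areas")))
    stop("sim config needs `habitats` and `areas` entries")
  hs <- habitat_set(split_c(get("habitats")),
                    as.numeric(split_c(get("areas"))))
  totals <- matrix(0L, length(tick_stages), length(tick_seasons),
                   dimnames = list(tick_stages, tick_seasons))
  weights <- list()
  for (i in seq_along(keys)) {
    if (startsWith(keys[i], "totals.")) {
      parts <- strsplit(sub("^totals\\.", "", keys[i]), "\\.")[[1]]
      totals[parts[1], parts[2]] <- as.integer(vals[i])
    } else if (startsWith(keys[i], "weights.")) {
      weights[[sub("^weights\\.", "", keys[i])]] <-
        as.numeric(split_c(vals[i]))
    }
  }
  if (!length(weights)) weights <- rep(1, hs$k)
  q <- if (is.na(get("trap_fraction"))) 0.7
       else as.numeric(get("trap_fraction"))
  seed <- if (is.na(get("seed"))) NULL else as.integer(get("seed"))
  sim_config(hs, weights, totals, q, seed)
}

#' @rdname read_sim_config
#' @param config a [sim_config()] to serialise.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- c(
    paste0("habitats: ", paste(config$habitats$names, collapse = ", ")),
    paste0("areas: ", paste(config$habitats$areas, collapse = ", ")),
    paste0("trap_fraction: ", config$trap_fraction))
  if (!is.null(config$seed)) out <- c(out, paste0("seed: ", config$seed))
  for (key in names(config$weights))
    out <- c(out, paste0("weights.", key, ": ",
                         paste(config$weights[[key]], collapse = ", ")))
  for (stage in rownames(config$totals))
    for (season in colnames(config$totals))
      if (config$totals[stage, season] > 0)
        out <- c(out, paste0("totals.", stage, ".", season, ": ",
                             config$totals[stage, season]))
  writeLines(out, path)
  invisible(path)
}
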
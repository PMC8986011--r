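# Availability proportions, expected use, and composition summaries.

#' Area-derived availability proportions
#'
#' The proportional availability of habitat i is its available area divided
#' by the total study area, `p_i = A_i / sum(A)`. Under no selection, use is
#' expected to match availability, so `p` is the null expectation for every
#' downstream test and index. The same availability applies to both seasons
#' unless an explicit override is supplied (see [availability_vector()]).
#'
#' @param habitats a [habitat_set()].
#' @return A named numeric vector of class `availability` summing to 1, with
#'   attribute `source = "areas"`.
#' @examples
#' availability(habitat_set(c("A", "B"), c(1, 3)))
#' @export
availability <- function(habitats) {
  stopifnot(inherits(habitats, "habitat_set"))
  p <- habitats$areas / sum(habitats$areas)
  structure(p, source = "areas", class = "availability")
}

#' Explicit availability proportions
#'
#' Wraps a user-supplied availability vector (for instance a per-season
#' override) after validating that it is a strictly positive probability
#' vector over the habitat set.
#'
#' @param p numeric vector of proportions, one per habitat, summing to 1
#'   (tolerance 1e-9); all entries strictly positive.
#' @param habitats a [habitat_set()] giving names and order; optional if `p`
#'   is already named.
#' @return A named `availability` vector with attribute `source = "explicit"`.
#' @export
availability_vector <- function(p, habitats = NULL) {
  p <- as.numeric(p)
  if (!is.null(habitats)) {
    stopifnot(inherits(habitats, "habitat_set"))
    if (length(p) != habitats$k)
      stop("availability vector length ", length(p),
           " does not match k = ", habitats$k)
    names(p) <- habitats$names
  }
  if (any(p <= 0)) stop("availability proportions must be > 0")
  if (abs(sum(p) - 1) > 1e-9)
    stop("availability proportions must sum to 1 (got ", sum(p), ")")
  structure(p / sum(p), source = "explicit", class = "availability")
}

#' Expected use under availability
#'
#' The expected count in habitat i for a profile of total size N is
#' `E_i = N * p_i`: the allocation a non-selective population of the same
#' size would show. These are the expectations used by the G and chi-square
#' tests and by the Bailey classification.
#'
#' @param profile a [use_profile()] with `N > 0`.
#' @param p an `availability` vector over the same habitats.
#' @return A named numeric vector `E` of class `expected_use`, with
#'   attributes `N` and `p`.
#' @export
expected_use <- function(profile, p) {
  stopifnot(inherits(profile, "use_profile"))
  if (length(p) != length(profile$O))
    stop("dimension mismatch between profile and availability")
  if (!is.null(names(p)) && !identical(names(p), names(profile$O)))
    stop("habitat names of profile and availability disagree")
  E <- profile$N * as.numeric(p)
  names(E) <- names(profile$O)
  structure(E, N = profile$N, p = as.numeric(p), class = "expected_use")
}

round_ha <- function(x, digits) {
  # round half away from zero (display convention of the report tables;
  # base round() is banker's)
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Composition summary of a capture survey
#'
#' Descriptive statistics of survey composition: per-season stage shares (%
#' of the season total), the overall sex ratio (females:males pooled over
#' seasons), and collection-method totals and efficiency ratios per season
#' and per stage. Ratios with a zero denominator are returned as `NA`
#' (reported "undefined").
#'
#' @param counts a [count_matrix()] with at least one nonzero cell.
#' @return A list of class `composition_summary` with elements
#'   `stage_shares` (season x stage matrix, %), `season_totals`,
#'   `sex_ratio`, `method_totals` (season x method), `method_ratio`
#'   (per season: larger method subtotal / smaller), and
#'   `method_ratio_by_stage` (season x stage, trap/transect).
#' @export
composition_summary <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  arr <- unclass(counts)
  if (sum(arr) == 0) stop("composition summary needs at least one capture")
  by_ss <- apply(arr, c("season", "stage"), sum)      # season x stage
  season_tot <- rowSums(by_ss)
  shares <- sweep(by_ss, 1, ifelse(season_tot > 0, season_tot, NA), "/") * 100
  females <- sum(arr["female", , , ])
  males   <- sum(arr["male", , , ])
  sexr <- if (males > 0) females / males else NA_real_
  meth <- apply(arr, c("season", "method"), sum)      # season x method
  mratio <- apply(meth, 1, function(x) {
    if (min(x) == 0) NA_real_ else max(x) / min(x)
  })
  by_ssm <- apply(arr, c("season", "stage", "method"), sum)
  mr_stage <- by_ssm[, , "trap"] / ifelse(by_ssm[, , "transect"] > 0,
                                          by_ssm[, , "transect"], NA)
  structure(list(stage_shares = shares, season_totals = season_tot,
                 sex_ratio = sexr, sex_counts = c(females = females,
                                                  males = males),
                 method_totals = meth, method_ratio = mratio,
                 method_ratio_by_stage = mr_stage),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Stage shares (% of season total):\n")
  print(round_ha(x$stage_shares, 1))
  cat("Sex ratio (F:M):", round_ha(x$sex_ratio, 3), "\n")
  cat("Method ratio (larger:smaller) per season:\n")
  print(round_ha(x$method_ratio, 1))
  invisible(x)
}
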
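# The five habitat-preference indices, their decision rules, and the
# cross-index consensus call.

#' Ivlev's electivity index
#'
#' `E_i = (r_i - p_i) / (r_i + p_i)`, in [-1, 1]. Positive values mean the
#' habitat is used more than its availability predicts (preference); a
#' habitat with zero use gives -1.
#'
#' @param r use proportions (sum to 1).
#' @param p availability proportions (sum to 1, all > 0).
#' @return Named numeric vector of electivities.
#' @export
ivlev <- function(r, p) {
  nm <- names(r)
  r <- as.numeric(r); p <- as.numeric(p)
  E <- (r - p) / (r + p)
  names(E) <- nm
  E
}

#' Jacobs' D ("Interpretation of II")
#'
#' A rescaled electivity less sensitive to rare habitats:
#' `D_i = (r_i - p_i) / (r_i + p_i - 2 r_i p_i)`, in [-1, 1].
#' The decision bins follow the published rule: strong avoidance down to
#' -0.5, moderate avoidance to -0.26, indifference within +/-0.25, neutral
#' selection from 0.26 to 0.49, strong selection from 0.5 up. The published
#' bins leave the gaps (-0.26, -0.25) and (0.25, 0.26) uncovered; values in
#' a gap are assigned to the adjacent, stronger bin.
#'
#' @inheritParams ivlev
#' @return Named numeric vector of D values.
#' @seealso [jacobs_bin()]
#' @export
jacobs_ii <- function(r, p) {
  nm <- names(r)
  r <- as.numeric(r); p <- as.numeric(p)
  den <- r + p - 2 * r * p
  if (any(den <= 0)) stop("degenerate cell: r and p both zero")
  D <- (r - p) / den
  names(D) <- nm
  D
}

#' Decision bin for a Jacobs' D value
#' @param D numeric vector of Jacobs' D values in [-1, 1].
#' @return Character vector of bin labels.
#' @export
jacobs_bin <- function(D) {
  # published endpoints: strong bins are closed at +/-0.5; the gaps the
  # published bins leave near +/-0.25 close toward the stronger label
  ifelse(D <= -0.5, "strong_avoidance",
  ifelse(D <= -0.25, "moderate_avoidance",
  ifelse(D < 0.25, "indifference",
  ifelse(D < 0.5, "neutral_selection", "strong_selection"))))
}

#' Manly's alpha (constant resources)
#'
#' Normalised selectivity ratios `alpha_i = (r_i/p_i) / sum_j(r_j/p_j)`.
#' Sums to 1; parity (no selection) at `1/k`. Preference is signalled when
#' `alpha_i > 1/k`.
#'
#' @inheritParams ivlev
#' @return Named numeric vector of alphas summing to 1.
#' @export
manly_alpha <- function(r, p) {
  nm <- names(r)
  r <- as.numeric(r); p <- as.numeric(p)
  w <- r / p
  if (sum(w) == 0) stop("all use proportions are zero")
  a <- w / sum(w)
  names(a) <- nm
  a
}

#' Duncan preference index
#'
#' The published decision rule is "preference if > 0.3". The default formula
#' is the forage ratio normalised by the number of habitats,
#' `r_i / (k * p_i)` (parity at `1/k`); it reproduces the published
#' decisions at the 0.3 threshold but not every published magnitude, so the
#' formula is a configuration point.
#'
#' @inheritParams ivlev
#' @param k number of habitats (defaults to `length(r)`).
#' @param formula a function `(r, p, k) -> numeric` overriding the default.
#' @param threshold preference threshold (default 0.3).
#' @return Named numeric vector with attribute `threshold`.
#' @export
duncan_index <- function(r, p, k = length(r), formula = NULL,
                         threshold = 0.3) {
  nm <- names(r)
  r <- as.numeric(r); p <- as.numeric(p)
  v <- if (is.null(formula)) r / (k * p) else formula(r, p, k)
  names(v) <- nm
  structure(v, threshold = threshold)
}

#' Bailey simultaneous confidence intervals and classification
#'
#' Bonferroni-adjusted simultaneous binomial intervals on each true use
#' proportion (normal approximation with +/- 1/(2N) continuity correction,
#' z at `alpha_level / (2k)`), scaled to counts. A habitat is classified
#' `preference` when the lower bound of observed use exceeds the expected
#' count, `no_preference` when the upper bound falls below it, and `use`
#' otherwise.
#'
#' @param O observed counts per habitat.
#' @param E expected counts (`N * p`), from [expected_use()].
#' @param alpha_level familywise significance level (default 0.05).
#' @return A data.frame `habitat, O, E, lower, upper, decision` (bounds on
#'   the count scale, clamped to [0, N]).
#' @export
bailey_classification <- function(O, E, alpha_level = 0.05) {
  N <- sum(O)
  if (N <= 0) stop("Bailey classification needs N > 0")
  k <- length(O)
  r <- O / N
  z <- stats::qnorm(1 - alpha_level / (2 * k))
  half <- z * sqrt(r * (1 - r) / N) + 1 / (2 * N)
  lower <- pmax(0, (r - half)) * N
  upper <- pmin(1, (r + half)) * N
  decision <- ifelse(lower > E, "preference",
                     ifelse(upper < E, "no_preference", "use"))
  data.frame(habitat = if (is.null(names(O))) seq_len(k) else names(O),
             O = as.numeric(O), E = as.numeric(E),
             lower = lower, upper = upper, decision = decision,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-habitat preference report across the five indices
#'
#' Evaluates Duncan, Ivlev, Bailey, Manly alpha and Jacobs' D for one
#' group-season profile against an availability vector, attaching each
#' index's published decision rule. Habitats with zero captures get the
#' decision `absent` for every index (their values are still reported where
#' defined).
#'
#' @param profile a [use_profile()].
#' @param p an availability vector.
#' @param alpha_level significance level for the Bailey intervals.
#' @param duncan_formula optional override passed to [duncan_index()].
#' @return A data.frame `group, season, habitat, index, value, decision`
#'   with one row per habitat x index.
#' @export
preference_report <- function(profile, p, alpha_level = 0.05,
                              duncan_formula = NULL) {
  stopifnot(inherits(profile, "use_profile"))
  r <- profile$r
  k <- length(r)
  E  <- ivlev(r, p)
  D  <- jacobs_ii(r, p)
  a  <- manly_alpha(r, p)
  dn <- duncan_index(r, p, k, formula = duncan_formula)
  bl <- bailey_classification(profile$O, profile$N * as.numeric(p),
                              alpha_level)
  dec <- list(
    duncan    = ifelse(dn > attr(dn, "threshold"), "preference",
                       "no_preference"),
    ivlev     = ifelse(E > 0, "preference", "no_preference"),
    bailey    = bl$decision,
    alpha     = ifelse(a > 1 / k, "preference", "no_preference"),
    jacobs_ii = jacobs_bin(D))
  val <- list(duncan = as.numeric(dn), ivlev = E, bailey = bl$E,
              alpha = a, jacobs_ii = D)
  out <- do.call(rbind, lapply(names(dec), function(ix) {
    data.frame(group = profile$group, season = profile$season,
               habitat = names(r), index = ix,
               value = as.numeric(val[[ix]]),
               decision = ifelse(profile$O == 0, "absent",
                                 as.character(dec[[ix]])),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(out, "jacobs_bin") <- jacobs_bin(D)  # numeric bins incl. absent cells
  out
}

#' Cross-index consensus call
#'
#' A habitat is `preferred` when at least 3 of the 5 indices signal
#' preference (for Jacobs' D, neutral or strong selection counts as a
#' preference signal), `avoided` when Jacobs' D falls in an avoidance bin
#' and no index signals preference, and `used` otherwise. Habitats with
#' zero captures are called `avoided` (zero use against positive
#' availability; Jacobs' D is -1 there).
#'
#' @param report the output of [preference_report()].
#' @return A data.frame `group, season, habitat, votes, label`.
#' @export
consensus <- function(report) {
  stopifnot(all(c("habitat", "index", "decision") %in% names(report)))
  habs <- unique(report$habitat)
  jac_num <- attr(report, "jacobs_bin")
  rows <- lapply(seq_along(habs), function(i) {
    h <- habs[i]
    sub <- report[report$habitat == h, ]
    if (nrow(sub) < 3) stop("consensus needs at least 3 indices")
    absent <- all(sub$decision == "absent")
    pref_sig <- sub$decision %in%
      c("preference", "neutral_selection", "strong_selection")
    votes <- sum(pref_sig)
    jbin <- if (!is.null(jac_num)) jac_num[i]
            else sub$decision[sub$index == "jacobs_ii"]
    label <- if (absent) "avoided"
             else if (votes >= 3) "preferred"
             else if (jbin %in% c("strong_avoidance", "moderate_avoidance") &&
                      votes == 0) "avoided"
             else "used"
    data.frame(group = sub$group[1], season = sub$season[1], habitat = h,
               votes = if (absent) 0L else votes, label = label,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
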
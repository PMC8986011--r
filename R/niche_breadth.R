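# Niche-breadth (amplitude) statistics: Shannon and Levins families plus
# the Ivlev-amplitude variant.

#' Shannon niche breadth
#'
#' Shannon diversity of use in nats, `H = -sum(r_i * log(r_i))` over
#' habitats with nonzero use (`0 log 0 = 0`), and its standardised form
#' `H_std = H / log(k)`. Normalisation always uses the full habitat count
#' `k`, including zero-use habitats: a stage concentrated in 2 of 4
#' habitats is narrow relative to the 4 available, not to the 2 occupied.
#'
#' @param r use proportions (sum to 1).
#' @param k number of habitats (>= 2); defaults to `length(r)`.
#' @return A list `(H, H_std)`.
#' @export
shannon_breadth <- function(r, k = length(r)) {
  if (k < 2) stop("niche breadth needs k >= 2")
  r <- as.numeric(r)
  pos <- r > 0
  H <- -sum(r[pos] * log(r[pos]))
  list(H = H, H_std = H / log(k))
}

#' Levins niche-breadth family
#'
#' Levins' measure `B = 1 / sum(r_i^2)` (the inverse Simpson concentration:
#' the effective number of habitats used, in [1, k]), its standardised form
#' `B_std = (B - 1) / (k - 1)` in [0, 1], and the modified standardised
#' form `B_mod = B / k` in [1/k, 1].
#'
#' @inheritParams shannon_breadth
#' @return A list `(B, B_std, B_mod)`.
#' @export
levins_family <- function(r, k = length(r)) {
  if (k < 2) stop("niche breadth needs k >= 2")
  r <- as.numeric(r)
  B <- 1 / sum(r^2)
  list(B = B, B_std = (B - 1) / (k - 1), B_mod = B / k)
}

#' Ivlev niche amplitude
#'
#' The sum of absolute electivities over all habitats,
#' `sum(|(r_i - p_i)/(r_i + p_i)|)`. Orientation is inverted relative to
#' the Shannon/Levins family: 0 means maximum amplitude (use tracks
#' availability everywhere) and larger values mean narrower niches.
#' Zero-use habitats contribute `|-1| = 1`.
#'
#' @param r use proportions.
#' @param p availability proportions.
#' @return The amplitude statistic (scalar >= 0).
#' @export
ivlev_amplitude <- function(r, p) sum(abs(ivlev(r, p)))

#' Niche-breadth report for one group-season profile
#'
#' @param profile a [use_profile()].
#' @param p an availability vector (needed only for the Ivlev amplitude).
#' @return A one-row data.frame `group, season, H, H_std, B, B_std, B_mod,
#'   ivlev_amp`.
#' @export
breadth_report <- function(profile, p) {
  stopifnot(inherits(profile, "use_profile"))
  k <- length(profile$r)
  sh <- shannon_breadth(profile$r, k)
  lv <- levins_family(profile$r, k)
  data.frame(group = profile$group, season = profile$season,
             H = sh$H, H_std = sh$H_std,
             B = lv$B, B_std = lv$B_std, B_mod = lv$B_mod,
             ivlev_amp = ivlev_amplitude(profile$r, p),
             row.names = NULL, stringsAsFactors = FALSE)
}
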
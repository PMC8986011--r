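# Goodness of fit of observed use against availability and the Cherry
# sample-adequacy criterion.

check_OE <- function(O, E) {
  if (length(O) != length(E)) stop("O and E lengths differ")
  N <- sum(O)
  if (N <= 0) stop("goodness-of-fit test needs N > 0")
  if (any(E == 0 & O > 0)) stop("zero expectation with a positive count")
  N
}

#' Log-likelihood-ratio (G) goodness-of-fit test
#'
#' Tests whether observed per-habitat counts `O` are consistent with the
#' expected counts `E = N p` under availability:
#' `G = 2 * sum(O_i * log(O_i / E_i))` over cells with `O_i > 0` (empty
#' cells contribute zero, the `O log O -> 0` limit), with `df = k - 1` and
#' an upper-tail chi-square p-value.
#'
#' @param O non-negative integer counts per habitat.
#' @param E expected counts from [expected_use()] (or any numeric vector of
#'   the same length with the same total).
#' @return A list `(G, df, p)`.
#' @examples
#' g_test(c(10, 0), c(5, 5))
#' @export
g_test <- function(O, E) {
  check_OE(O, E)
  pos <- O > 0
  G <- 2 * sum(O[pos] * log(O[pos] / E[pos]))
  G <- max(G, 0)
  df <- length(O) - 1L
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Pearson chi-square goodness-of-fit test
#'
#' `X2 = sum((O - E)^2 / E)` with `df = k - 1`. Second-order equivalent to
#' the G-test near the null.
#'
#' @inheritParams g_test
#' @return A list `(X2, df, p)`.
#' @export
chi_square_test <- function(O, E) {
  check_OE(O, E)
  X2 <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  list(X2 = X2, df = df, p = stats::pchisq(X2, df, lower.tail = FALSE))
}

#' Cherry sample-adequacy flags
#'
#' The Cherry criterion for use/availability tests requires every expected
#' count `N p_i` and complement `N (1 - p_i)` to exceed 5 before inference
#' at the population level is considered reliable.
#'
#' @param N total captures in the profile (integer >= 0).
#' @param p an availability vector.
#' @return A list `(cherry_np, cherry_nq)` of logicals:
#'   `min(N * p) > 5` and `min(N * (1 - p)) > 5`.
#' @export
cherry_flags <- function(N, p) {
  stopifnot(N >= 0)
  p <- as.numeric(p)
  list(cherry_np = min(N * p) > 5,
       cherry_nq = min(N * (1 - p)) > 5)
}

#' Sample-adequacy report over all group-season profiles
#'
#' Runs [g_test()], [chi_square_test()] and [cherry_flags()] for every
#' group (each stage, adults, all) and season with nonzero captures.
#'
#' @param counts a [count_matrix()].
#' @param p_by_season named list with elements `dry` and `wet`, each an
#'   availability vector; defaults to area-derived availability for both.
#' @param groups group selectors to report on.
#' @return A data.frame with one row per group-season: `group, season, N,
#'   G, df, p_G, X2, p_X2, cherry_np, cherry_nq`.
#' @export
adequacy_report <- function(counts,
                            p_by_season = NULL,
                            groups = c("all", "adults", "nymph", "larva")) {
  stopifnot(inherits(counts, "count_matrix"))
  hs <- habitats_of(counts)
  if (is.null(p_by_season)) {
    p0 <- availability(hs)
    p_by_season <- list(dry = p0, wet = p0)
  }
  rows <- list()
  for (season in tick_seasons) {
    p <- p_by_season[[season]]
    for (g in groups) {
      prof <- tryCatch(use_profile(counts, g, season), error = function(e) NULL)
      if (is.null(prof)) next
      E <- expected_use(prof, p)
      gt <- g_test(prof$O, E)
      ct <- chi_square_test(prof$O, E)
      ch <- cherry_flags(prof$N, p)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, season = season, N = prof$N,
        G = gt$G, df = gt$df, p_G = gt$p,
        X2 = ct$X2, p_X2 = ct$p,
        cherry_np = ch$cherry_np, cherry_nq = ch$cherry_nq,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
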
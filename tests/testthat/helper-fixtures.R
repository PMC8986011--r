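# Shared fixtures: the bundled case-study tables plus generators for
# property-style tests.

amx <- amblyomma_survey()
amx_p <- availability(amx$habitats)

# published dry-season G statistics (group -> G)
published_G_dry <- c(all = 14838.4, adults = 338.7, nymph = 11019.2,
                     larva = 3788.5)

# published dry-season preference-index matrices (Table-style, 1 dp),
# rows all/adults/nymph/larva, columns in canonical habitat order
published_ivlev_dry <- rbind(
  all    = c(0.4, -0.5, 0.2, 0.9),
  adults = c(0.0, -0.4, 0.1, 0.9),
  nymph  = c(0.3, -0.6, 0.1, 0.9),
  larva  = c(0.4, -0.5, 0.3, 0.8))
published_jacobs_dry <- rbind(
  all    = c(0.4, -0.8, 0.2, 0.9),
  adults = c(0.0, -0.7, 0.1, 0.9),
  nymph  = c(0.4, -0.9, 0.1, 1.0),
  larva  = c(0.5, -0.8, 0.3, 0.9))
published_alpha_dry <- rbind(
  all    = c(0.1, 0.0, 0.1, 0.8),
  adults = c(0.1, 0.0, 0.1, 0.9),
  nymph  = c(0.1, 0.0, 0.0, 0.9),
  larva  = c(0.2, 0.0, 0.1, 0.7))

# published niche-breadth cells (2 dp): dry and availability-free wet
published_breadth <- list(
  H_dry      = c(all = 1.31, adults = 1.22, nymph = 1.24, larva = 1.36),
  H_std_dry  = c(all = 0.94, adults = 0.88, nymph = 0.90, larva = 0.98),
  B_std_dry  = c(all = 0.82, adults = 0.68, nymph = 0.68, larva = 0.94),
  B_mod_dry  = c(all = 0.86, adults = 0.76, nymph = 0.76, larva = 0.96),
  amp_dry    = c(all = 1.95, adults = 1.38, nymph = 1.92, larva = 1.99),
  H_wet      = c(all = 1.33, adults = 1.33, nymph = 1.04, larva = 0.44),
  H_std_wet  = c(all = 0.96, adults = 0.96, nymph = 0.75, larva = 0.32),
  B_std_wet  = c(all = 0.86, adults = 0.88, nymph = 0.56, larva = 0.12),
  B_mod_wet  = c(all = 0.90, adults = 0.91, nymph = 0.67, larva = 0.34))

# uniform random point on the k-simplex (strictly positive)
rsimplex <- function(k) {
  x <- stats::rexp(k) + 1e-9
  x / sum(x)
}

# round half away from zero, mirroring the report display convention
rha <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d

# small two-habitat survey used by error-path tests
tiny_habitats <- habitat_set(c("A", "B"), c(100, 300))
tiny_counts <- count_matrix(
  data.frame(group = c("nymph", "nymph"), habitat = c("A", "B"),
             season = "dry", method = "trap", count = c(30, 10)),
  tiny_habitats)
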
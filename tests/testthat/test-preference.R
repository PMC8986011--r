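dry_groups <- c("all", "adults", "nymph", "larva")
dry_profiles <- lapply(dry_groups, function(g) use_profile(amx$counts, g, "dry"))
names(dry_profiles) <- dry_groups

test_that("Ivlev electivity reproduces every published dry-season cell", {
  for (g in dry_groups)
    expect_equal(unname(rha(ivlev(dry_profiles[[g]]$r, amx_p), 1)),
                 unname(published_ivlev_dry[g, ]), label = g)
  # r = p -> 0 everywhere; zero use -> -1
  expect_equal(unname(ivlev(amx_p, amx_p)), rep(0, 4))
  expect_equal(unname(ivlev(c(0, 1), c(0.5, 0.5))), c(-1, 1 / 3))
})

test_that("Jacobs' D reproduces every published dry-season cell", {
  for (g in dry_groups)
    expect_equal(unname(rha(jacobs_ii(dry_profiles[[g]]$r, amx_p), 1)),
                 unname(published_jacobs_dry[g, ]), label = g)
  expect_equal(unname(jacobs_ii(amx_p, amx_p)), rep(0, 4))
  expect_equal(jacobs_bin(rep(0, 4)), rep("indifference", 4))
  # Cocoa Crop total, derived by brute force from the printed counts/areas
  expect_equal(unname(jacobs_ii(dry_profiles$all$r, amx_p)[1]), 0.425,
               tolerance = 1e-3)
  # gap values go to the adjacent stronger bin
  expect_equal(jacobs_bin(c(-0.255, 0.255, -0.5, 0.5)),
               c("moderate_avoidance", "neutral_selection",
                 "strong_avoidance", "strong_selection"))
  expect_error(jacobs_ii(c(0, 1), c(0, 1)), "degenerate")
})

test_that("Manly alpha reproduces every published dry-season cell", {
  for (g in dry_groups)
    expect_equal(unname(rha(manly_alpha(dry_profiles[[g]]$r, amx_p), 1)),
                 unname(published_alpha_dry[g, ]), label = g)
  expect_equal(unname(manly_alpha(amx_p, amx_p)), rep(0.25, 4))
  # Star Grass total from normalised selectivity ratios
  expect_equal(rha(unname(manly_alpha(dry_profiles$all$r, amx_p)[3]), 3),
               0.064)
})

test_that("Duncan default formula behaves at the 0.3 threshold", {
  d <- duncan_index(amx_p, amx_p)
  expect_equal(as.numeric(d), rep(0.25, 4))
  dt <- duncan_index(dry_profiles$all$r, amx_p)
  expect_equal(unname(rha(dt[c(1, 2)], 1)), c(0.5, 0.1))
  expect_equal(unname(duncan_index(c(0, 1), c(0.5, 0.5))[1]), 0)
  # formula is a configuration point
  alt <- duncan_index(c(0.5, 0.5), c(0.25, 0.75),
                      formula = function(r, p, k) r / (r + p))
  expect_equal(as.numeric(alt), c(0.5 / 0.75, 0.5 / 1.25))
})

test_that("Bailey classification matches the published bold/plain calls", {
  totals <- dry_profiles$all
  bl <- bailey_classification(totals$O, unclass(expected_use(totals, amx_p)))
  expect_equal(bl$decision[bl$habitat == "King Grass Crop"], "preference")
  expect_equal(bl$decision[bl$habitat == "Riparian Forest"], "no_preference")
  adults <- dry_profiles$adults
  bla <- bailey_classification(adults$O, unclass(expected_use(adults, amx_p)))
  expect_equal(bla$decision[bla$habitat == "Riparian Forest"],
               "no_preference")
  # O == E exactly -> use
  expect_equal(bailey_classification(c(a = 25, b = 75), c(25, 75))$decision,
               c("use", "use"))
  expect_error(bailey_classification(c(0, 0), c(0, 0)), "N > 0")
})

test_that("consensus reproduces the published habitat calls", {
  cons <- consensus(preference_report(dry_profiles$all, amx_p))
  king <- cons[cons$habitat == "King Grass Crop", ]
  expect_equal(king$label, "preferred")
  expect_equal(king$votes, 5L)
  expect_equal(cons$label[cons$habitat == "Riparian Forest"], "avoided")
  expect_equal(cons$label[cons$habitat == "Star Grass Paddock"], "preferred")

  # a no-selection profile is "used" everywhere
  flat <- structure(list(group = "all", season = "dry",
                         O = round(1000 * amx_p), N = sum(round(1000 * amx_p)),
                         r = unclass(amx_p)), class = "use_profile")
  cons_flat <- consensus(preference_report(flat, amx_p))
  expect_true(all(cons_flat$label == "used"))
})

test_that("absent habitats are labelled absent and called avoided", {
  wl <- use_profile(amx$counts, "larva", "wet")
  pr <- preference_report(wl, amblyomma_wet_availability)
  expect_true(all(pr$decision[pr$habitat == "Cocoa Crop"] == "absent"))
  cons <- consensus(pr)
  expect_equal(cons$label[cons$habitat == "Cocoa Crop"], "avoided")
  expect_equal(cons$votes[cons$habitat == "Cocoa Crop"], 0L)
})

test_that("index identities and inequalities hold on random profiles", {
  set.seed(31)
  for (i in 1:40) {
    k <- sample(3:6, 1)
    r <- rsimplex(k); p <- rsimplex(k)
    a <- manly_alpha(r, p)
    expect_equal(sum(a), 1, tolerance = 1e-12)
    E <- ivlev(r, p); D <- jacobs_ii(r, p)
    expect_true(all(sign(D) == sign(E)))
    expect_true(all(abs(D) >= abs(E) - 1e-12))
    expect_true(all(abs(E) <= 1 & abs(D) <= 1 + 1e-12))
  }
  # E = 0, D = 0, alpha = 1/k simultaneously iff r = p
  p <- rsimplex(5)
  expect_equal(max(abs(ivlev(p, p))), 0)
  expect_equal(max(abs(jacobs_ii(p, p))), 0)
  expect_equal(unname(manly_alpha(p, p)), rep(0.2, 5))
  r2 <- p + c(0.01, -0.01, 0, 0, 0)
  expect_gt(max(abs(ivlev(r2, p))), 0)
})

test_that("decisions are invariant under habitat permutation", {
  set.seed(41)
  prof <- dry_profiles$all
  for (i in 1:10) {
    perm <- sample(4)
    prof_p <- structure(list(group = "all", season = "dry",
                             O = prof$O[perm], N = prof$N,
                             r = prof$r[perm]), class = "use_profile")
    pr0 <- preference_report(prof, amx_p)
    prp <- preference_report(prof_p, unclass(amx_p)[perm])
    for (ix in unique(pr0$index)) {
      d0 <- with(pr0[pr0$index == ix, ], setNames(decision, habitat))
      dp <- with(prp[prp$index == ix, ], setNames(decision, habitat))
      expect_equal(dp[names(d0)], d0, label = ix)
    }
  }
})
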
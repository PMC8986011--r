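groups <- c("all", "adults", "nymph", "larva")
profiles <- list(
  dry = lapply(setNames(groups, groups),
               function(g) use_profile(amx$counts, g, "dry")),
  wet = lapply(setNames(groups, groups),
               function(g) use_profile(amx$counts, g, "wet")))

test_that("Shannon breadth reproduces every published cell", {
  for (season in c("dry", "wet")) {
    key <- paste0("H_std_", season)
    for (g in groups) {
      sh <- shannon_breadth(profiles[[season]][[g]]$r)
      expect_equal(rha(sh$H_std, 2), unname(published_breadth[[key]][g]),
                   label = paste(g, season))
      # the cell printed under the ambiguous "Levins Index" header is
      # numerically Shannon H in nats
      expect_equal(rha(sh$H, 2),
                   unname(published_breadth[[paste0("H_", season)]][g]),
                   label = paste(g, season))
    }
  }
  expect_equal(shannon_breadth(rep(0.25, 4))$H_std, 1)
  expect_error(shannon_breadth(1, k = 1), "k >= 2")
})

test_that("Levins family reproduces every published cell", {
  for (season in c("dry", "wet")) for (g in groups) {
    lv <- levins_family(profiles[[season]][[g]]$r)
    expect_equal(rha(lv$B_std, 2),
                 unname(published_breadth[[paste0("B_std_", season)]][g]),
                 label = paste(g, season))
    expect_equal(rha(lv$B_mod, 2),
                 unname(published_breadth[[paste0("B_mod_", season)]][g]),
                 label = paste(g, season))
  }
  one <- levins_family(c(1, 0, 0, 0))
  expect_equal(one, list(B = 1, B_std = 0, B_mod = 0.25))
})

test_that("Ivlev amplitude reproduces dry cells and the wet-override cell", {
  for (g in groups)
    expect_equal(rha(ivlev_amplitude(profiles$dry[[g]]$r, amx_p), 2),
                 unname(published_breadth$amp_dry[g]), label = g)
  expect_equal(ivlev_amplitude(amx_p, amx_p), 0)
  expect_equal(rha(ivlev_amplitude(profiles$wet$larva$r,
                                   amblyomma_wet_availability), 2), 3.24)
})

test_that("breadth statistics respect their bounds and Hill ordering", {
  set.seed(51)
  for (i in 1:40) {
    k <- sample(2:8, 1)
    r <- rsimplex(k); p <- rsimplex(k)
    sh <- shannon_breadth(r, k); lv <- levins_family(r, k)
    expect_gte(sh$H_std, 0); expect_lte(sh$H_std, 1)
    expect_gte(lv$B, 1); expect_lte(lv$B, k + 1e-12)
    expect_gte(lv$B_std, 0); expect_lte(lv$B_std, 1)
    expect_gte(lv$B_mod, 1 / k - 1e-12); expect_lte(lv$B_mod, 1)
    # Hill-number ordering: inverse Simpson never exceeds exp(Shannon)
    expect_lte(lv$B, exp(sh$H) + 1e-9)
    expect_gte(ivlev_amplitude(r, p), 0)
  }
})

test_that("breadth is permutation-invariant and transfer-monotone", {
  set.seed(61)
  for (i in 1:20) {
    r <- rsimplex(5); p <- rsimplex(5)
    perm <- sample(5)
    expect_equal(shannon_breadth(r[perm])$H_std, shannon_breadth(r)$H_std)
    expect_equal(levins_family(r[perm])$B_std, levins_family(r)$B_std)
    expect_equal(ivlev_amplitude(r[perm], p[perm]), ivlev_amplitude(r, p))
    # Pigou-Dalton: moving mass from the most- to the least-used habitat
    # never decreases H or B
    hi <- which.max(r); lo <- which.min(r)
    eps <- (r[hi] - r[lo]) * runif(1, 0, 0.5)
    r2 <- r; r2[hi] <- r2[hi] - eps; r2[lo] <- r2[lo] + eps
    expect_gte(shannon_breadth(r2)$H + 1e-12, shannon_breadth(r)$H)
    expect_gte(levins_family(r2)$B + 1e-12, levins_family(r)$B)
  }
})

test_that("breadth_report assembles the per-profile table", {
  br <- breadth_report(profiles$dry$all, amx_p)
  expect_equal(rha(br$H_std, 2), 0.94)
  expect_equal(rha(br$ivlev_amp, 2), 1.95)
  expect_equal(names(br), c("group", "season", "H", "H_std", "B", "B_std",
                            "B_mod", "ivlev_amp"))
})
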
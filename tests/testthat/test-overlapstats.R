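test_that("the exact overlap pmf is a proper distribution with a decreasing tail", {
  for (prm in list(c(20, 5, 7), c(50, 10, 10), c(512, 30, 30), c(8, 8, 3))) {
    pmf <- pdspeech:::overlap_pmf(prm[1], prm[2], prm[3])
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    lo <- max(0, prm[2] + prm[3] - prm[1])
    hi <- min(prm[2], prm[3])
    tails <- sapply(lo:hi, function(m) hypergeom_tail(prm[1], prm[2], prm[3], m))
    expect_true(all(diff(tails) < 0))
  }
})

test_that("hypergeometric tail matches enumeration, closed forms and phyper", {
  expect_equal(hypergeom_tail(512, 30, 30, 0), 1)
  expect_equal(hypergeom_tail(4, 2, 2, 2), 1 / 6)
  expect_equal(hypergeom_tail(512, 30, 30, 5), 0.0246, tolerance = 2e-3)

  # brute-force enumeration over every k2-subset, all pools up to N = 12
  for (N in 2:12) {
    for (k1 in unique(c(1, N %/% 3, N %/% 2, N - 1))) {
      if (k1 < 1) next
      for (k2 in unique(c(1, N %/% 2))) {
        for (m in 0:min(k1, k2)) {
          expect_equal(hypergeom_tail(N, k1, k2, m),
                       tail_enumeration(N, k1, k2, m), tolerance = 1e-12)
        }
      }
    }
  }

  # independent distribution-function oracle
  for (m in c(1, 3, 5, 10, 30)) {
    expect_equal(hypergeom_tail(512, 30, 30, m),
                 phyper(m - 1, 30, 482, 30, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_tail(10, 11, 2, 1), "k1, k2")
  expect_error(hypergeom_tail(10, 5, 5, 6), "min")
})

test_that("overlap_test classifies maximal, partial and empty overlaps", {
  full <- overlap_test(1:30, 1:30, N = 512)
  expect_equal(full$m, 30)
  expect_lt(full$p.value, 1e-20)
  expect_true(full$significant)

  none <- overlap_test(1:30, 31:60, N = 512)
  expect_equal(none$p.value, 1)
  expect_false(none$significant)

  # six shared features survive a three-fold correction
  six <- overlap_test(1:30, c(1:6, 101:124), N = 512, correction = 3)
  expect_equal(six$m, 6)
  expect_lt(six$p.corrected, 0.05)
  expect_true(six$significant)
  expect_equal(six$p.corrected, min(1, 3 * six$p.value))

  expect_error(overlap_test(c(1, 600), 1:3, N = 512), "pool")
  # agreement with the one-sided Fisher exact test on the 2x2 overlap table
  ft <- fisher.test(matrix(c(6, 24, 24, 458), 2), alternative = "greater")
  expect_equal(six$p.value, ft$p.value, tolerance = 1e-9)
})

test_that("the Monte-Carlo null matches the exact distribution", {
  expect_error(mc_null(10, 11), "exceed")
  forced <- mc_null(6, 6, runs = 50, seed = 1)
  expect_equal(unname(forced$counts["6"]), 50)
  expect_equal(forced$mean, 6)

  null <- mc_null(200, 20, runs = 5000, seed = 2)
  expect_equal(sum(null$counts), 5000)
  draws_sd <- sqrt(sum(null$counts * (as.numeric(names(null$counts)) -
                                        null$mean)^2) / null$runs)
  expect_lte(abs(null$mean - 20^2 / 200), 4 * draws_sd / sqrt(null$runs))

  # total-variation distance to the exact pmf, averaged over seeds
  pmf <- pdspeech:::overlap_pmf(50, 10, 10)
  tv <- sapply(1:3, function(s) {
    emp <- mc_null(50, 10, runs = 10000, seed = s)$counts / 10000
    full <- numeric(11)
    names(full) <- 0:10
    full[names(pmf)] <- pmf
    sum(abs(emp - full)) / 2
  })
  expect_lte(mean(tv), 0.02)

  expect_identical(mc_null(100, 10, runs = 200, seed = 3)$counts,
                   mc_null(100, 10, runs = 200, seed = 3)$counts)
})

test_that("minimum significant overlap reproduces the exact thresholds", {
  expect_equal(sapply(c(10, 20, 30, 50), min_significant_overlap, N = 512),
               c(2L, 3L, 5L, 9L))
  expect_equal(min_significant_overlap(512, 30, correction = 3), 6L)
  expect_equal(min_significant_overlap(512, 30, alpha = 1), 0L)
  expect_warning(m <- min_significant_overlap(4, 1, alpha = 0.01), "no overlap")
  expect_true(is.na(m))

  # monotone: non-increasing in alpha, non-decreasing in correction
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  ms <- sapply(alphas, function(a) min_significant_overlap(512, 30, alpha = a))
  expect_true(all(diff(ms) >= 0))
  cs <- sapply(c(1, 2, 3, 10), function(cc)
    min_significant_overlap(512, 30, correction = cc))
  expect_true(all(diff(cs) >= 0))
  # and non-decreasing in k
  ks <- sapply(c(5, 10, 20, 30, 50, 100), min_significant_overlap, N = 512)
  expect_true(all(diff(ks) >= 0))
})

test_that("overlap_matrix handles identical, disjoint and mixed-pool rankings", {
  mk <- function(scores) pdspeech:::new_ranking(scores, NULL, "impurity", "cls")
  base <- numeric(100)
  r_same <- mk(replace(base, 1:10, 10:1))
  om_same <- overlap_matrix(list(a = r_same, b = r_same, c = r_same), k = 10)
  expect_true(all(om_same$pairs$m == 10))
  expect_equal(unname(om_same$venn["a&b&c"]), 10)
  expect_equal(sum(om_same$venn), 10)
  expect_equal(om_same$correction, 3)

  r1 <- mk(replace(base, 1:10, 1))
  r2 <- mk(replace(base, 11:20, 1))
  r3 <- mk(replace(base, 21:30, 1))
  om_dis <- overlap_matrix(list(x = r1, y = r2, z = r3), k = 10)
  expect_true(all(om_dis$pairs$m == 0))
  expect_false(any(om_dis$pairs$significant))
  expect_equal(unname(om_dis$venn[c("x", "y", "z")]), c(10, 10, 10))

  expect_error(overlap_matrix(list(a = mk(base), b = mk(numeric(50)))),
               "different feature pools")
})

test_that("repeated-overlap experiment flags shared tasks and not null tasks", {
  shared <- 1:30
  ta <- small_cohort_table(seed = 41, n = 20, D = 512, planted = shared,
                           effect = 3, frames = c(5, 8), name = "sA")
  tb <- small_cohort_table(seed = 42, n = 20, D = 512, planted = shared,
                           effect = 3, frames = c(5, 8), name = "sB")
  exp_shared <- repeated_overlap_experiment(ta, tb, repeats = 5, seed = 2)
  s30 <- exp_shared$summary[exp_shared$summary$k == 30, ]
  expect_identical(s30$flag, "**")

  # disjoint planted channels: no flags at any k in nearly all seeds
  clean <- 0L
  n_seeds <- 8L
  for (s in seq_len(n_seeds)) {
    na <- small_cohort_table(seed = 100 + s, n = 15, D = 512, planted = 1:20,
                             effect = 3, frames = c(5, 8), name = "nA")
    nb <- small_cohort_table(seed = 200 + s, n = 15, D = 512, planted = 41:60,
                             effect = 3, frames = c(5, 8), name = "nB")
    ex <- repeated_overlap_experiment(na, nb, repeats = 3, seed = s)
    clean <- clean + all(ex$summary$flag == "")
  }
  expect_gte(clean / n_seeds, 0.875)

  e1 <- repeated_overlap_experiment(ta, tb, repeats = 3, seed = 7)
  e2 <- repeated_overlap_experiment(ta, tb, repeats = 3, seed = 7)
  expect_identical(e1$summary, e2$summary)
  expect_error(repeated_overlap_experiment(ta, tb, repeats = 1), "2 repeats")
  expect_error(repeated_overlap_experiment(ta, drop_half_features(tb)),
               "different feature pools")
})
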
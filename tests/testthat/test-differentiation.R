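fx <- make_table2_fixture()
mhc_grouping <- list(g1 = c("Wild", "LGT", "DQ"), g2 = "YX", g3 = "BJ",
                     g4 = c("SD", "HN"))

test_that("hierarchical AMOVA reproduces the published decomposition", {
  a <- amova(fx, mhc_grouping, n_perm = 0)
  expect_identical(a$table$df, c(3, 3, 581))
  expect_equal(a$table$SS, c(12.800, 0.633, 206.899), tolerance = 1e-3)
  expect_equal(a$table$variance, c(0.02996, -0.00250, 0.35611),
               tolerance = 2e-3)
  expect_equal(a$table$percentage[1], 7.81, tolerance = 1e-3)
  expect_equal(unname(a$F["F_CT"]), 0.07810, tolerance = 1e-4)
  expect_equal(unname(a$F["F_SC"]), -0.00706, tolerance = 1e-3)
  expect_equal(unname(a$F["F_ST"]), 0.07159, tolerance = 1e-4)
  # percentages always sum to 100 even with negative components
  expect_equal(sum(a$table$percentage), 100, tolerance = 1e-9)
})

test_that("AMOVA permutation tests are significant where published, and seeded", {
  a <- amova(fx, mhc_grouping, n_perm = 1023, seed = 9)
  expect_lt(a$p[["F_CT"]], 0.05)
  expect_gt(a$p[["F_SC"]], 0.5)   # published 0.813
  expect_lt(a$p[["F_ST"]], 0.01)
  b <- amova(fx, mhc_grouping, n_perm = 1023, seed = 9)
  expect_identical(a$p, b$p)
})

test_that("AMOVA degenerates correctly on boundary cases", {
  # splitting one population into identical halves: no among-group signal
  m <- rbind(A = c(30, 20, 10), B = c(30, 20, 10))
  a <- amova(m, list("A", "B"), n_perm = 0)
  expect_lte(a$table$variance[1], 0)
  expect_lte(a$table$percentage[1], 0)  # negative component retained
  # fixed disjoint populations in their own groups: everything among groups
  m <- rbind(A = c(40, 0), B = c(0, 40))
  a <- amova(m, list("A", "B"), n_perm = 0)
  expect_equal(a$table$percentage[1], 100, tolerance = 1e-9)
  # errors
  expect_error(amova(fx, list(c("Wild", "YX"))), "partition")
  expect_error(amova(fx, list(character(0), rownames(fx))), "empty group")
})

test_that("two-level AMOVA F_ST equals the pairwise value and the WC oracle", {
  set.seed(13)
  for (rep in 1:40) {
    m <- random_count_table(2, sample(2:5, 1))
    f2 <- amova(m, NULL, n_perm = 0)$F[["F_ST"]]
    expect_equal(f2, pairwise_fst(m)[1, 2], tolerance = 1e-12)
    expect_equal(f2, oracle_wc_theta(m), tolerance = 1e-9)
  }
})

test_that("pairwise F_ST spans the published range on the fixture", {
  f <- pairwise_fst(fx)
  expect_identical(round(max(f, na.rm = TRUE), 3), 0.199)
  expect_identical(round(min(f, na.rm = TRUE), 3), -0.036)
  # identical populations: non-positive; fixed disjoint: exactly 1
  m <- rbind(A = c(25, 25), B = c(25, 25))
  expect_lte(pairwise_fst(m)[1, 2], 0)
  m <- rbind(A = c(50, 0), B = c(0, 50))
  expect_equal(pairwise_fst(m)[1, 2], 1, tolerance = 1e-12)
  expect_error(pairwise_fst(rbind(A = c(0, 0), B = c(1, 1))), "zero gene")
})

test_that("the grouping search ranks the published groupings correctly", {
  msat_grouping <- list(g1 = c("Wild", "YX", "LGT", "DQ"), g2 = "BJ",
                        g3 = c("SD", "HN"))
  rk <- grouping_search(fx, list(mhc = mhc_grouping, msat = msat_grouping),
                        n_perm = 200, seed = 2)
  expect_identical(rk$grouping[1], "mhc")
  expect_equal(rk$pct_among, c(7.81, 7.29), tolerance = 1e-2)
  # a grouping that merges identical synthetic populations beats a split
  m <- rbind(A = c(30, 10), B = c(30, 10), C = c(5, 35))
  good <- list(list(c("A", "B"), "C"))
  bad <- list(list(c("A", "C"), "B"))
  rk2 <- grouping_search(m, c(good, bad), n_perm = 0, seed = 1)
  expect_identical(rk2$grouping[1], "A,B | C")
  expect_warning(grouping_search(m, c(good, good, bad), n_perm = 0),
                 "duplicate")
})

test_that("G'ST matches the brute-force oracle and its defining properties", {
  # fixed disjoint populations: G'ST = 1 exactly
  m <- rbind(A = c(30, 0), B = c(0, 50))
  g <- gst_hedrick(m)
  expect_equal(g$G_prime_ST, 1, tolerance = 1e-12)
  # identical populations: near zero up to the sampling corrections of the
  # Nei-Chesser estimators (they can dip slightly negative)
  m <- rbind(A = c(30, 30), B = c(30, 30))
  g <- gst_hedrick(m)
  expect_lt(abs(g$G_ST), 0.02)
  expect_lt(abs(g$G_prime_ST), 0.05)
  # random tables match an independently coded textbook oracle to 1e-12
  set.seed(17)
  for (rep in 1:20) {
    m <- random_count_table(3, 4)
    g <- gst_hedrick(m)
    expect_equal(g$G_prime_ST, oracle_gst_prime(m), tolerance = 1e-12)
    expect_true(g$H_S <= g$H_T + 0.02)  # within estimator tolerance
    if (g$G_ST >= 0) expect_gte(g$G_prime_ST, g$G_ST - 1e-12)
  }
  # near-invariant to duplicating every count by a constant factor (exact
  # only without the finite-sample corrections, so checked on a strongly
  # differentiated table where the corrections are second order)
  m <- rbind(A = c(60, 5, 5), B = c(5, 60, 5), C = c(5, 5, 60))
  expect_equal(gst_hedrick(m)$G_prime_ST, gst_hedrick(m * 4L)$G_prime_ST,
               tolerance = 0.02)
})

test_that("loci bootstrap envelopes behave at the degenerate ends", {
  m <- rbind(A = c(20, 10), B = c(10, 20))
  # all loci identical: zero-width interval at the point estimate
  loci <- list(L1 = m, L2 = m, L3 = m)
  env <- gst_bootstrap_envelope(loci, B = 50, seed = 3)
  expect_equal(env$low, env$estimate, tolerance = 1e-12)
  expect_equal(env$high, env$estimate, tolerance = 1e-12)
  # B = 1: interval collapses onto the single replicate, flagged degenerate
  env1 <- gst_bootstrap_envelope(list(L1 = m,
                                      L2 = rbind(A = c(25, 5), B = c(5, 25))),
                                 B = 1, seed = 3)
  expect_true(all(env1$degenerate))
  expect_equal(env1$low, env1$high, tolerance = 1e-12)
  expect_warning(gst_bootstrap_envelope(list(L1 = m), B = 10), "single locus")
})

test_that("outlier calls respect closed intervals and matched pair sets", {
  env <- data.frame(pop1 = c("A", "A", "B"), pop2 = c("B", "C", "C"),
                    estimate = c(0.2, 0.3, 0.1),
                    low = c(0.1, 0.2, 0.05), high = c(0.3, 0.4, 0.15),
                    degenerate = FALSE)
  ad <- c("A:B" = 0.35, "A:C" = 0.4, "B:C" = 0.01)
  oc <- outlier_compare(ad, env)
  expect_identical(oc$calls$classification, c("above", "inside", "below"))
  expect_identical(oc$n_above, 1L)
  expect_identical(oc$n_below, 1L)
  expect_error(outlier_compare(c("A:B" = 0.1), env), "match")
})

test_that("the Mantel test recovers perfect correlation and is seeded", {
  set.seed(8)
  A <- matrix(runif(49), 7, 7); A <- A + t(A); diag(A) <- 0
  r <- mantel_test(A, A, n_perm = 99, seed = 1)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_lte(r$p, 1 / 100 + 1e-12)
  r2 <- mantel_test(A, 2 * A + 1 - diag(7), n_perm = 99, seed = 1)
  expect_equal(r2$r, 1, tolerance = 1e-9)
  B <- matrix(runif(49), 7, 7); B <- B + t(B); diag(B) <- 0
  expect_identical(mantel_test(A, B, n_perm = 99, seed = 2)$p,
                   mantel_test(A, B, n_perm = 99, seed = 2)$p)
  expect_error(mantel_test(A, B[1:5, 1:5]), "mismatch")
})

test_that("chord distances and the NJ tree recover known topologies", {
  # identical frequencies: distance zero; disjoint fixed: formula maximum
  m <- rbind(A = c(10, 10), B = c(20, 20), C = c(0, 40))
  D <- chord_distance(m)
  expect_equal(D["A", "B"], 0, tolerance = 1e-12)
  expect_equal(D["A", "C"],
               2 / pi * sqrt(2 * (1 - sqrt(0.5))), tolerance = 1e-12)
  # two identical populations form a cherry with full support
  m4 <- rbind(P1 = c(30, 10, 5), P2 = c(30, 10, 5), P3 = c(5, 30, 10),
              P4 = c(10, 5, 30))
  tr <- chord_nj_tree(m4, n_boot = 100, seed = 6)
  phy <- tr$tree
  pair <- ape::extract.clade(ape::root(phy, "P4"),
                             ape::getMRCA(ape::root(phy, "P4"),
                                          c("P1", "P2")))$tip.label
  expect_setequal(pair, c("P1", "P2"))
  # fixture: SD and HN form a cherry and BJ attaches to that cluster
  tf <- chord_nj_tree(fx)$tree
  rooted <- ape::root(tf, "Wild")
  sdhn <- ape::extract.clade(rooted, ape::getMRCA(rooted, c("SD", "HN")))
  expect_setequal(sdhn$tip.label, c("SD", "HN"))
  cluster1 <- ape::extract.clade(rooted,
                                 ape::getMRCA(rooted, c("SD", "HN", "BJ")))
  expect_setequal(cluster1$tip.label, c("SD", "HN", "BJ"))
  expect_error(chord_nj_tree(m), NA)
})

test_that("among- vs within-group pairwise F_ST t-test matches the soft target", {
  f <- pairwise_fst(fx)
  tt <- fst_group_ttest(f, mhc_grouping)
  expect_identical(tt$df, 19)
  expect_identical(tt$n_among + tt$n_within, 21L)
  # soft chained check: published 2.751 from appendix-precision inputs
  expect_equal(tt$t, 2.751, tolerance = 0.05)
  expect_lt(tt$p, 0.05)
  # exchangeable values rarely significant
  set.seed(3)
  fake <- matrix(0, 7, 7, dimnames = dimnames(f))
  v <- runif(21)
  fake[upper.tri(fake)] <- v; fake <- fake + t(fake)
  t0 <- fst_group_ttest(fake, mhc_grouping)
  expect_true(abs(t0$t) < 3)
  # zero variance in both classes refused
  ones <- matrix(1, 7, 7, dimnames = dimnames(f)); diag(ones) <- 0
  expect_error(fst_group_ttest(ones, mhc_grouping), "zero variance")
})
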
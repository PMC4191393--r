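# builds a CompositionTable in code from per-category counts
mk_ct <- function(df) {
  cats <- c("WT", "U", "A", "other", "ambiguous")
  for (cc in cats) {
    cn <- paste0("n_", cc)
    if (is.null(df[[cn]])) df[[cn]] <- 0L
  }
  df$total <- df$n_WT + df$n_U + df$n_A + df$n_other + df$n_ambiguous
  for (cc in cats) df[[paste0("frac_", cc)]] <- df[[paste0("n_", cc)]] / df$total
  stot <- tapply(df$total, df$sample, sum)
  df$rpm <- df$total / as.numeric(stot[df$sample]) * 1e6
  df$u_rpm <- df$n_U / as.numeric(stot[df$sample]) * 1e6
  if (is.null(df$arm)) df$arm <- "5p"
  class(df) <- c("CompositionTable", "data.frame")
  df
}

test_that("filter_uridylated applies both thresholds and the arm restriction", {
  # sample totals 1e5 -> u_rpm = n_U * 10
  ct <- mk_ct(data.frame(
    mirna = c("m1-5p", "m2-5p", "m3-5p", "m4-3p", "m5-5p"),
    sample = "ctl",
    arm = c("5p", "5p", "5p", "3p", "5p"),
    n_WT = c(580L, 2392L, 171L, 880L, 94851L),
    n_U = c(12L, 8L, 9L, 120L, 477L),
    n_A = c(8L, 0L, 0L, 0L, 472L),
    stringsAsFactors = FALSE))
  cfg <- filter_config(reference_sample = "ctl")
  got <- filter_uridylated(ct, cfg)
  # m1: u_rpm 120, frac 0.02 -> in; m2: frac 8/2400 < 1% -> out;
  # m3: u_rpm 90 but frac 5% -> in; m4: 3p -> out; m5: frac 0.5% -> out
  expect_equal(got, c("m3-5p", "m1-5p"))  # ordered by descending frac_U
  # raising either threshold never adds a miRNA (monotonicity)
  for (rpm in c(10, 50, 200)) for (fr in c(0.01, 0.03, 0.2)) {
    sub <- filter_uridylated(ct, filter_config(min_urid_rpm = rpm,
                                               min_urid_fraction = fr,
                                               reference_sample = "ctl"))
    expect_true(all(sub %in% got))
  }
  expect_error(filter_uridylated(ct, filter_config(reference_sample = "nope")),
               "missing")
})

test_that("compare_conditions deltas, fold changes, ranks", {
  ct <- mk_ct(data.frame(
    mirna = rep(c("a-5p", "b-5p"), 2),
    sample = rep(c("ctl", "kd"), each = 2),
    n_WT = c(700L, 670L, 670L, 720L),
    n_U = c(150L, 80L, 50L, 0L),
    n_A = c(150L, 250L, 280L, 280L),
    stringsAsFactors = FALSE))
  cmp <- compare_conditions(ct, "ctl", "kd", c("a-5p", "b-5p"))
  a <- cmp[cmp$mirna == "a-5p", ]
  expect_equal(a$fraction_U_ref, 0.15)
  expect_equal(a$fraction_U_test, 0.05)
  expect_equal(a$fold_change_U, 3.0)               # 0.15 -> 0.05
  expect_equal(a$delta_A, 0.13, tolerance = 1e-12) # 0.15 -> 0.28
  b <- cmp[cmp$mirna == "b-5p", ]
  expect_true(is.infinite(b$fold_change_U))        # test fraction 0
  expect_true(b$fold_infinite)
  expect_equal(cmp$rank_by_U_reference, c(1L, 2L))
  expect_true(all(sort(cmp$rank_by_A_test) == 1:2))
  # identity comparison: all deltas 0, folds 1
  same <- compare_conditions(ct, "ctl", "ctl", c("a-5p", "b-5p"))
  expect_equal(same$delta_U, c(0, 0))
  expect_equal(same$fold_change_U, c(1, 1))
  # survivor absent from a sample -> fraction 0 with warning
  ct2 <- ct[!(ct$mirna == "b-5p" & ct$sample == "kd"), ]
  class(ct2) <- c("CompositionTable", "data.frame")
  expect_warning(cmp2 <- compare_conditions(ct2, "ctl", "kd",
                                            c("a-5p", "b-5p")), "absent")
  expect_equal(cmp2$fraction_U_test[cmp2$mirna == "b-5p"], 0)
})

test_that("fisher_exact matches closed forms and handles degeneracy", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p, 1.0)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2))$p,
               2 / choose(20, 10), tolerance = 1e-12)
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 0, 5), 2))$p, "degenerate")
  expect_equal(p0, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "negative")
  expect_error(fisher_exact(matrix(c(0.5, 2, 3, 4), 2)), "integer")
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  set.seed(99)
  for (i in 1:200) {
    tb <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisher_exact(tb)$p, stats::fisher.test(tb)$p.value,
                 tolerance = 1e-6)
  }
})

test_that("enrichment_test builds the right table and p-values", {
  universe <- sprintf("m%03d", 1:100)
  lst <- universe[1:5]
  # predicted exactly equals the list: single most extreme table
  r <- enrichment_test(lst, lst, universe)
  expect_equal(unname(r$table[1, ]), c(5L, 0L))
  expect_equal(r$p, 1 / choose(100, 5), tolerance = 1e-12)
  # predicted = universe: degenerate, no discrimination possible
  expect_warning(r2 <- enrichment_test(universe, lst, universe))
  expect_equal(r2$p, 1)
  # disjoint sets: hypergeometric enumeration oracle
  r3 <- enrichment_test(universe[6:10], universe[11:20], universe)
  expect_equal(r3$p, oracle_fisher(0, 10, 5, 85), tolerance = 1e-9)
  # invariance under relabeling outside predicted + list
  uni2 <- c(universe[1:20], sprintf("zz%03d", 1:80))
  r4 <- enrichment_test(universe[6:10], universe[11:20], uni2)
  expect_equal(r4$p, r3$p)
  expect_error(enrichment_test("x", "x", character(0)), "empty universe")
  expect_error(enrichment_test("notin", "m001", universe), "universe")
})

test_that("compensation_test direction and exactness", {
  ct <- mk_ct(data.frame(
    mirna = "m-5p", sample = c("ctl", "kd"),
    n_WT = c(810L, 810L), n_U = c(80L, 20L), n_A = c(110L, 170L),
    stringsAsFactors = FALSE))
  r <- compensation_test(ct, "m-5p", "ctl", "kd")
  expect_equal(unname(r$table), matrix(c(80, 110, 20, 170), 2, byrow = TRUE))
  expect_equal(r$direction, "compensatory")
  expect_equal(r$p, oracle_fisher(80, 110, 20, 170), tolerance = 1e-9)
  expect_lt(r$p, 0.05)
  # equal compositions: p = 1, non-compensatory
  ct2 <- mk_ct(data.frame(mirna = "m-5p", sample = c("ctl", "kd"),
                          n_WT = c(800L, 800L), n_U = c(100L, 100L),
                          n_A = c(100L, 100L), stringsAsFactors = FALSE))
  r2 <- compensation_test(ct2, "m-5p", "ctl", "kd")
  expect_equal(r2$p, 1)
  expect_equal(r2$direction, "non-compensatory")
  # most extreme swap
  ct3 <- mk_ct(data.frame(mirna = "m-5p", sample = c("ctl", "kd"),
                          n_WT = c(90L, 90L), n_U = c(10L, 0L),
                          n_A = c(0L, 10L), stringsAsFactors = FALSE))
  r3 <- compensation_test(ct3, "m-5p", "ctl", "kd")
  expect_equal(r3$p, oracle_fisher(10, 0, 0, 10), tolerance = 1e-9)
  expect_equal(r3$direction, "compensatory")
  # all-zero cells: warning, p = 1
  ct4 <- mk_ct(data.frame(mirna = "m-5p", sample = c("ctl", "kd"),
                          n_WT = c(10L, 10L), stringsAsFactors = FALSE))
  expect_warning(r4 <- compensation_test(ct4, "m-5p", "ctl", "kd"), "zero")
  expect_equal(r4$p, 1)
})

test_that("abundance_concordance: identity, scale invariance, guards", {
  ct <- mk_ct(data.frame(
    mirna = rep(sprintf("m%d-5p", 1:5), 2),
    sample = rep(c("ctl", "kd"), each = 5),
    n_WT = c(10L, 100L, 1000L, 10000L, 300L,
             20L, 200L, 2000L, 20000L, 600L),
    stringsAsFactors = FALSE))
  # second sample is exactly 2x the first: identical RPM -> R^2 = 1
  expect_equal(abundance_concordance(ct, "ctl", "kd"), 1, tolerance = 1e-12)
  expect_equal(abundance_concordance(ct, "ctl", "ctl"), 1)
  ct2 <- ct[ct$mirna %in% c("m1-5p", "m2-5p"), ]
  class(ct2) <- c("CompositionTable", "data.frame")
  expect_error(abundance_concordance(ct2, "ctl", "kd"), "fewer than 3")
})

test_that("simulated depletion pair recovers the planted compensation", {
  # fractions 0.08 -> 0.02 (U) and 0.11 -> 0.17 (A) at n = 5000 reads:
  # direction detected with p < 0.05 in >= 95% of seeds
  hits <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    n <- 5000L
    ref_counts <- as.integer(stats::rmultinom(1, n, c(0.80, 0.08, 0.11, 0.01)))
    test_counts <- as.integer(stats::rmultinom(1, n, c(0.80, 0.02, 0.17, 0.01)))
    ct <- mk_ct(data.frame(
      mirna = "m-5p", sample = c("ctl", "kd"),
      n_WT = c(ref_counts[1], test_counts[1]),
      n_U = c(ref_counts[2], test_counts[2]),
      n_A = c(ref_counts[3], test_counts[3]),
      n_other = c(ref_counts[4], test_counts[4]),
      stringsAsFactors = FALSE))
    r <- compensation_test(ct, "m-5p", "ctl", "kd")
    if (r$direction == "compensatory" && r$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})
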
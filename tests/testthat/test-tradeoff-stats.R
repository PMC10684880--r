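test_that("pearson recovers exact linear relations and validates input", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(pearson(1:3, 1:4), class = "LENGTH_MISMATCH")
  expect_error(pearson(1:2, 1:2), class = "LENGTH_MISMATCH")
  expect_error(pearson(c(1, 1, 1), 1:3), class = "ZERO_VARIANCE")
})

test_that("pearson is invariant under positive affine transforms", {
  set.seed(5)
  for (i in 1:10) {
    x <- stats::rnorm(20)
    y <- stats::rnorm(20)
    r <- pearson(x, y)
    a <- stats::runif(1, 0.1, 5)
    b <- stats::rnorm(1)
    expect_equal(pearson(a * x + b, y), r, tolerance = 1e-12)
    expect_equal(pearson(x, a * y + b), r, tolerance = 1e-12)
  }
})

test_that("subset statistics are mean and sample SD over explicit ids", {
  t1 <- table1_scores()
  ids <- c("S1", "S5", "S10")
  got <- subset_stats(t1, ids, "scaled_fcs")
  v <- t1$scaled_fcs[match(ids, t1$scenario_id)]
  expect_equal(got$mean, sum(v) / 3)
  expect_equal(got$sd, sqrt(sum((v - mean(v))^2) / 2))
  expect_equal(got$n, 3)

  expect_warning(single <- subset_stats(t1, "S5", "scaled_fcs"),
                 class = "SINGLETON_SUBSET")
  expect_equal(single$mean, 71.79)
  expect_true(is.na(single$sd))
  expect_error(subset_stats(t1, character(0), "scaled_fcs"),
               class = "EMPTY_SUBSET")
  expect_error(subset_stats(t1, "S99", "scaled_fcs"), class = "EMPTY_SUBSET")
})

test_that("count_above uses a strict inequality", {
  t1 <- table1_scores()
  expect_equal(count_above(t1, "scaled_fcs", 71), 22)
  expect_equal(count_above(t1, "scaled_fcs", 100), 0)
  expect_equal(count_above(t1, "scaled_fcs", 0), 24)
  # a value exactly on the threshold does not count
  fake <- data.frame(scenario_id = c("a", "b"), x = c(71, 71.0001))
  expect_equal(count_above(fake, "x", 71), 1)
})

test_that("ranking is a tie-averaged permutation with extreme anchors", {
  t1 <- table1_scores()
  for (col in c("scaled_fcs", "heni_minutes")) {
    rk <- rank_scenarios(t1, col)
    expect_equal(sum(rk$rank), 24 * 25 / 2)
    expect_equal(rk$rank[rk$scenario_id == "S1"], 24)
    expect_equal(rk$rank[rk$scenario_id == "S10"], 1)
  }
  asc <- rank_scenarios(t1, "scaled_fcs", direction = "asc")
  expect_equal(asc$rank[asc$scenario_id == "S1"], 1)
})

test_that("kruskal_h matches the reference implementation with ties", {
  set.seed(31)
  for (i in 1:10) {
    g <- sample(c("a", "b", "c"), 30, replace = TRUE)
    v <- sample(1:8, 30, replace = TRUE)  # forces ties
    expect_equal(kruskal_h(v, g),
                 unname(stats::kruskal.test(v, factor(g))$statistic),
                 tolerance = 1e-12)
  }
  # identical values in all groups: H = 0, all ranks average
  v0 <- rep(4, 12)
  g0 <- rep(c("a", "b"), 6)
  expect_equal(kruskal_h(v0, g0), 0)
  tab <- data.frame(scenario_id = letters[1:12], x = v0)
  rk <- rank_scenarios(tab, "x", groups = g0)
  expect_equal(rk$rank, rep(6.5, 12))
  expect_equal(attr(rk, "kruskal_h"), 0)
})

test_that("two-group H agrees with a brute-force rank-sum computation", {
  set.seed(17)
  v <- stats::rnorm(10)
  g <- rep(c("a", "b"), each = 5)
  # explicit rank sums, no ties by construction
  r <- rank(v)
  n <- 10
  h_brute <- 12 / (n * (n + 1)) *
    (5 * (mean(r[g == "a"]) - (n + 1) / 2)^2 +
     5 * (mean(r[g == "b"]) - (n + 1) / 2)^2)
  expect_equal(kruskal_h(v, g), h_brute, tolerance = 1e-12)
})

test_that("Pareto flags match an explicit pairwise dominance oracle", {
  expect_true(tradeoff_table(
    data.frame(scenario_id = "only", n = 1, i = 1), "n", "i")$pareto)

  two <- data.frame(scenario_id = c("A", "B"), n = c(2, 1), i = c(1, 2))
  expect_equal(tradeoff_table(two, "n", "i")$pareto, c(TRUE, FALSE))

  set.seed(23)
  for (rep in 1:5) {
    tab <- data.frame(scenario_id = paste0("s", 1:15),
                      n = sample(1:5, 15, TRUE), i = sample(1:5, 15, TRUE))
    got <- tradeoff_table(tab, "n", "i")$pareto
    oracle <- rep(TRUE, 15)
    for (a in 1:15) for (b in 1:15) {
      if (a == b) next
      if (tab$n[b] >= tab$n[a] && tab$i[b] <= tab$i[a] &&
          (tab$n[b] > tab$n[a] || tab$i[b] < tab$i[a])) {
        oracle[a] <- FALSE
      }
    }
    expect_equal(got, oracle)
  }
})

test_that("the most sustainable ladder scenario is Pareto-non-dominated", {
  # impacts fall and scores rise to S9M3, then both rise at S10
  tab <- data.frame(
    scenario_id = c("S1", "S2M3", "S5", "S9M3", "S10"),
    fcs = c(65, 71, 72, 74.1, 81.7),
    gw = c(0.19, 0.20, 0.16, 0.11, 0.13))
  got <- tradeoff_table(tab, "fcs", "gw")
  expect_true(got$pareto[got$scenario_id == "S9M3"])
  expect_false(got$pareto[got$scenario_id == "S2M3"])
})

test_that("correlation matrices agree with a loop-based pearson oracle", {
  set.seed(41)
  m <- matrix(stats::rnorm(20), nrow = 5, ncol = 4,
              dimnames = list(NULL, paste0("ind", 1:4)))
  got <- correlation_matrix(m)
  expect_equal(got$r, t(got$r))
  expect_equal(diag(got$r), rep(1, 4), ignore_attr = TRUE)
  for (a in 1:4) for (b in 1:4) {
    if (a != b) {
      expect_equal(got$r[a, b], pearson(m[, a], m[, b]), tolerance = 1e-12)
    }
  }
  dup <- cbind(m, ind5 = m[, 1])
  expect_equal(correlation_matrix(dup)$r["ind1", "ind5"], 1)
  anti <- cbind(m[, 1, drop = FALSE], ind6 = -2 * m[, 1])
  expect_equal(correlation_matrix(anti)$r[1, 2], -1)
  flat <- cbind(m, ind7 = 1)
  expect_warning(got0 <- correlation_matrix(flat), class = "ZERO_VARIANCE")
  expect_true(all(is.na(got0$r[, "ind7"])))
})
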
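# Evaluation measures against hand examples and brute-force oracles.

test_that("Q3 and Q10 count correct assignments", {
  expect_equal(q3(c(rep("H", 8), "E", "E"), c(rep("H", 8), "O", "O")), 80)
  expect_equal(q3(c("H", "E"), c("H", "E")), 100)
  expect_equal(q3(c("H", "H"), c("E", "E")), 0)
  expect_error(q3("H", c("H", "E")), "mismatch")
  expect_equal(q10(c(rep("a", 7), "b", "b", "b"),
                   c(rep("a", 7), "c", "c", "c")), 70)
  expect_equal(q10(letters[1:10], letters[1:10]), 100)
  expect_equal(q10(rep("a", 4), rep("b", 4)), 0)
})

test_that("per-chain aggregation uses population SD and SE = SD/sqrt(n-1)", {
  r <- aggregate_per_chain(c(80, 80, 80))
  expect_equal(r$mean, 80)
  expect_equal(r$sd, 0)
  expect_equal(r$se, 0)
  # SD = 2 at n = 5 gives SE = 1
  vals <- c(78, 80, 82, 78, 82)
  sd_pop <- sqrt(mean((vals - mean(vals))^2))
  r2 <- aggregate_per_chain(vals)
  expect_equal(r2$sd, sd_pop)
  expect_equal(r2$se, sd_pop / 2)
  expect_equal(r2$ci95, 1.96 * r2$se)
  r1 <- aggregate_per_chain(42)
  expect_true(is.na(r1$sd) && is.na(r1$se))
  expect_equal(r1$mean, 42)
})

test_that("Spearman handles monotone, anti-monotone and tied inputs", {
  expect_equal(spearman(1:10, (1:10)^3), 1)
  expect_equal(spearman(1:10, -(1:10)), -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(s <- spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(s))
  expect_error(spearman(1, 1), "at least 2")
})

test_that("F1 follows the precision/recall definitions and edge conventions", {
  obs <- c("b", "b", "b", "n", "n", "n")
  perfect <- f1_binary(obs, obs, positive = "b")
  expect_equal(perfect$precision, 100)
  expect_equal(perfect$recall, 100)
  expect_equal(perfect$f1, 100)
  # TP=2 FP=1 FN=1
  pred <- c("b", "b", "n", "b", "n", "n")
  r <- f1_binary(pred, obs, positive = "b")
  expect_equal(r$precision, 200 / 3, tolerance = 1e-9)
  expect_equal(r$recall, 200 / 3, tolerance = 1e-9)
  expect_equal(r$f1, 200 / 3, tolerance = 1e-9)
  # nothing predicted positive: precision undefined, F1 = 0
  none <- f1_binary(rep("n", 4), c("b", "b", "n", "n"), positive = "b")
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  expect_equal(none$f1, 0)
})

test_that("segment extraction returns ordered maximal runs", {
  expect_equal(extract_segments(strsplit("OOHHHOO", "")[[1]], "H"),
               data.frame(start = 3L, end = 5L))
  expect_equal(extract_segments(strsplit("HHOHH", "")[[1]], "H"),
               data.frame(start = c(1L, 4L), end = c(2L, 5L)))
  expect_equal(nrow(extract_segments(rep("O", 5), "H")), 0)
})

test_that("the segment rule enforces both the +/-5 and half-union criteria", {
  # obs residues 10..30, pred 12..28: diffs 2/2, inter 17 >= union 21 / 2
  expect_true(segment_match(list(start = 12, end = 28),
                            list(start = 10, end = 30)))
  # end differs by 20: fails even though overlap is large
  expect_false(segment_match(list(start = 10, end = 50),
                             list(start = 10, end = 30)))
  expect_true(segment_match(list(start = 10, end = 30),
                            list(start = 10, end = 30)))
  # endpoints within 5 but overlap below half the union
  expect_false(segment_match(list(start = 1, end = 2),
                             list(start = 6, end = 7)))
})

test_that("Q_ok counts proteins with all segments matched, in order", {
  obs <- list(p1 = c(rep("O", 5), rep("M", 10), rep("O", 5)),
              p2 = c(rep("M", 8), rep("O", 12)),
              p3 = c(rep("O", 10), rep("M", 6), rep("O", 4)))
  pred <- obs
  pred$p3 <- c(rep("O", 2), rep("M", 6), rep("O", 12))  # start shifted by 8
  expect_equal(q_ok(pred, obs, "M"), 100 * 2 / 3, tolerance = 1e-9)
  # proteins without observed segments leave the denominator
  obs$p4 <- rep("O", 20); pred$p4 <- rep("O", 20)
  expect_equal(q_ok(pred, obs, "M"), 100 * 2 / 3, tolerance = 1e-9)
  # an extra predicted segment makes the protein incorrect
  pred2 <- obs[c("p1", "p2", "p3")]
  pred2$p1[1:2] <- "M"
  expect_equal(q_ok(pred2, obs[c("p1", "p2", "p3")], "M"), 100 * 2 / 3,
               tolerance = 1e-9)
  expect_warning(res <- q_ok(list(a = rep("O", 3)), list(a = rep("O", 3)), "M"),
                 "no protein")
  expect_true(is.na(res))
})

test_that("conservation MCC binarizes at class >= 6", {
  obs <- c(9, 9, 9, 1, 1, 1)
  expect_equal(mcc_conservation(obs, obs), 1)
  expect_equal(mcc_conservation(10 - obs, obs), -1)
  # TP=3 TN=3 FP=1 FN=1 -> (9-1)/sqrt(4^4) = 0.5
  pred <- c(7, 7, 7, 2, 2, 2, 8, 3)
  obs2 <- c(8, 8, 8, 3, 3, 3, 2, 9)
  expect_equal(mcc_conservation(pred, obs2), 0.5)
  expect_warning(m <- mcc_conservation(rep(9, 4), rep(9, 4)), "degenerate")
  expect_true(is.na(m))
})

test_that("baselines match their closed forms", {
  b3 <- baseline_shuffle_labels(rep(1 / 3, 3), n = 20000, seed = 2)
  expect_equal(b3$expected, 100 / 3)
  expect_lt(abs(b3$simulated - b3$expected), 1.5)
  bd <- baseline_shuffle_labels(c(1, 0, 0), n = 100, seed = 1)
  expect_equal(bd$expected, 100)
  expect_equal(bd$simulated, 100)

  maj <- baseline_majority(c(rep("O", 6), rep("H", 3), "E"),
                           classes = c("H", "E", "O"))
  expect_equal(maj$class, "O")
  expect_equal(maj$accuracy, 60)
  expect_equal(baseline_majority(rep("H", 5))$accuracy, 100)
  tie <- baseline_majority(c("H", "H", "O", "O"), classes = c("H", "E", "O"))
  expect_equal(tie$class, "H")
})

test_that("metrics agree with brute-force oracles on random small instances", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    pred <- sample(c("H", "E", "O"), n, TRUE)
    obs <- sample(c("H", "E", "O"), n, TRUE)
    expect_equal(q3(pred, obs), oracle_accuracy(pred, obs))
    expect_equal(f1_binary(pred, obs, "H")$f1, oracle_f1(pred, obs, "H"))
    u <- rnorm(n); v <- rnorm(n)
    expect_equal(spearman(u, v), oracle_spearman(u, v), tolerance = 1e-12)
    cp <- sample(1:9, n, TRUE); co <- sample(1:9, n, TRUE)
    expect_equal(suppressWarnings(mcc_conservation(cp, co)),
                 oracle_mcc(cp >= 6, co >= 6), tolerance = 1e-12)
  }
})

test_that("Q3/Q10/F1 are invariant under consistent relabeling", {
  set.seed(7)
  relab <- c(H = "E", E = "O", O = "H")
  for (i in 1:20) {
    n <- sample(5:30, 1)
    pred <- sample(c("H", "E", "O"), n, TRUE)
    obs <- sample(c("H", "E", "O"), n, TRUE)
    expect_equal(q3(pred, obs), q3(unname(relab[pred]), unname(relab[obs])))
    expect_equal(f1_binary(pred, obs, "H")$f1,
                 f1_binary(unname(relab[pred]), unname(relab[obs]), "E")$f1)
  }
})

test_that("Spearman and MCC flip sign under prediction inversion", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    u <- rnorm(n); v <- rnorm(n)
    expect_equal(spearman(-u, v), -spearman(u, v), tolerance = 1e-12)
    cp <- sample(1:9, n, TRUE); co <- sample(1:9, n, TRUE)
    inv <- ifelse(cp >= 6, 1L, 9L)  # flip the binarized call per residue
    m1 <- suppressWarnings(mcc_conservation(cp, co))
    m2 <- suppressWarnings(mcc_conservation(inv, co))
    if (!is.na(m1) && !is.na(m2)) expect_equal(m2, -m1, tolerance = 1e-12)
  }
})

test_that("perturbing a matched segment beyond the rule never raises Q_ok", {
  obs <- list(p = c(rep("O", 10), rep("M", 12), rep("O", 10)))
  good <- list(p = c(rep("O", 12), rep("M", 12), rep("O", 8)))  # shift 2
  expect_equal(q_ok(good, obs, "M"), 100)
  for (shift in 6:10) {
    bad <- list(p = c(rep("O", 10 + shift), rep("M", 12), rep("O", 10 - shift)))
    expect_equal(q_ok(bad, obs, "M"), 0)
  }
})
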
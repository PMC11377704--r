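# PIDE, the HSSP curve, PSSM construction and the redundancy splitter.

test_that("PIDE is the identity fraction over match states", {
  expect_equal(compute_pide(50, 100), 50)
  expect_equal(compute_pide(0, 80), 0)
  expect_equal(compute_pide(33, 66), 50)
  expect_error(compute_pide(0, 0), "L")
  expect_error(compute_pide(5, 4), "n_ident")
})

test_that("HVAL reproduces the three branches of the HSSP curve", {
  # short alignments: only full identity is significant
  expect_equal(compute_hval(100, 10), 0)
  expect_equal(compute_hval(100, 11), 0)
  # long alignments: constant 19.5 offset
  expect_equal(compute_hval(30, 500), 10.5)
  expect_equal(compute_hval(80, 451), 60.5)
  # middle branch, hand-evaluated: 480*100^(-0.32*(1+e^-0.1)) = 28.99
  expect_lt(abs(compute_hval(29, 100)), 0.05)
  expect_error(compute_hval(101, 50), "pide")
  expect_error(compute_hval(50, 0), "L")
})

test_that("the HVAL curve is continuous at L = 450 and monotone in PIDE", {
  expect_lt(abs(compute_hval(50, 450) - compute_hval(50, 451)), 0.1)
  for (L in c(12, 50, 200, 450, 1000)) {
    pides <- seq(0, 100, by = 5)
    hv <- compute_hval(pides, rep(L, length(pides)))
    expect_true(all(diff(hv) > 0))
  }
  # identity threshold (PIDE at HVAL = 0) is non-increasing in L
  thr <- vapply(c(12, 20, 50, 100, 250, 450, 500), function(L)
    -compute_hval(0, L), 1.0)
  expect_true(all(diff(thr) <= 1e-9))
})

test_that("pairwise_stats counts match states and identities", {
  st <- pairwise_stats("AC-DE", "AVD-E")
  # columns 1,2,5 have residues in both rows; 1 and 5 identical
  expect_equal(st$L, 3)
  expect_equal(st$n_ident, 2)
})

test_that("PSSM frequencies follow the pseudocount formula", {
  m1 <- msa(c(q = "A"), "q")
  p1 <- compute_pssm(m1, alpha = 0)
  expect_equal(unname(p1$values[1, "A"]), 1)
  expect_equal(sum(p1$values), 1)

  m2 <- msa(c(q = "A", h = "C"), "q")
  p2 <- compute_pssm(m2, alpha = 0)
  expect_equal(unname(p2$values[1, c("A", "C")]), c(0.5, 0.5))

  m3 <- msa(c(q = "A", h = "A"), "q")
  p3 <- compute_pssm(m3, alpha = 1)
  expect_equal(unname(p3$values[1, "A"]), (2 + 0.05) / 3)
})

test_that("PSSM rows always sum to 1 and single-row alpha=0 is one-hot", {
  for (seed in 1:5) {
    fam <- simulate_family(family_sim_config(L = 25, N = 6, seed = seed),
                           paste0("pf", seed))
    p <- compute_pssm(fam$msa, alpha = 1)
    expect_equal(rowSums(p$values), rep(1, 25), tolerance = 1e-9)
  }
  fam1 <- simulate_family(family_sim_config(L = 15, N = 0, seed = 2), "solo")
  oh <- compute_pssm(fam1$msa, alpha = 0)$values
  expect_equal(rowSums(oh), rep(1, 15))
  expect_true(all(apply(oh, 1, max) == 1))
  qchars <- strsplit(fam1$query$seq, "")[[1]]
  expect_equal(colnames(oh)[apply(oh, 1, which.max)], qchars)
})

test_that("log-odds PSSM features are clipped into [-1, 1]", {
  m <- msa(c(q = "AAAA", h = "AAAA"), "q")
  p <- compute_pssm(m, alpha = 0.01, scheme = "log-odds")
  f <- pssm_features(p)
  expect_true(all(f >= -1 & f <= 1))
  # frequency features pass through unchanged
  pf <- compute_pssm(m, alpha = 1)
  expect_identical(pssm_features(pf), unname(pf$values))
})

mk_stats <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(id1 = r[[1]], id2 = r[[2]], n_ident = as.numeric(r[[3]]),
               L = as.numeric(r[[4]]))))
}

test_that("redundancy_split assigns all records when no constraint binds", {
  ids <- c("a", "b", "c")
  stats <- mk_stats(list("a", "b", 10, 500), list("a", "c", 10, 500),
                    list("b", "c", 10, 500))  # PIDE 2, HVAL << 0
  sp <- redundancy_split(ids, stats, n_test = 1, n_val = 1, seed = 3)
  expect_setequal(sp$partition, c("test", "val", "train"))
  expect_equal(sum(sp$partition == "dropped"), 0)
})

test_that("a record similar to a test member is dropped from every partition", {
  ids <- c("a", "b")
  # HVAL(a, b) = PIDE - 19.5 = 25 - 19.5 = 5.5 > 0
  stats <- mk_stats(list("a", "b", 125, 500))
  sp <- redundancy_split(ids, stats, n_test = 1, n_val = 0, seed = 1,
                         eligible = c(b = FALSE))  # forces a into test
  part <- setNames(sp$partition, sp$id)
  expect_equal(unname(part["a"]), "test")
  expect_equal(unname(part["b"]), "dropped")
})

test_that("of two training chains above the identity cap exactly one is dropped", {
  ids <- c("c", "d")
  stats <- mk_stats(list("c", "d", 400, 500))  # PIDE 80 > 70
  sp <- redundancy_split(ids, stats, n_test = 0, n_val = 0, seed = 1)
  expect_setequal(sp$partition, c("train", "dropped"))
})

test_that("unattainable split sizes fail with the attainable maximum", {
  ids <- c("a", "b", "c")
  # every pair far above the curve: only one chain can enter test
  stats <- mk_stats(list("a", "b", 450, 500), list("a", "c", 450, 500),
                    list("b", "c", 450, 500))
  expect_error(redundancy_split(ids, stats, n_test = 2, n_val = 0, seed = 1),
               "at most 1")
})

test_that("missing pairs count as dissimilar", {
  ids <- c("a", "b", "c")
  stats <- mk_stats(list("a", "b", 10, 500))  # no record for the other pairs
  sp <- redundancy_split(ids, stats, n_test = 1, n_val = 1, seed = 2)
  expect_equal(sum(sp$partition == "dropped"), 0)
})

test_that("verify_no_leakage reports exactly the offending cross pairs", {
  assign <- data.frame(id = c("t1", "v1", "r1"),
                       partition = c("test", "val", "train"))
  clean <- mk_stats(list("t1", "v1", 50, 500), list("t1", "r1", 50, 500),
                    list("v1", "r1", 50, 500))  # PIDE 10
  rep1 <- verify_no_leakage(assign, clean, threshold = 0.3)
  expect_equal(nrow(rep1), 0)
  expect_true(attr(rep1, "pass"))

  dirty <- mk_stats(list("t1", "r1", 200, 500))  # PIDE 40
  rep2 <- verify_no_leakage(assign, dirty, threshold = 0.3)
  expect_equal(nrow(rep2), 1)
  expect_setequal(c(rep2$id1, rep2$id2), c("t1", "r1"))
  # a vacuous threshold always passes
  expect_true(attr(verify_no_leakage(assign, dirty, threshold = 1.0), "pass"))
})

test_that("split output passes the leakage check implied by its own criteria", {
  # long alignments: HVAL <= 0 bounds cross-set identity at 19.5%
  set.seed(7)
  ids <- paste0("s", 1:20)
  pairs <- t(combn(ids, 2))
  stats <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
                      n_ident = sample(0:110, nrow(pairs), TRUE), L = 500)
  sp <- redundancy_split(ids, stats, n_test = 3, n_val = 3, seed = 9)
  rep <- verify_no_leakage(sp, stats, threshold = 19.5 / 100 + 1e-9)
  # only train-train pairs may exceed it; filter those out of the report
  cross <- rep[rep$partition1 != "train" | rep$partition2 != "train", ]
  expect_equal(nrow(cross), 0)
})
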
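# The five prediction strategies and their reduction identities.

fit_base <- function(tr, D = 8, seed = 17, epochs = 30) {
  cfg <- cnn_config(variant = "base", input_width = D, max_epochs = epochs,
                    patience = epochs, seed = seed)
  residue_cnn(tr$feats, tr$labs, config = cfg)
}

test_that("single-row MSAs make the MSA workflows reduce to the raw workflow", {
  tr <- toy_training(n_chains = 6, L = 25, sigma = 0.2, seed = 23, D = 8)
  mod <- fit_base(tr)
  fam <- tr$fams[[1]]
  raw <- predict_raw(fam$query, fam$provider, mod)
  m1 <- fam$msa  # N = 0 in toy_training: the MSA is query-only
  expect_equal(length(m1$rows), 1)
  msaemb <- predict_msa_embedding(fam$query, m1, fam$provider, mod,
                                  records = fam$records)
  cons <- predict_msacons(fam$query, m1, cnn_predictor(mod, fam$provider),
                          records = fam$records)
  expect_identical(unclass(raw)[, ], unclass(msaemb)[, ])
  expect_identical(unname(unclass(raw)[, ]), unclass(cons)[, ])
})

test_that("identical-row MSAs also collapse to the raw prediction", {
  prov <- seq_provider()
  tr <- toy_training(n_chains = 6, L = 25, sigma = 0, seed = 24, D = 8)
  mod <- fit_base(tr)
  # build features under the sequence-deterministic provider for exactness
  rec <- protein_record("q", "ACDEFGHIKL")
  cfg2 <- cnn_config(variant = "base", input_width = 2, max_epochs = 3,
                     patience = 3, seed = 2)
  feats <- setNames(list(embed_record(prov, rec)), "q")
  labs <- setNames(list(rep(c("H", "O"), 5)), "q")
  mod2 <- residue_cnn(feats, labs, config = cfg2)
  raw <- predict_raw(rec, prov, mod2)
  m <- msa(c(q = rec$seq, h1 = rec$seq, h2 = rec$seq), "q")
  msaemb <- predict_msa_embedding(rec, m, prov, mod2)
  cons <- predict_msacons(rec, m, cnn_predictor(mod2, prov))
  expect_equal(unclass(raw)[, ], unclass(msaemb)[, ], tolerance = 1e-12)
  expect_equal(unname(unclass(raw)[, ]), unclass(cons)[, ], tolerance = 1e-12)
})

test_that("MSACons averages channel vectors column-wise", {
  # two rows with constant per-residue vectors [1,0,0] and [0,1,0]
  m <- msa(c(q = "ACD", h = "ACD"), "q")
  pred_tbl <- list(q = rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)),
                   h = rbind(c(0, 1, 0), c(0, 1, 0), c(0, 1, 0)))
  predictor <- function(record) pred_tbl[[record$id]]
  out <- predict_msacons(protein_record("q", "ACD"), m, predictor)
  expect_equal(unclass(out)[, ], matrix(c(0.5, 0.5, 0), 3, 3, byrow = TRUE))
})

test_that("a row gapped at a column is excluded from that column's average", {
  # h2 is gapped at column 2: column 2 averages only q and h1
  m <- msa(c(q = "ACD", h1 = "ACD", h2 = "A-D"), "q")
  pred_tbl <- list(q = rbind(c(1, 0), c(1, 0), c(1, 0)),
                   h1 = rbind(c(0, 1), c(0, 1), c(0, 1)),
                   h2 = rbind(c(0, 1), c(0, 1)))
  predictor <- function(record) pred_tbl[[record$id]]
  out <- predict_msacons(protein_record("q", "ACD"), m, predictor)
  expect_equal(unclass(out)[2, ], c(0.5, 0.5))
  expect_equal(unclass(out)[1, ], c(1 / 3, 2 / 3))
  expect_equal(unclass(out)[3, ], c(1 / 3, 2 / 3))
})

test_that("MSACons is invariant to row order and warns on failing rows", {
  fam <- simulate_family(family_sim_config(L = 18, N = 5, sigma = 0.5,
                                           seed = 19), "wf")
  tr <- toy_training(n_chains = 5, L = 20, sigma = 0.5, seed = 20, D = 16)
  feats <- setNames(lapply(tr$fams, function(f) embed_record(f$provider, f$query)),
                    names(tr$feats))
  cfg <- cnn_config(variant = "base", input_width = 16, max_epochs = 10,
                    patience = 10, seed = 3)
  mod <- residue_cnn(feats, tr$labs, config = cfg)
  pr <- cnn_predictor(mod, fam$provider)
  c1 <- predict_msacons(fam$query, fam$msa, pr, records = fam$records)
  ids <- names(fam$msa$rows)
  perm <- c(fam$msa$query_row, rev(setdiff(seq_along(ids), fam$msa$query_row)))
  m2 <- msa(fam$msa$rows[perm], ids[fam$msa$query_row])
  c2 <- predict_msacons(fam$query, m2, pr, records = fam$records)
  expect_equal(unclass(c1), unclass(c2), ignore_attr = TRUE)

  # a predictor that fails on one homolog: warn and continue
  flaky <- function(record) {
    if (record$id == ids[2]) stop("cannot embed")
    pr(record)
  }
  expect_warning(c3 <- predict_msacons(fam$query, fam$msa, flaky,
                                       records = fam$records), "skipping")
  expect_equal(dim(unclass(c3)), dim(unclass(c1)))
})

test_that("PSSM fusion workflows consume D+20 features and keep L", {
  tr <- toy_training(n_chains = 8, L = 22, sigma = 0.5, seed = 27, D = 8)
  fams <- lapply(seq_along(tr$fams), function(i)
    simulate_family(family_sim_config(L = 22, N = 4, sigma = 0.5, seed = 27,
                                      mu = signal_table(c("H", "E", "O"), D = 8)),
                    paste0("pw", i)))
  ids <- vapply(fams, function(f) f$query$id, "")
  labs <- setNames(lapply(fams, `[[`, "labels"), ids)
  emb <- setNames(lapply(fams, function(f) embed_record(f$provider, f$query)), ids)
  pssm <- setNames(lapply(fams, function(f)
    pssm_features(compute_pssm(f$msa))), ids)
  concat_feats <- setNames(Map(cbind, emb, pssm), ids)
  expect_true(all(vapply(concat_feats, ncol, 1L) == 28))

  cfg_c <- cnn_config(variant = "concat", input_width = 8, max_epochs = 8,
                      patience = 8, seed = 4)
  mod_c <- residue_cnn(concat_feats, labs, config = cfg_c)
  out_c <- predict_pssm_concat(fams[[1]]$query, fams[[1]]$msa,
                               fams[[1]]$provider, mod_c)
  expect_equal(nrow(out_c), 22)
  expect_equal(rowSums(unclass(out_c)[, ]), rep(1, 22), tolerance = 1e-9)

  split_feats <- setNames(Map(function(e, p) list(emb = e, pssm = p),
                              emb, pssm), ids)
  cfg_s <- cnn_config(variant = "split", input_width = 8, max_epochs = 8,
                      patience = 8, seed = 4)
  mod_s <- residue_cnn(split_feats, labs, config = cfg_s)
  out_s <- predict_pssm_split(fams[[1]]$query, fams[[1]]$msa,
                              fams[[1]]$provider, mod_s)
  expect_equal(nrow(out_s), 22)

  # a base model is rejected by the fusion workflows and vice versa
  mod_b <- fit_base(tr, epochs = 2)
  expect_error(predict_pssm_concat(fams[[1]]$query, fams[[1]]$msa,
                                   fams[[1]]$provider, mod_b), "concat")
  expect_error(predict_raw(fams[[1]]$query, fams[[1]]$provider, mod_c), "base")
})

test_that("an uninformative (uniform) PSSM leaves concat close to raw", {
  # alpha -> infinity drives every PSSM row to the uniform background
  n <- 24
  fams <- lapply(seq_len(n), function(i)
    simulate_family(family_sim_config(L = 40, N = 5, sigma = 1, seed = 301,
                                      mu = signal_table(c("H", "E", "O"), D = 8)),
                    paste0("ab", i)))
  ids <- vapply(fams, function(f) f$query$id, "")
  labs <- setNames(lapply(fams, `[[`, "labels"), ids)
  emb <- setNames(lapply(fams, function(f) embed_record(f$provider, f$query)), ids)
  flat <- setNames(lapply(fams, function(f)
    pssm_features(compute_pssm(f$msa, alpha = 1e9))), ids)
  expect_true(all(abs(unlist(flat) - 0.05) < 1e-6))
  tr_ids <- ids[1:16]; te_ids <- ids[17:24]

  cfg_b <- cnn_config(variant = "base", input_width = 8, max_epochs = 100,
                      patience = 100, seed = 6)
  mod_b <- residue_cnn(emb[tr_ids], labs[tr_ids], config = cfg_b)
  q3_b <- mean(mapply(function(p, o) q3(p, o),
                      predict(mod_b, emb[te_ids], type = "class"),
                      labs[te_ids]))

  cfg_c <- cnn_config(variant = "concat", input_width = 8, max_epochs = 100,
                      patience = 100, seed = 6)
  concat_feats <- setNames(Map(cbind, emb, flat), ids)
  mod_c <- residue_cnn(concat_feats[tr_ids], labs[tr_ids], config = cfg_c)
  q3_c <- mean(mapply(function(p, o) q3(p, o),
                      predict(mod_c, concat_feats[te_ids], type = "class"),
                      labs[te_ids]))
  expect_lt(abs(q3_b - q3_c), 6)
})
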
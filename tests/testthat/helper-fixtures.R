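# Shared fixtures: tiny files and toy providers built in code.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Provider that embeds each residue as a fixed function of the amino acid:
# deterministic on the sequence (not the id), D = 2.
seq_provider <- function() {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYVX", "")[[1]]
  embedding_provider("seqhash", 2L, function(record) {
    idx <- match(strsplit(record$seq, "")[[1]], aa)
    matrix(c(idx, idx^2) * 1.0, ncol = 2)
  })
}

# Provider with fixed per-id embedding matrices (for hand-computed averages).
table_provider <- function(tbl, D) {
  embedding_provider("table", D, function(record) {
    m <- tbl[[record$id]]
    if (is.null(m)) stop("no embedding for ", record$id)
    m
  })
}

# A small separable training setup shared by model/workflow tests.
toy_training <- function(n_chains = 10, L = 30, sigma = 0, seed = 5,
                         D = 8) {
  mu <- signal_table(c("H", "E", "O"), D = D, separation = 2)
  cfg <- family_sim_config(L = L, N = 0, sub_rate = 0, indel_rate = 0,
                           mu = mu, sigma = sigma, seed = seed)
  fams <- lapply(seq_len(n_chains), function(i)
    simulate_family(cfg, paste0("toy", i)))
  ids <- vapply(fams, function(f) f$query$id, "")
  feats <- setNames(lapply(fams, function(f) embed_record(f$provider, f$query)), ids)
  labs <- setNames(lapply(fams, `[[`, "labels"), ids)
  list(feats = feats, labs = labs, fams = fams, mu = mu)
}
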
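# Whole-benchmark simulation: independent families per split, written to
# disk in the package's plain-text formats with a manifest.

#' Simulate a train/validation/test benchmark of families
#'
#' Families are drawn independently (unrelated random queries), so any two
#' chains in different splits share only random-level identity and the split
#' passes [verify_no_leakage()] at the conventional 0.3 threshold with
#' overwhelming probability for `L >= 100`.
#'
#' @param n_train,n_val,n_test Number of families per split.
#' @param config A [family_sim_config()]; the per-family seed derives from
#'   `config$seed` and the family id.
#' @param dir Optional output directory; when given, each split gets the
#'   query FASTA, per-family MSAs (aligned FASTA), label TSV and an
#'   embedding container, plus a `manifest.yaml` listing every file and the
#'   full configuration.
#' @return Named list of splits (`train`, `val`, `test`), each a list of
#'   [simulate_family()] objects; attribute `manifest` when written.
#' @export
simulate_benchmark <- function(n_train, n_val, n_test, config, dir = NULL) {
  stopifnot(n_train >= 1, n_val >= 0, n_test >= 1,
            inherits(config, "family_sim_config"))
  make_split <- function(split, n) {
    fams <- lapply(seq_len(n), function(i)
      simulate_family(config, family_id = paste0(split, i)))
    names(fams) <- vapply(fams, function(f) f$family_id, "")
    fams
  }
  out <- list(train = make_split("train", n_train),
              val = make_split("val", n_val),
              test = make_split("test", n_test))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(config = config_as_list(config),
                     splits = list())
    for (split in names(out)) {
      fams <- out[[split]]
      if (length(fams) == 0) next
      sdir <- file.path(dir, split)
      dir.create(sdir, showWarnings = FALSE)
      queries <- lapply(fams, `[[`, "query")
      fasta <- file.path(sdir, "queries.fasta")
      write_fasta(queries, fasta)
      labels <- lapply(fams, `[[`, "labels")
      names(labels) <- vapply(queries, `[[`, "", "id")
      ltsv <- file.path(sdir, "labels.tsv")
      write_label_tracks(labels, ltsv)
      emb <- lapply(fams, function(f) embed_record(f$provider, f$query))
      names(emb) <- names(labels)
      econ <- file.path(sdir, "embeddings.tsv")
      write_embeddings(emb, econ)
      msa_files <- vapply(names(fams), function(fid) {
        p <- file.path(sdir, paste0(fid, ".afa"))
        write_msa(fams[[fid]]$msa, p)
        basename(p)
      }, "")
      manifest$splits[[split]] <-
        list(n_families = length(fams),
             queries = basename(fasta), labels = basename(ltsv),
             embeddings = basename(econ), msas = unname(msa_files))
    }
    mpath <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(manifest, mpath)
    attr(out, "manifest") <- mpath
  }
  out
}

#' @noRd
config_as_list <- function(config) {
  list(L = config$L, N = config$N, sub_rate = config$sub_rate,
       indel_rate = config$indel_rate,
       mean_seg_len = as.list(config$mean_seg_len),
       classes = config$classes, D = config$D, sigma = config$sigma,
       label_flip_rate = config$label_flip_rate, seed = config$seed)
}

#' Cross-split pairwise identity statistics of a benchmark
#'
#' Computes position-wise identity between the query sequences of different
#' splits (all queries share the configured length, so the gap-free global
#' alignment is the position-by-position comparison). The result feeds
#' [verify_no_leakage()].
#'
#' @param bench A [simulate_benchmark()] result.
#' @return Data frame `id1`, `id2`, `n_ident`, `L` over all cross-split
#'   query pairs.
#' @export
benchmark_cross_stats <- function(bench) {
  splits <- names(bench)
  qs <- list()
  part <- character(0)
  for (s in splits) for (f in bench[[s]]) {
    qs[[f$query$id]] <- f$query$seq
    part[f$query$id] <- s
  }
  ids <- names(qs)
  res <- list()
  k <- 0L
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    if (part[ids[i]] == part[ids[j]]) next
    st <- pairwise_stats(qs[[ids[i]]], qs[[ids[j]]])
    k <- k + 1L
    res[[k]] <- data.frame(id1 = ids[i], id2 = ids[j],
                           n_ident = st$n_ident, L = st$L)
  }
  if (k == 0L) return(data.frame(id1 = character(0), id2 = character(0),
                                 n_ident = integer(0), L = integer(0)))
  do.call(rbind, res)
}
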
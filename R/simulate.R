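# Synthetic protein families: the statistical structure the pipeline
# assumes — homologs with controlled identity, per-residue labels with
# segment structure conserved across the family, and label-driven noisy
# embeddings so that MSA-averaging demonstrably denoises.

#' Configuration of the family simulator
#'
#' @param L Query length in residues.
#' @param N Number of homolog rows in addition to the query.
#' @param sub_rate Per-residue substitution probability in a homolog
#'   (replacement drawn uniformly over the 20 residues, so the expected
#'   identity to the query is `1 - sub_rate * 19/20`).
#' @param indel_rate Per-residue deletion probability in a homolog (recorded
#'   as a gap; columns stay locked to query positions).
#' @param mean_seg_len Named per-state mean segment lengths of the label
#'   process (geometric lengths, first-order state changes).
#' @param classes Label alphabet, in tie-break order.
#' @param mu Class signal table (see [signal_table()]); defines `D`.
#' @param sigma Embedding noise standard deviation per coordinate.
#' @param label_flip_rate Probability that a homolog residue's label is
#'   resampled uniformly (emulates poorly conserved annotations, e.g.
#'   disorder, where family averaging can hurt).
#' @param seed Integer root seed; all randomness derives from it.
#' @return List of class `family_sim_config`.
#' @export
family_sim_config <- function(L = 100L, N = 50L, sub_rate = 0.2,
                              indel_rate = 0.05,
                              mean_seg_len = c(H = 10, E = 5, O = 8),
                              classes = c("H", "E", "O"),
                              mu = signal_table(classes, D = 16L),
                              sigma = 1, label_flip_rate = 0,
                              seed = 1L) {
  stopifnot(L >= 1, N >= 0, sub_rate >= 0, sub_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            all(mean_seg_len >= 1), sigma >= 0,
            label_flip_rate >= 0, label_flip_rate <= 1,
            identical(sort(names(mean_seg_len)), sort(classes)),
            identical(sort(names(mu)), sort(classes)))
  structure(list(L = as.integer(L), N = as.integer(N), sub_rate = sub_rate,
                 indel_rate = indel_rate, mean_seg_len = mean_seg_len,
                 classes = classes, mu = mu, D = length(mu[[1]]),
                 sigma = sigma, label_flip_rate = label_flip_rate,
                 seed = as.integer(seed)),
            class = "family_sim_config")
}

#' Simulate a per-residue label track with segment structure
#'
#' First-order segment process: draw a state, draw a geometric segment length
#' with that state's configured mean, emit, then move to a different state;
#' repeat until `L` residues are produced. Deterministic under the seed.
#'
#' @param config A [family_sim_config()] (fields `L`, `mean_seg_len`,
#'   `classes`, `seed` are used).
#' @param seed Override seed (defaults to the config's).
#' @return Character vector of length `L`.
#' @export
simulate_labels <- function(config, seed = config$seed) {
  with_seed(mix_seed(seed, 101L), {
    classes <- config$classes
    out <- character(0)
    state <- sample(classes, 1L)
    while (length(out) < config$L) {
      m <- config$mean_seg_len[[state]]
      len <- if (m <= 1) 1L else stats::rgeom(1L, 1 / m) + 1L
      out <- c(out, rep(state, len))
      state <- sample(setdiff(classes, state), 1L)
    }
    out[seq_len(config$L)]
  })
}

#' Simulate one protein family
#'
#' The query sequence is drawn uniformly over the 20 residues; each homolog
#' derives from the query by i.i.d. substitutions (uniform replacement) and
#' deletions recorded as gaps, so alignment columns coincide with query
#' positions. The per-residue label track is attached to the aligned columns
#' and thus conserved across the family (up to the optional label-flip
#' noise). A [synthetic_provider()] built from the family's signal table
#' embeds any of its rows.
#'
#' @param config A [family_sim_config()].
#' @param family_id Identifier prefix for the family's records.
#' @return Object of class `synthetic_family`: `query` (labelled
#'   [protein_record()]), `msa`, `labels`, `records` (per-row labelled
#'   records), `provider` and `config`.
#' @export
simulate_family <- function(config, family_id = "fam1") {
  stopifnot(inherits(config, "family_sim_config"))
  seed <- mix_seed(config$seed, hash_string(family_id))
  labels <- simulate_labels(config, seed = seed)
  with_seed(mix_seed(seed, 202L), {
    qseq <- paste(sample(AA20, config$L, replace = TRUE), collapse = "")
    qid <- paste0(family_id, "_q")
    rows <- setNames(qseq, qid)
    records <- list()
    records[[qid]] <- protein_record(qid, qseq, labels = labels)
    if (config$N > 0) {
      qchars <- strsplit(qseq, "")[[1]]
      for (j in seq_len(config$N)) {
        hc <- qchars
        sub <- stats::runif(config$L) < config$sub_rate
        hc[sub] <- sample(AA20, sum(sub), replace = TRUE)
        del <- stats::runif(config$L) < config$indel_rate
        hc[del] <- "-"
        if (all(hc == "-")) hc[1] <- qchars[1]  # keep the row embeddable
        hid <- paste0(family_id, "_h", j)
        rows[[hid]] <- paste(hc, collapse = "")
        hl <- labels[!del]
        if (config$label_flip_rate > 0) {
          flip <- stats::runif(length(hl)) < config$label_flip_rate
          hl[flip] <- sample(config$classes, sum(flip), replace = TRUE)
        }
        records[[hid]] <- protein_record(hid, paste(hc[!del], collapse = ""),
                                         labels = hl)
      }
    }
    al <- msa(rows, qid)
    provider <- synthetic_provider(config$mu, config$sigma,
                                   seed = mix_seed(seed, 303L))
    structure(list(query = records[[qid]], msa = al, labels = labels,
                   records = records, provider = provider, config = config,
                   family_id = family_id),
              class = "synthetic_family")
  })
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat("<synthetic_family> ", x$family_id, ": L = ", x$config$L, ", ",
      length(x$records) - 1L, " homologs, sigma = ", x$config$sigma, "\n",
      sep = "")
  invisible(x)
}

#' Simulate a segment-prediction task with controlled jitter
#'
#' Builds per-protein observed tracks containing transmembrane-like segments
#' of one type and prediction tracks whose segment endpoints are shifted by a
#' per-protein jitter, so the exact expected per-segment score under the
#' matching rule can be computed by direct counting.
#'
#' @param n_proteins Number of proteins.
#' @param L Track length.
#' @param n_segments Observed segments per protein.
#' @param jitter Integer endpoint shift applied to every predicted segment
#'   (both endpoints moved `jitter` residues towards the C-terminus), either
#'   a scalar or one value per protein.
#' @param type Segment label; background is `"O"`.
#' @param seg_len Length of each observed segment.
#' @param seed Integer seed for segment placement.
#' @return List with `obs` and `pred`, both named lists of label tracks, and
#'   `jitter` as used per protein.
#' @export
simulate_segment_task <- function(n_proteins = 10L, L = 120L, n_segments = 3L,
                                  jitter = 0L, type = "M", seg_len = 18L,
                                  seed = 1L) {
  stopifnot(n_proteins >= 1, n_segments >= 1, seg_len >= 1)
  jitter <- rep_len(as.integer(jitter), n_proteins)
  slot <- L %/% n_segments
  stopifnot(slot >= seg_len + 2L)
  with_seed(mix_seed(seed, 404L), {
    obs <- list()
    pred <- list()
    for (i in seq_len(n_proteins)) {
      track <- rep("O", L)
      ptrack <- rep("O", L)
      for (s in seq_len(n_segments)) {
        lo <- (s - 1L) * slot + 1L
        start <- lo + sample.int(slot - seg_len - 1L, 1L)
        end <- start + seg_len - 1L
        track[start:end] <- type
        ps <- min(max(1L, start + jitter[i]), L)
        pe <- min(max(1L, end + jitter[i]), L)
        ptrack[ps:pe] <- type
      }
      id <- paste0("p", i)
      obs[[id]] <- track
      pred[[id]] <- ptrack
    }
    list(obs = obs, pred = pred, jitter = jitter)
  })
}
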
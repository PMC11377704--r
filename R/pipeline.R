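# End-to-end pipeline: simulate -> (features per workflow) -> train ->
# predict -> evaluate, with a JSON summary.

#' Run the synthetic end-to-end pipeline
#'
#' Simulates a family benchmark, builds the input features of the requested
#' workflows, trains one predictor per workflow (identical architecture, so
#' performance differences are attributable to the inputs), predicts the
#' held-out test queries and reports per-chain Q3. Deterministic given the
#' configuration.
#'
#' @param config Either a list or a path to a YAML file with entries:
#'   `workflows` (subset of `raw`, `msa-emb`, `msacons`, `pssm-concat`,
#'   `pssm-split`), `n_train`, `n_val`, `n_test`, `family` (arguments for
#'   [family_sim_config()]), `model` (overrides for [cnn_config()]:
#'   `kernel_size`, `max_epochs`, `patience`, `lr`), `seed`, and optional
#'   `out_dir` for artifacts.
#' @return List of class `pipeline_result`: per-workflow
#'   [aggregate_per_chain()] reports of test Q3, the trained models, the
#'   configuration, and the path of the JSON summary if written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  workflows <- config$workflows %||% c("raw", "msa-emb")
  known <- c("raw", "msa-emb", "msacons", "pssm-concat", "pssm-split")
  bad <- setdiff(workflows, known)
  if (length(bad)) stop("unknown workflow(s): ", paste(bad, collapse = ", "))
  seed <- config$seed %||% 1L
  fam_args <- config$family %||% list()
  fam_args$seed <- fam_args$seed %||% seed
  fam <- do.call(family_sim_config, fam_args)
  bench <- simulate_benchmark(config$n_train %||% 40L, config$n_val %||% 10L,
                              config$n_test %||% 10L, fam,
                              dir = config$out_dir)

  model_over <- config$model %||% list()
  base_cfg <- function(variant) {
    cnn_config(variant = variant,
               input_width = fam$D, pssm_width = 20L,
               n_classes = length(fam$classes), classes = fam$classes,
               kernel_size = model_over$kernel_size %||% 7L,
               lr = model_over$lr %||% 1e-3,
               max_epochs = model_over$max_epochs %||% 200L,
               patience = model_over$patience %||% 10L,
               seed = mix_seed(seed, 7L))
  }

  feature_sets <- pipeline_features(bench, workflows)
  lab <- lapply(list(train = "train", val = "val", test = "test"), function(s) {
    y <- lapply(bench[[s]], `[[`, "labels")
    names(y) <- vapply(bench[[s]], function(f) f$query$id, "")
    y
  })

  results <- list()
  models <- list()
  for (wf in workflows) {
    variant <- switch(wf, "pssm-concat" = "concat", "pssm-split" = "split",
                      "base")
    cfg <- base_cfg(variant)
    fs <- feature_sets[[wf]]
    model <- residue_cnn(fs$train, lab$train,
                         val_x = if (length(fs$val)) fs$val else NULL,
                         val_y = if (length(fs$val)) lab$val else NULL,
                         config = cfg)
    models[[wf]] <- model
    pred <- if (wf == "msacons") {
      lapply(bench$test, function(f) {
        track <- predict_msacons(f$query, f$msa,
                                 cnn_predictor(model, f$provider),
                                 records = f$records)
        track_labels(track, cfg$classes)
      })
    } else {
      predict(model, fs$test, type = "class")
    }
    names(pred) <- names(lab$test)
    per_chain <- vapply(names(pred), function(id) q3(pred[[id]], lab$test[[id]]),
                        1.0)
    results[[wf]] <- aggregate_per_chain(per_chain)
  }

  summary <- list(seed = seed, workflows = workflows,
                  q3 = lapply(results, function(r)
                    list(mean = r$mean, sd = r$sd, se = r$se, n = r$n)))
  json_path <- NULL
  if (!is.null(config$out_dir)) {
    json_path <- file.path(config$out_dir, "summary.json")
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  structure(list(reports = results, models = models, config = config,
                 summary = summary, summary_path = json_path),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> test Q3 per workflow:\n")
  for (wf in names(x$reports)) {
    r <- x$reports[[wf]]
    cat(sprintf("  %-12s %6.2f", wf, r$mean))
    if (!is.na(r$se)) cat(sprintf(" +/- %.2f (SE, n = %d)", r$se, r$n))
    cat("\n")
  }
  invisible(x)
}

# Build the model-input features of each workflow for every split.
# msacons trains on raw features (the original method is applied per row).
#' @noRd
pipeline_features <- function(bench, workflows) {
  out <- list()
  need_raw <- any(workflows %in% c("raw", "msacons", "pssm-concat", "pssm-split"))
  raw <- msaemb <- concat <- split_f <- list()
  for (s in c("train", "val", "test")) {
    fams <- bench[[s]]
    ids <- vapply(fams, function(f) f$query$id, "")
    if (need_raw) {
      raw[[s]] <- setNames(lapply(fams, function(f)
        embed_record(f$provider, f$query)), ids)
    }
    if ("msa-emb" %in% workflows) {
      msaemb[[s]] <- setNames(lapply(fams, function(f)
        msa_average_embeddings(f$msa, f$provider, records = f$records)), ids)
    }
    if (any(workflows %in% c("pssm-concat", "pssm-split"))) {
      pssms <- setNames(lapply(fams, function(f)
        pssm_features(compute_pssm(f$msa))), ids)
      if ("pssm-concat" %in% workflows)
        concat[[s]] <- setNames(Map(cbind, raw[[s]], pssms), ids)
      if ("pssm-split" %in% workflows)
        split_f[[s]] <- setNames(Map(function(e, p) list(emb = e, pssm = p),
                                     raw[[s]], pssms), ids)
    }
  }
  for (wf in workflows) {
    out[[wf]] <- switch(wf,
      raw = raw, msacons = raw, "msa-emb" = msaemb,
      "pssm-concat" = concat, "pssm-split" = split_f)
  }
  out
}
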
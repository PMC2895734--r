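#' End-to-end study orchestration
#'
#' Three stage functions reproduce the study design on synthetic data and
#' write their outputs (standoff corpora, agreement statistics, consensus
#' sets, cross-validation reports) to disk with full provenance: every
#' output directory contains the resolved configuration and seeds needed to
#' regenerate byte-identical results.  A thin command-line wrapper around
#' these functions ships in `inst/cli/phigold.R`.
#'
#' @param cfg an [experiment_config()].
#' @return Each stage returns its main in-memory result invisibly and
#'   writes files under `cfg$out_dir`.
#' @name pipeline
NULL

#' Experiment configuration
#'
#' @param synth a [synth_config()].
#' @param models list of [annotator_error_model()]s.
#' @param policy a [resolution_policy()].
#' @param rules a [guideline_ruleset()].
#' @param schemes character vector of registered scheme names to evaluate.
#' @param k folds for cross-validation (vector allowed, e.g. `c(4, 10)`).
#' @param features a [feature_config()].
#' @param c2,maxit CRF training controls.
#' @param seed master seed (fold shuffles; generator/annotator seeds live
#'   in their own configs).
#' @param out_dir output directory.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(synth = synth_config(),
                              models = default_error_models(synth$seed),
                              policy = resolution_policy(),
                              rules = guideline_ruleset(),
                              schemes = "manual_gs",
                              k = 4L,
                              features = feature_config(),
                              c2 = 1.0, maxit = 100L,
                              seed = 1L,
                              out_dir = tempfile("phigold_run_")) {
  structure(list(synth = synth, models = models, policy = policy,
                 rules = rules, schemes = schemes, k = k,
                 features = features, c2 = c2, maxit = maxit,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

write_provenance <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(
    seed = cfg$seed,
    synth = cfg$synth[c("n_documents", "tokens_per_doc", "phi_per_doc",
                        "weekday_rate", "distractor_rate", "seed")],
    class_frequencies = as.list(cfg$synth$class_frequencies),
    models = lapply(cfg$models, function(m)
      m[c("miss_rate", "boundary_jitter", "spurious_rate", "seed")]),
    schemes = cfg$schemes, k = cfg$k, c2 = cfg$c2, maxit = cfg$maxit,
    char_ngram_max = cfg$features$char_ngram_max)
  yaml::write_yaml(prov, file.path(dir, "config.yaml"))
}

#' @describeIn pipeline Generate the synthetic corpus and annotator sets;
#'   writes `.txt`/`.ann` pairs, a class histogram, and the config echo.
#' @export
run_generate <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  study <- build_annotation_study(cfg$synth, cfg$models)
  write_provenance(cfg, cfg$out_dir)
  corpus_dir <- file.path(cfg$out_dir, "corpus")
  write_corpus_files(study$corpus, corpus_dir,
                     c(list(gold = study$gold), study$sets))
  hist <- sort(table(study$gold$label), decreasing = TRUE)
  utils::write.csv(data.frame(label = names(hist),
                              count = as.integer(hist)),
                   file.path(cfg$out_dir, "class_histogram.csv"),
                   row.names = FALSE)
  invisible(study)
}

#' @param study an [annotation_study()] (regenerated from `cfg` when
#'   omitted).
#' @param mode `"auto"` for the automatic consensus, `"manual"` for the
#'   guideline-rule consensus applied on top of it.
#' @describeIn pipeline Build a consensus set; writes standoff output, the
#'   per-cluster audit (auto) or change log (manual), and agreement
#'   statistics.
#' @export
run_consensus <- function(cfg, study = NULL, mode = c("auto", "manual")) {
  mode <- match.arg(mode)
  if (is.null(study)) study <- build_annotation_study(cfg$synth, cfg$models)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in c("exact", "partial"))
    write_agreement_csv(pairwise_matrix(study, m),
                        file.path(cfg$out_dir, paste0("iaa_", m, ".csv")))
  write_agreement_csv(agreement_table(study),
                      file.path(cfg$out_dir, "agreement_table.csv"))
  cons <- build_automatic_consensus(study, cfg$policy)
  if (mode == "manual") {
    cons <- apply_guidelines(cons, study$corpus, cfg$rules)
    log <- attr(cons, "changelog")
    utils::write.table(log, file.path(cfg$out_dir, "changelog.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    audit <- attr(cons, "audit")
    if (!is.null(audit))
      utils::write.table(audit, file.path(cfg$out_dir, "consensus_audit.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_standoff(cons, file.path(cfg$out_dir,
                                 paste0("consensus_", mode, ".ann")),
                 study$corpus)
  invisible(cons)
}

#' @param consensus the consensus [annotation_set()] to train on
#'   (regenerated when omitted).
#' @describeIn pipeline Run the cross-validation experiment series: for each
#'   scheme and each `k`, a full document-level cross-validation with
#'   per-class reports and a false-positive audit; a master summary table
#'   (scheme x k x mode x P/R/F) is written and returned.
#' @export
run_experiment <- function(cfg, study = NULL, consensus = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(study)) study <- build_annotation_study(cfg$synth, cfg$models)
  if (is.null(consensus))
    consensus <- build_automatic_consensus(study, cfg$policy)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_provenance(cfg, cfg$out_dir)
  summary_rows <- list()
  results <- list()
  for (scheme_name in cfg$schemes) {
    for (k in cfg$k) {
      cv <- cross_validate(study$corpus, consensus, k = k,
                           scheme = scheme_name, features = cfg$features,
                           c2 = cfg$c2, maxit = cfg$maxit, seed = cfg$seed)
      tag <- paste0(scheme_name, "_k", k)
      results[[tag]] <- cv
      write_eval_report(cv$aggregate,
                        file.path(cfg$out_dir, paste0("report_", tag, ".tsv")))
      if (requireNamespace("jsonlite", quietly = TRUE))
        write_eval_report(cv$aggregate,
                          file.path(cfg$out_dir, paste0("report_", tag, ".json")))
      gold_mapped <- apply_scheme(consensus, scheme_name)
      audit <- fp_audit(gold_mapped, cv$predictions, study$corpus)
      utils::write.table(audit,
                         file.path(cfg$out_dir, paste0("fp_audit_", tag, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      agg <- as.data.frame(cv$aggregate)
      mi <- agg[agg$label == "micro", ]
      summary_rows[[tag]] <- data.frame(
        scheme = scheme_name, k = k, mode = mi$mode,
        precision = mi$precision, recall = mi$recall, f = mi$f,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, c(summary_rows, list(NULL)))
  rownames(summary) <- NULL
  utils::write.table(summary, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(summary = summary, results = results))
}
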
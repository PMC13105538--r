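## End-to-end orchestration: ingest -> de-dup -> cohorts -> four-method
## scan -> atlas -> shared-PT -> similarity/backbone/MDS, with a
## machine-readable manifest and fully seeded determinism.

#' Pipeline run configuration
#'
#' Exactly one of `input` (paths to FAERS-dialect files or a directory
#' holding them) or `synth` (a [synth_config()]; the corpus is generated
#' under the run directory) must be given. Thresholds, the chi-square
#' correction, backbone percentiles and top-k values default to the
#' package's standard analysis settings.
#'
#' @param input character paths, or `NULL`.
#' @param synth a [synth_config()], or `NULL`.
#' @param dict a [drug_dictionary()].
#' @param indications an [indication_terms()] set.
#' @param require_indication filter cohorts on indication?
#' @param background_scope `"all"` (the whole de-duplicated corpus forms
#'   the comparator) or `"indication"` (restrict the universe to reports
#'   carrying a qualifying indication on any drug).
#' @param thresholds a [signal_thresholds()].
#' @param chi2_correction `"yates"` or `"pearson"`.
#' @param bcpnn_method `"posterior"` or `"two_sigma"`.
#' @param pt_soc_map path to a PT-SOC mapping file; defaults to the mock
#'   map emitted with a synthetic corpus.
#' @param percentiles backbone percentiles (first entry is the primary
#'   backbone, the rest sensitivity settings).
#' @param top_k_count,top_k_ebgm ranking depths (by report count / by
#'   EBGM).
#' @param out_dir run directory.
#' @param seed integer seed governing all randomness of the run.
#' @return a validated `run_config` list.
#' @export
run_config <- function(input = NULL, synth = NULL,
                       dict = default_drug_dictionary(),
                       indications = default_indication_terms(),
                       require_indication = FALSE,
                       background_scope = c("all", "indication"),
                       thresholds = signal_thresholds(),
                       chi2_correction = "yates",
                       bcpnn_method = "posterior",
                       pt_soc_map = NULL,
                       percentiles = c(80, 70, 90),
                       top_k_count = 10L, top_k_ebgm = 5L,
                       out_dir, seed = 1L) {
  background_scope <- match.arg(background_scope)
  if (is.null(input) == is.null(synth)) {
    stop("give exactly one of `input` or `synth`", call. = FALSE)
  }
  if (!is.null(input)) {
    bad <- input[!file.exists(input)]
    if (length(bad)) {
      stop("input path(s) not found: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(pt_soc_map)) {
      stop("pt_soc_map is required when reading an external corpus",
           call. = FALSE)
    }
  }
  if (!is.null(pt_soc_map) && !file.exists(pt_soc_map)) {
    stop("pt_soc_map file not found: ", pt_soc_map, call. = FALSE)
  }
  if (!inherits(dict, "drug_dictionary")) {
    stop("`dict` must be a drug_dictionary", call. = FALSE)
  }
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie in (0, 100)", call. = FALSE)
  }
  if (top_k_count < 1 || top_k_ebgm < 1) {
    stop("top-k values must be >= 1", call. = FALSE)
  }
  structure(list(input = input, synth = synth, dict = dict,
                 indications = indications,
                 require_indication = require_indication,
                 background_scope = background_scope,
                 thresholds = thresholds,
                 chi2_correction = chi2_correction,
                 bcpnn_method = bcpnn_method, pt_soc_map = pt_soc_map,
                 percentiles = percentiles,
                 top_k_count = as.integer(top_k_count),
                 top_k_ebgm = as.integer(top_k_ebgm),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

.tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
}

#' Run the full pipeline
#'
#' Executes ingest, de-duplication, cohort construction, the four-method
#' disproportionality scan with concordance calling, ranking, the
#' drug-SOC-PT atlas, the shared-PT analysis, and the Jaccard
#' similarity/backbone/MDS stage, writing every interface table plus a
#' `manifest.json` (resolved settings, seed, per-stage row counts and
#' drop attribution) under the run directory. Reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory stage results: `store`,
#'   `cohorts`, `scores`, `signal_matrix`, `atlas`, `shared`,
#'   `similarity`, `backbones`, `mds`, `evaluation` (synthetic runs only)
#'   and `dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  corpus <- NULL
  if (!is.null(config$synth)) {
    corpus <- generate_corpus(config$synth, file.path(out, "corpus"))
    inputs <- unname(corpus$files)
    map_path <- if (is.null(config$pt_soc_map)) corpus$pt_soc_map else
      config$pt_soc_map
  } else {
    inputs <- config$input
    map_path <- config$pt_soc_map
  }

  store <- read_faers_tables(inputs)
  n_parsed <- nrow(store$demo)
  store <- deduplicate(store)
  n_dedup <- nrow(store$demo)
  store <- match_store_drugs(store, config$dict)
  write_store(store, file.path(out, "store"))

  universe <- store
  n_universe <- n_dedup
  if (config$background_scope == "indication") {
    terms <- unclass(config$indications)
    qual <- unique(universe$indications[
      gsub("[[:space:]]+", " ", toupper(trimws(indi_pt))) %in% terms,
      primaryid])
    keep <- universe$demo$primaryid %in% qual
    universe$demo <- universe$demo[keep]
    sub <- function(dt) dt[dt$primaryid %in% universe$demo$primaryid]
    for (nm in c("drugs", "events", "indications", "outcomes", "therapy",
                 "sources")) {
      universe[[nm]] <- sub(universe[[nm]])
    }
    n_universe <- nrow(universe$demo)
  }

  cohorts <- build_all_cohorts(
    universe, config$dict, indications = config$indications,
    require_indication = config$require_indication)
  .tsv(data.table::data.table(
    drug = names(cohorts),
    class = vapply(cohorts, function(x) x$class, character(1)),
    n = vapply(cohorts, function(x) x$n, integer(1))),
    file.path(out, "cohort_sizes.tsv"))

  desc <- data.table::rbindlist(lapply(names(cohorts), function(id) {
    s <- descriptive_summary(cohorts[[id]], universe)
    cbind(data.table::data.table(drug = id),
          rbind(s$categorical, s$binned))
  }))
  .tsv(desc, file.path(out, "descriptives.tsv"))
  yearly <- data.table::rbindlist(lapply(names(cohorts), function(id) {
    yc <- yearly_counts(cohorts[[id]], universe)
    if (nrow(yc)) cbind(data.table::data.table(drug = id), yc)
  }))
  .tsv(yearly, file.path(out, "yearly_counts.tsv"))
  missing <- data.table::rbindlist(lapply(names(cohorts), function(id) {
    cbind(data.table::data.table(drug = id),
          missingness_profile(cohorts[[id]], universe))
  }))
  .tsv(missing, file.path(out, "missingness.tsv"))

  scores <- signal_scan(universe, cohorts,
                        thresholds = config$thresholds,
                        chi2_correction = config$chi2_correction,
                        bcpnn_method = config$bcpnn_method)
  .tsv(scores, file.path(out, "signals.tsv"))
  top_count <- data.table::rbindlist(lapply(names(cohorts), function(id) {
    rank_signals(scores, by = "count", k = config$top_k_count, drug = id)
  }))
  .tsv(top_count, file.path(out, "top_signals_by_count.tsv"))
  top_ebgm <- data.table::rbindlist(lapply(names(cohorts), function(id) {
    rank_signals(scores, by = "ebgm", k = config$top_k_ebgm, drug = id)
  }))
  .tsv(top_ebgm, file.path(out, "top_signals_by_ebgm.tsv"))

  sm <- signal_matrix(scores, drugs = names(cohorts))
  map <- load_pt_soc_map(map_path)
  atlas <- build_atlas(scores, map)
  .tsv(atlas$atlas, file.path(out, "atlas.tsv"))
  jsonlite::write_json(
    split(atlas$soc_histogram[, .(soc, n_pt, total_a)],
          atlas$soc_histogram$drug),
    file.path(out, "soc_histogram.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  .tsv(atlas$concordance, file.path(out, "marker_organ_concordance.tsv"))
  shared <- shared_pt_counts(sm)
  .tsv(shared$per_pt, file.path(out, "shared_pts.tsv"))

  sim <- jaccard_matrix(sm)
  sim_dt <- data.table::as.data.table(unclass(sim), keep.rownames = "drug")
  .tsv(sim_dt, file.path(out, "similarity.tsv"))
  backbones <- lapply(config$percentiles, function(p) backbone(sim, p))
  names(backbones) <- paste0("p", config$percentiles)
  for (nm in names(backbones)) {
    bb <- backbones[[nm]]
    .tsv(bb$edges, file.path(out, paste0("backbone_", nm, ".tsv")))
    jsonlite::write_json(
      list(threshold = bb$threshold, percentile = bb$percentile,
           nodes = data.table::data.table(
             drug = bb$nodes, class = unname(bb$classes[bb$nodes])),
           edges = bb$edges),
      file.path(out, paste0("network_", nm, ".json")),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  emb <- mds_embed(sim)
  .tsv(data.table::data.table(drug = rownames(emb$points),
                              x = emb$points[, 1], y = emb$points[, 2],
                              class = unname(
                                emb$classes[rownames(emb$points)])),
       file.path(out, "mds.tsv"))

  evaluation <- NULL
  if (!is.null(corpus)) {
    evaluation <- evaluate_recovery(corpus$truth, scores)
    jsonlite::write_json(evaluation, file.path(out, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  prior <- attr(scores, "mgps_prior")
  manifest <- list(
    package = "pvatlas",
    version = as.character(utils::packageVersion("pvatlas")),
    seed = config$seed,
    settings = list(
      require_indication = config$require_indication,
      background_scope = config$background_scope,
      thresholds = unclass(config$thresholds),
      chi2_correction = config$chi2_correction,
      bcpnn_method = config$bcpnn_method,
      percentiles = config$percentiles,
      top_k_count = config$top_k_count,
      top_k_ebgm = config$top_k_ebgm,
      synthetic = !is.null(config$synth),
      synth_seed = if (!is.null(config$synth)) config$synth$seed),
    mgps_prior = prior[c("alpha1", "beta1", "alpha2", "beta2", "p",
                         "loglik", "n_pairs")],
    counts = list(
      reports_parsed = n_parsed,
      reports_after_dedup = n_dedup,
      dropped_as_duplicates = n_parsed - n_dedup,
      universe_reports = n_universe,
      dropped_by_background_scope = n_dedup - n_universe,
      cohort_sizes = lapply(cohorts, function(x) x$n),
      pairs_scanned = nrow(scores),
      key_signals = sum(scores$key),
      signal_set_sizes = as.list(signal_set_sizes(sm))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  invisible(list(store = store, cohorts = cohorts, scores = scores,
                 signal_matrix = sm, atlas = atlas, shared = shared,
                 similarity = sim, backbones = backbones, mds = emb,
                 evaluation = evaluation, truth = corpus$truth,
                 dir = out))
}
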
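#' Default end-to-end run configuration
#'
#' All tunable parameters of the pipeline in one nested list,
#' serializable losslessly to YAML. The defaults reproduce the study
#' conditions: 233 plants over seven single-seed-descent generations,
#' the three known instability events implanted as truth, ~1400 markers
#' over ten 10-Mb chromosome sets, array deletion-miscall behaviour on,
#' and 30x sequencing of event carriers.
#'
#' @param seed Master seed.
#' @return A `RunConfig` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    pedigree = list(n_founder_seeds = 6L, generations = 7L),
    genome = list(n_sets = 10L, set_length = 10e6),
    markers = list(per_set = 140L, b_high_fraction = 0.5),
    events = list(mode = "study"),   # or "random" with prob/heritable_prob
    noise = noise_params(),
    array = list(deletion_miscall = TRUE),
    caller = dosage_params(),
    cascade = list(exclude_samples = TRUE, sample_sd = 4),
    detection = list(min_run = 2L, prevalence_threshold = 0.5),
    wgs = list(enabled = TRUE, depth = 30, sites_per_set = 2000L,
               window_size = 1e6, min_sites = 20L, tolerance = 0.35)
  ), class = c("RunConfig", "list"))
}

#' Read / write a run configuration as YAML
#' @param config A `RunConfig`.
#' @param path YAML file path.
#' @return The path (writer) or a `RunConfig` (reader).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("RunConfig", "list"))
}

.build_truth <- function(pedigree, config, seed) {
  ev <- config$events
  if (identical(ev$mode, "study")) {
    spec <- default_truth_events(set_length = config$genome$set_length)
  } else if (identical(ev$mode, "random")) {
    spec <- list(prob = ev$prob %||% 0.02,
                 heritable_prob = ev$heritable_prob %||% 0.5,
                 kinds = ev$kinds,
                 min_size = ev$min_size, max_size = ev$max_size)
  } else if (is.data.frame(ev$spec)) {
    spec <- ev$spec
  } else stop("events$mode must be 'study', 'random', or give $spec")
  implant_events(pedigree, spec, seed = derive_seed(seed, "events"),
                 n_sets = config$genome$n_sets,
                 set_length = config$genome$set_length)
}

#' Run the full pipeline on a simulated cohort
#'
#' Orchestrates simulate -> call dosage -> filter cascade -> event
#' detection -> inheritance tracing -> rate, plus (optionally) the
#' sequencing branch: 30x allele depths for every plant carrying a
#' candidate event, window classification and array/sequencing
#' reconciliation. With `out_dir` set, all tabular artifacts and a
#' provenance manifest are written; identical config + seed give
#' byte-identical files.
#'
#' @param config A [default_config()]-shaped `RunConfig`.
#' @param seed Master seed (defaults to `config$seed`).
#' @param out_dir Optional output directory.
#' @return List with `pedigree`, `truth`, `signals`, `dosage`,
#'   `cascade`, `calls`, `origins`, `rate`, `pca`, and (if enabled)
#'   `wgs` (`windows` and `reconciliation` per sequenced plant).
#' @export
run_all <- function(config = default_config(), seed = config$seed,
                    out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  pedigree <- stage("pedigree", generate_pedigree(
    n_founder_seeds = config$pedigree$n_founder_seeds,
    generations = config$pedigree$generations))
  truth <- stage("events", .build_truth(pedigree, config, seed))
  map <- stage("marker_map", make_marker_map(
    n_sets = config$genome$n_sets, markers_per_set = config$markers$per_set,
    set_length = config$genome$set_length,
    b_high_fraction = config$markers$b_high_fraction, seed = seed))
  signals <- stage("simulate_array", simulate_array(
    pedigree, truth, map, noise = config$noise, seed = seed,
    deletion_miscall = isTRUE(config$array$deletion_miscall)))
  dosage <- stage("call_dosage", call_dosage(signals, config$caller))
  casc <- stage("filter_cascade", run_cascade(
    dosage, map, exclude_samples = isTRUE(config$cascade$exclude_samples),
    sample_sd = config$cascade$sample_sd))
  drafts <- stage("call_runs", call_runs(
    casc$dosage, casc$marker_map, min_run = config$detection$min_run))
  classified <- stage("classify_background", classify_background(
    drafts, prevalence_threshold = config$detection$prevalence_threshold))
  traced <- stage("trace_inheritance", trace_inheritance(classified, pedigree))
  n_assayed <- attr(drafts, "n_plants")
  rate <- stage("rate", compute_rate(nrow(traced$origins), n_assayed))
  pca <- stage("pca", genotype_pca(casc$dosage))

  wgs <- NULL
  if (isTRUE(config$wgs$enabled)) {
    wgs <- stage("wgs", {
      seq_plants <- unique(traced$calls$plant[
        traced$calls$status %in% c("novel", "inherited")])
      if (length(seq_plants) > 0) {
        sites <- make_diagnostic_sites(
          n_sets = config$genome$n_sets,
          sites_per_set = config$wgs$sites_per_set,
          set_length = config$genome$set_length, seed = seed)
        counts <- simulate_wgs(seq_plants, truth, sites,
                               depth = config$wgs$depth, seed = seed)
        baseline <- counts[counts$sample == "synthetic_tetraploid", ]
        per_plant <- lapply(seq_plants, function(pl) {
          norm <- normalize_counts(counts[counts$sample == pl, ], baseline)
          win <- window_classify(norm, window_size = config$wgs$window_size,
                                 min_sites = config$wgs$min_sites,
                                 tolerance = config$wgs$tolerance)
          rec <- reconcile(traced$calls[traced$calls$status != "background", ,
                                        drop = FALSE], win, plant = pl)
          list(windows = win, reconciliation = rec)
        })
        names(per_plant) <- seq_plants
        per_plant
      } else list()
    })
  }

  result <- list(pedigree = pedigree, truth = truth, signals = signals,
                 dosage = dosage, cascade = casc, calls = traced$calls,
                 origins = traced$origins, rate = rate, pca = pca, wgs = wgs,
                 config = config, seed = seed)
  if (!is.null(out_dir)) .write_run(result, out_dir)
  result
}

.write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_config(result$config, fp("config.yaml"))
  write_pedigree_tsv(result$pedigree, fp("pedigree.tsv"))
  .write_tsv(result$truth$events, fp("truth_events.tsv"))
  write_dosage_tsv(result$cascade$dosage, fp("dosage_filtered.tsv"))
  .write_tsv(result$cascade$report, fp("filter_report.tsv"))
  .write_tsv(result$calls, fp("event_calls.tsv"))
  .write_tsv(result$origins, fp("origins.tsv"))
  .write_tsv(composition_matrix(result$cascade$dosage),
             fp("composition_matrix.tsv"))
  .write_tsv(result$pca$coordinates, fp("pca_coordinates.tsv"))
  if (!is.null(result$wgs) && length(result$wgs) > 0) {
    recs <- do.call(rbind, lapply(result$wgs, `[[`, "reconciliation"))
    .write_tsv(recs, fp("wgs_reconciliation.tsv"))
  }
  manifest <- list(
    package = "homeoscan",
    version = as.character(utils::packageVersion("homeoscan")),
    seed = result$seed,
    config_md5 = unname(tools::md5sum(fp("config.yaml"))),
    rate_percent = result$rate$rate_percent,
    n_origins = result$rate$n_events,
    n_plants = result$rate$n_plants,
    files = list.files(out_dir)
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Compare detected origins against a truth ledger
#'
#' A truth event is recovered if some detected origin lies on the same
#' chromosome set, overlaps its interval, has a compatible composition
#' (a hemizygous B-loss may surface as `DELETION_CANDIDATE`, or as an
#' AAAB/AAAA run under the array's miscall behaviour), and originates at
#' the truth plant or one of its descendants. Detected origins matching
#' no truth event are false origins.
#'
#' @param origins `origins` from [trace_inheritance()] / [run_all()].
#' @param truth An [implant_events()] result.
#' @param pedigree The matching pedigree.
#' @return List with `per_event` (truth ledger with `detected` and
#'   `exact_plant` flags), `sensitivity`, `n_false`.
#' @export
compare_origins <- function(origins, truth, pedigree) {
  compat <- list(
    DELETION_B = c("DELETION_B", "DELETION_CANDIDATE", "AAAB", "AAAA"),
    DELETION_A = c("DELETION_A", "DELETION_CANDIDATE", "ABBB", "BBBB"),
    ABBB = "ABBB", AAAB = "AAAB", AAAA = "AAAA", BBBB = "BBBB",
    TRISOMY_A = "TRISOMY_A", TRISOMY_B = "TRISOMY_B"
  )
  ev <- truth$events
  matched_origin <- rep(FALSE, nrow(origins))
  detected <- logical(nrow(ev))
  exact <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    fam <- c(ev$plant[i],
             if (ev$plant[i] %in% pedigree$label)
               pedigree_descendants(pedigree, ev$plant[i]))
    hit <- origins$chrom_set == ev$chrom_set[i] &
      .overlaps(origins$start, origins$end, ev$start[i], ev$end[i]) &
      origins$composition %in% compat[[ev$kind[i]]] &
      origins$plant %in% fam
    detected[i] <- any(hit)
    exact[i] <- any(hit & origins$plant == ev$plant[i])
    matched_origin <- matched_origin | hit
  }
  per_event <- cbind(ev, detected = detected, exact_plant = exact)
  list(per_event = per_event,
       sensitivity = if (nrow(ev) > 0) mean(detected) else NA_real_,
       n_false = sum(!matched_origin))
}
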
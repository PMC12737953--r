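#' Call composition events from per-plant dosage runs
#'
#' On the A-counting scale a run of two or more consecutive markers
#' sharing the same non-euploid score is one draft event call:
#' score 0 is BBBB, 1 ABBB, 3 AAAB and 4 AAAA. Runs in which the
#' deletion-consistent low-intensity flag covers at least half the
#' markers are labelled `DELETION_CANDIDATE` instead — the array cannot
#' distinguish a hemizygous deletion from an exchange there, and
#' resolution is deferred to sequencing ([reconcile()]). The call
#' interval spans the first to one past the last marker position.
#'
#' @param dosage A filtered, oriented `DosageMatrix` (only lineage
#'   samples are scanned).
#' @param marker_map Map rows matching the matrix markers (same order),
#'   positions strictly increasing within chromosome sets.
#' @param min_run Minimum markers per run (default 2, the
#'   consecutive-marker rule).
#' @return Data frame of draft calls: `plant`, `chrom_set`, `start`,
#'   `end`, `composition`, `array_composition` (the score-implied label,
#'   kept alongside a `DELETION_CANDIDATE`), `n_markers`,
#'   `low_intensity_fraction`.
#' @export
call_runs <- function(dosage, marker_map = dosage$markers, min_run = 2) {
  stopifnot(min_run >= 2, nrow(marker_map) == nrow(dosage$score))
  for (cs in unique(marker_map$chrom_set)) {
    p <- marker_map$position[marker_map$chrom_set == cs]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker map positions not strictly increasing in set ", cs)
  }
  lin <- .lineage_cols(dosage)
  calls <- list()
  for (j in lin) {
    plant <- dosage$samples$plant[j]
    for (cs in unique(marker_map$chrom_set)) {
      idx <- which(marker_map$chrom_set == cs)
      sc <- dosage$score[idx, j]
      sc_key <- ifelse(is.na(sc), -1L, sc)
      r <- rle(sc_key)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values %in% c(0L, 1L, 3L, 4L) & r$lengths >= min_run)
      for (h in hit) {
        ii <- idx[starts[h]:ends[h]]
        low_frac <- mean(dosage$low_intensity[ii, j])
        comp <- score_to_composition(r$values[h])
        calls[[length(calls) + 1L]] <- data.frame(
          plant = plant, chrom_set = cs,
          start = marker_map$position[ii[1L]],
          end = marker_map$position[ii[length(ii)]] + 1,
          composition = if (low_frac >= 0.5) "DELETION_CANDIDATE" else comp,
          array_composition = comp,
          n_markers = length(ii), low_intensity_fraction = low_frac,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(calls) > 0) do.call(rbind, calls) else
    data.frame(plant = character(0), chrom_set = integer(0),
               start = numeric(0), end = numeric(0),
               composition = character(0), array_composition = character(0),
               n_markers = integer(0), low_intensity_fraction = numeric(0),
               stringsAsFactors = FALSE)
  attr(out, "n_plants") <- length(unique(dosage$samples$plant[lin]))
  out
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Separate cohort-wide background compositions from novel candidates
#'
#' Reference lines of segmental allotetraploids already carry unbalanced
#' compositions at some chromosome terminals; these appear in (nearly)
#' every plant and must not count as new instability. A call is
#' background if an overlapping call of the same composition on the same
#' chromosome set is present in more than `prevalence_threshold` of
#' assayed plants, or (in reference mode) overlaps the supplied
#' reference profile; otherwise it is a candidate.
#'
#' @param calls Draft calls from [call_runs()].
#' @param prevalence_threshold Fraction of plants above which a
#'   composition is background (default 0.5).
#' @param reference Optional data frame (`chrom_set`, `start`, `end`,
#'   `composition`) describing the reference line's known compositions;
#'   when given it replaces the prevalence rule.
#' @param n_plants Number of plants assayed (defaults to the attribute
#'   set by [call_runs()]).
#' @return The calls with a `status` column (`"background"` or
#'   `"candidate"`).
#' @export
classify_background <- function(calls, prevalence_threshold = 0.5,
                                reference = NULL,
                                n_plants = attr(calls, "n_plants")) {
  if (nrow(calls) == 0) {
    calls$status <- character(0)
    return(calls)
  }
  status <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (!is.null(reference)) {
      hit <- reference$chrom_set == calls$chrom_set[i] &
        reference$composition == calls$composition[i] &
        .overlaps(reference$start, reference$end, calls$start[i], calls$end[i])
      status[i] <- if (any(hit)) "background" else "candidate"
    } else {
      stopifnot(!is.null(n_plants), n_plants >= 1)
      same <- calls$chrom_set == calls$chrom_set[i] &
        calls$composition == calls$composition[i] &
        .overlaps(calls$start, calls$end, calls$start[i], calls$end[i])
      prev <- length(unique(calls$plant[same])) / n_plants
      status[i] <- if (prev > prevalence_threshold) "background" else "candidate"
    }
  }
  calls$status <- status
  calls
}

#' Trace candidate events through the pedigree and count origins
#'
#' A candidate call whose parent plant carries an overlapping call of the
#' same composition on the same chromosome set is `inherited`; otherwise
#' it is `novel` and counts as one independent origin, however many
#' descendants later carry it. Transient events (present in one plant,
#' absent from its progeny) are single origins by the same rule.
#'
#' @param candidates Calls with status `"candidate"` (background rows are
#'   passed through untouched).
#' @param pedigree A [generate_pedigree()] result covering every plant
#'   with a candidate call.
#' @return List with `calls` (status refined to
#'   `background`/`novel`/`inherited` and an `origin_id` column) and
#'   `origins` (one row per independent origin: `origin_id`, `plant`,
#'   `chrom_set`, `start`, `end`, `composition`, `origin_generation`,
#'   `n_carriers`, `transient`).
#' @export
trace_inheritance <- function(candidates, pedigree) {
  calls <- candidates
  calls$origin_id <- NA_character_
  cand <- which(calls$status == "candidate")
  if (length(cand) > 0) {
    missing <- setdiff(calls$plant[cand], pedigree$label)
    if (length(missing) > 0)
      stop("plant(s) not in pedigree: ", paste(missing, collapse = ", "))
  }
  gen <- pedigree$generation[match(calls$plant, pedigree$label)]
  parent <- pedigree$parent_label[match(calls$plant, pedigree$label)]
  n_origin <- 0L
  for (i in cand[order(gen[cand])]) {
    par <- parent[i]
    par_calls <- which(calls$plant %in% par &
                         calls$chrom_set == calls$chrom_set[i] &
                         calls$composition == calls$composition[i] &
                         .overlaps(calls$start, calls$end,
                                   calls$start[i], calls$end[i]) &
                         calls$status %in% c("novel", "inherited"))
    if (length(par_calls) > 0) {
      calls$status[i] <- "inherited"
      calls$origin_id[i] <- calls$origin_id[par_calls[1L]]
    } else {
      n_origin <- n_origin + 1L
      calls$status[i] <- "novel"
      calls$origin_id[i] <- paste0("origin", n_origin)
    }
  }
  novel <- which(calls$status == "novel")
  origins <- do.call(rbind, lapply(novel, function(i) {
    carriers <- sum(calls$origin_id == calls$origin_id[i], na.rm = TRUE)
    kids <- pedigree$label[pedigree$parent_label %in% calls$plant[i]]
    kid_has <- any(calls$plant %in% kids &
                     calls$origin_id == calls$origin_id[i], na.rm = TRUE)
    data.frame(origin_id = calls$origin_id[i], plant = calls$plant[i],
               chrom_set = calls$chrom_set[i], start = calls$start[i],
               end = calls$end[i], composition = calls$composition[i],
               origin_generation = gen[i], n_carriers = carriers,
               transient = length(kids) > 0 && !kid_has,
               stringsAsFactors = FALSE)
  }))
  if (is.null(origins))
    origins <- data.frame(origin_id = character(0), plant = character(0),
                          chrom_set = integer(0), start = numeric(0),
                          end = numeric(0), composition = character(0),
                          origin_generation = integer(0),
                          n_carriers = integer(0), transient = logical(0),
                          stringsAsFactors = FALSE)
  list(calls = calls, origins = origins)
}

#' Instability rate from independent origins and plants assayed
#'
#' The rate is `100 * n_origins / n_plants`, rounded half away from zero
#' to one decimal — e.g. 3 origins among 233 plants is 1.3%.
#'
#' @param n_origins Number of independent novel origins.
#' @param n_plants Number of plants assayed (> 0).
#' @return A list of class `"RateSummary"` with `n_events`, `n_plants`,
#'   `rate_percent`.
#' @export
compute_rate <- function(n_origins, n_plants) {
  stopifnot(n_origins >= 0)
  if (length(n_plants) != 1 || !is.finite(n_plants) || n_plants <= 0)
    stop("n_plants must be a positive number")
  structure(list(n_events = n_origins, n_plants = n_plants,
                 rate_percent = round_half_away(100 * n_origins / n_plants, 1)),
            class = "RateSummary")
}

#' @export
print.RateSummary <- function(x, ...) {
  cat(sprintf("%d independent origin(s) among %d plants: %.1f%%\n",
              x$n_events, x$n_plants, x$rate_percent))
  invisible(x)
}

#' Cohort size after sample exclusions
#'
#' Bookkeeping for the analyzed-cohort denominator: genotyped plants
#' minus platform-QC failures minus samples excluded for excess
#' non-modal scores (e.g. 233 - 2 - 4 = 227).
#'
#' @param n_genotyped Plants genotyped.
#' @param n_excluded Integer vector of exclusion counts.
#' @return Number of plants entering the analysis.
#' @export
analyzed_cohort <- function(n_genotyped, n_excluded = integer(0)) {
  stopifnot(n_genotyped >= 0, all(n_excluded >= 0))
  out <- n_genotyped - sum(n_excluded)
  if (out < 0) stop("exclusions exceed the genotyped cohort")
  out
}
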
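#' Modal (most frequent) dosage score with euploid tie-breaking
#'
#' Ties break toward the euploid score 2: if 2 is among the tied modes it
#' wins, otherwise the tied mode closest to 2 (and below 2 on a further
#' tie) is taken — conservative toward the euploid null.
#'
#' @param x Integer scores (NAs ignored).
#' @return The modal score, or `NA` if all values are missing.
#' @export
modal_score <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_integer_)
  counts <- tabulate(x + 1L, nbins = 5L)
  top <- which(counts == max(counts)) - 1L
  if (2L %in% top) return(2L)
  top[order(abs(top - 2L), top)][1L]
}

.lineage_cols <- function(dosage) which(dosage$samples$role == "lineage")

.role_cols <- function(dosage, role) which(dosage$samples$role == role)

#' Keep markers completely scored across all lineage samples
#'
#' @param dosage A [call_dosage()]-shaped `DosageMatrix`.
#' @return Named logical vector over markers (TRUE = retained).
#' @export
filter_complete <- function(dosage) {
  lin <- .lineage_cols(dosage)
  if (length(lin) == 0) stop("no lineage samples declared")
  keep <- rowSums(is.na(dosage$score[, lin, drop = FALSE])) == 0
  stats::setNames(keep, rownames(dosage$score))
}

#' Keep markers whose control samples behave as their mixtures demand
#'
#' A marker is retained only if (i) each control group (A ancestor,
#' B ancestor, 1:1, 3:1 and 1:3 A:B mixtures) scores uniformly, (ii) the
#' A- and B-ancestor scores differ by at least 2 (e.g. 3 vs 1), (iii) the
#' 3:1 and 1:3 mixtures score differently, and (iv) the 1:1 mixture has
#' modal score 2 — i.e. the marker genuinely separates subgenome dosage.
#'
#' @param dosage A `DosageMatrix` whose sample sheet declares the five
#'   control roles.
#' @return Named logical vector over markers.
#' @export
filter_controls <- function(dosage) {
  roles <- c("A_parent", "B_parent", "mix_1_1", "mix_3_1", "mix_1_3")
  cols <- lapply(roles, .role_cols, dosage = dosage)
  names(cols) <- roles
  if (any(lengths(cols) == 0))
    stop("missing control role(s): ",
         paste(roles[lengths(cols) == 0], collapse = ", "))
  sc <- dosage$score
  uniform_value <- function(v) {
    if (anyNA(v) || length(unique(v)) != 1L) NA_integer_ else v[1L]
  }
  vals <- vapply(cols, function(cc)
    apply(sc[, cc, drop = FALSE], 1, uniform_value), integer(nrow(sc)))
  vals <- matrix(vals, nrow = nrow(sc), dimnames = list(NULL, roles))
  keep <- rowSums(is.na(vals)) == 0 &
    abs(vals[, "A_parent"] - vals[, "B_parent"]) >= 2 &
    vals[, "mix_3_1"] != vals[, "mix_1_3"] &
    vals[, "mix_1_1"] == 2L
  keep[is.na(keep)] <- FALSE
  stats::setNames(keep, rownames(sc))
}

#' Keep markers on which every replicate pair agrees
#'
#' Replicate pairs are duplicate DNA extractions of the same plant
#' (declared via `replicate_of` in the sample sheet); disagreement at a
#' marker marks it as unreliably scored.
#'
#' @param dosage A `DosageMatrix` with at least one declared replicate.
#' @return Named logical vector over markers.
#' @export
filter_replicates <- function(dosage) {
  rep_idx <- which(!is.na(dosage$samples$replicate_of))
  if (length(rep_idx) == 0) stop("no replicate pairs declared")
  mate <- match(dosage$samples$replicate_of[rep_idx], dosage$samples$sample)
  if (anyNA(mate))
    stop("unpaired replicate id(s): ",
         paste(dosage$samples$replicate_of[rep_idx][is.na(mate)],
               collapse = ", "))
  keep <- rep(TRUE, nrow(dosage$score))
  for (k in seq_along(rep_idx)) {
    a <- dosage$score[, rep_idx[k]]
    b <- dosage$score[, mate[k]]
    keep <- keep & !is.na(a) & !is.na(b) & a == b
  }
  stats::setNames(keep, rownames(dosage$score))
}

#' Keep euploid-modal markers and coherent consecutive deviations
#'
#' The cohort-wide modal score of a retained marker must be 2 (euploid),
#' *unless* the marker sits in a positional run of two or more
#' consecutive markers whose modes deviate from 2 in the same direction
#' (all toward A, scores 3-4, or all toward B, scores 0-1). Isolated
#' deviating markers are almost always mis-scored probes; runs are real
#' unbalanced compositions shared across the cohort.
#'
#' @param dosage A `DosageMatrix`.
#' @param marker_map Map rows for the matrix markers (same order),
#'   positions strictly increasing within each chromosome set.
#' @return Named logical vector over markers.
#' @export
filter_modal_rule <- function(dosage, marker_map) {
  stopifnot(nrow(marker_map) == nrow(dosage$score))
  lin <- .lineage_cols(dosage)
  if (length(lin) == 0) stop("no lineage samples declared")
  for (cs in unique(marker_map$chrom_set)) {
    p <- marker_map$position[marker_map$chrom_set == cs]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker map positions not strictly increasing in set ", cs)
  }
  modal <- apply(dosage$score[, lin, drop = FALSE], 1, modal_score)
  dev <- sign(modal - 2L)        # -1 toward B, +1 toward A, 0 euploid
  keep <- dev == 0
  for (cs in unique(marker_map$chrom_set)) {
    idx <- which(marker_map$chrom_set == cs)
    d <- dev[idx]
    r <- rle(d)
    run_keep <- r$values != 0 & r$lengths >= 2
    keep[idx] <- keep[idx] | inverse.rle(list(values = run_keep,
                                              lengths = r$lengths))
  }
  keep[is.na(keep)] <- FALSE
  stats::setNames(keep, rownames(dosage$score))
}

#' Standardize all markers to count A-subgenome alleles
#'
#' Raw scores count whichever allele the probe was designed against. This
#' step flips markers whose A-ancestor control scores *below* the
#' B-ancestor control (score s becomes 4 - s), after which every score
#' counts A alleles: BBBB = 0, ABBB = 1, AABB = 2, AAAB = 3, AAAA = 4,
#' and the 3:1 mixture scores above the 1:3 mixture at every marker.
#' Markers whose two ancestor controls score equally cannot be oriented
#' and are dropped.
#'
#' @param dosage A `DosageMatrix` with control roles declared.
#' @return List with `dosage` (oriented matrix, unorientable markers
#'   removed), `retained` (logical over input markers) and `flipped`
#'   (logical over retained markers).
#' @export
standardize_orientation <- function(dosage) {
  a_cols <- .role_cols(dosage, "A_parent")
  b_cols <- .role_cols(dosage, "B_parent")
  if (length(a_cols) == 0 || length(b_cols) == 0)
    stop("missing control role(s): ancestor controls required")
  a <- apply(dosage$score[, a_cols, drop = FALSE], 1, modal_score)
  b <- apply(dosage$score[, b_cols, drop = FALSE], 1, modal_score)
  retained <- !is.na(a) & !is.na(b) & a != b
  flip <- retained & a < b
  out <- dosage_subset(dosage, markers = which(retained))
  fl <- flip[retained]
  out$score[fl, ] <- 4L - out$score[fl, , drop = FALSE]
  list(dosage = out,
       retained = stats::setNames(retained, rownames(dosage$score)),
       flipped = stats::setNames(fl, rownames(out$score)))
}

#' Subset a dosage matrix by markers and/or samples
#'
#' @param dosage A `DosageMatrix`.
#' @param markers,samples Index vectors (logical, integer or names).
#' @return The subset `DosageMatrix`.
#' @export
dosage_subset <- function(dosage, markers = NULL, samples = NULL) {
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, rownames(dosage$score))
    dosage$score <- dosage$score[markers, , drop = FALSE]
    dosage$low_intensity <- dosage$low_intensity[markers, , drop = FALSE]
    dosage$confidence <- dosage$confidence[markers, , drop = FALSE]
    dosage$markers <- dosage$markers[markers, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, colnames(dosage$score))
    dosage$score <- dosage$score[, samples, drop = FALSE]
    dosage$low_intensity <- dosage$low_intensity[, samples, drop = FALSE]
    dosage$confidence <- dosage$confidence[, samples, drop = FALSE]
    dosage$samples <- dosage$samples[samples, , drop = FALSE]
  }
  dosage
}

#' Flag samples with an excess of isolated non-modal scores
#'
#' Low-quality DNA produces scattered non-modal calls genome wide,
#' whereas real unbalanced compositions are positionally coherent runs.
#' Each lineage sample is therefore scored by its fraction of *isolated*
#' deviations — cells deviating from the euploid score 2 that are not
#' part of a same-direction run of two or more consecutive markers —
#' and samples exceeding `mean + n_sd * sd` of that fraction are flagged.
#'
#' @param dosage A `DosageMatrix`.
#' @param marker_map Map rows matching the matrix markers (same order).
#' @param n_sd Exclusion threshold in standard deviations (default 4).
#' @return Character vector of excluded sample names.
#' @export
flag_noisy_samples <- function(dosage, marker_map = dosage$markers, n_sd = 4) {
  lin <- .lineage_cols(dosage)
  if (length(lin) == 0) stop("no lineage samples declared")
  sc <- dosage$score[, lin, drop = FALSE]
  # deviation is taken orientation-blind (|score - 2| > 0): raw scores mix
  # A- and B-counting markers, so a real composition run alternates sign
  # but stays deviant, whereas mis-scored cells are positionally isolated
  iso_frac <- vapply(seq_len(ncol(sc)), function(j) {
    dev <- as.integer(sc[, j] != 2L)
    dev[is.na(dev)] <- 0L
    iso <- 0L
    for (cs in unique(marker_map$chrom_set)) {
      r <- rle(dev[marker_map$chrom_set == cs])
      iso <- iso + sum(r$lengths[r$values != 0 & r$lengths == 1L])
    }
    iso / nrow(sc)
  }, numeric(1))
  cut <- mean(iso_frac) + n_sd * stats::sd(iso_frac)
  if (is.na(cut)) return(character(0))
  dosage$samples$sample[lin][iso_frac > cut]
}

#' Run the complete marker-filter cascade
#'
#' Stages, in order: complete scoring across lineages; control-group
#' consistency; replicate concordance; euploid-modal / consecutive-run
#' rule; orientation standardization (A-allele counting). Optionally,
#' samples with an excess of non-modal scores are excluded first. The
#' cascade is idempotent and its stage counts telescope.
#'
#' @param dosage A `DosageMatrix`.
#' @param marker_map Map rows matching the matrix markers (same order).
#' @param exclude_samples Apply [flag_noisy_samples()] before marker
#'   filters (default TRUE).
#' @param sample_sd Threshold for sample exclusion.
#' @return List with `dosage` (filtered, oriented), `marker_map`
#'   (subset), `report` (`FilterReport`: stage, n_in, n_out), `dropped`
#'   (marker, stage, reason) and `excluded_samples`.
#' @export
run_cascade <- function(dosage, marker_map = dosage$markers,
                        exclude_samples = TRUE, sample_sd = 4) {
  stopifnot(nrow(marker_map) == nrow(dosage$score))
  excluded <- character(0)
  if (exclude_samples) {
    excluded <- flag_noisy_samples(dosage, marker_map, n_sd = sample_sd)
    if (length(excluded) > 0) {
      keep_s <- !dosage$samples$sample %in% excluded
      dosage <- dosage_subset(dosage, samples = which(keep_s))
    }
  }
  report <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), stringsAsFactors = FALSE)
  dropped <- data.frame(marker = character(0), stage = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  apply_stage <- function(stage, keep) {
    n_in <- nrow(dosage$score)
    drop_ids <- rownames(dosage$score)[!keep]
    if (length(drop_ids) > 0)
      dropped <<- rbind(dropped, data.frame(
        marker = drop_ids, stage = stage, reason = stage,
        stringsAsFactors = FALSE))
    dosage <<- dosage_subset(dosage, markers = which(keep))
    marker_map <<- marker_map[keep, , drop = FALSE]
    report <<- rbind(report, data.frame(
      stage = stage, n_in = n_in, n_out = nrow(dosage$score),
      stringsAsFactors = FALSE))
  }
  apply_stage("complete", filter_complete(dosage))
  apply_stage("controls", filter_controls(dosage))
  apply_stage("replicates", filter_replicates(dosage))
  apply_stage("modal_rule", filter_modal_rule(dosage, marker_map))
  ori <- standardize_orientation(dosage)
  n_in <- nrow(dosage$score)
  drop_ids <- rownames(dosage$score)[!ori$retained]
  if (length(drop_ids) > 0)
    dropped <- rbind(dropped, data.frame(
      marker = drop_ids, stage = "orientation", reason = "unorientable",
      stringsAsFactors = FALSE))
  marker_map <- marker_map[ori$retained, , drop = FALSE]
  dosage <- ori$dosage
  report <- rbind(report, data.frame(
    stage = "orientation", n_in = n_in, n_out = nrow(dosage$score),
    stringsAsFactors = FALSE))
  list(dosage = dosage, marker_map = marker_map, report = report,
       dropped = dropped, excluded_samples = excluded)
}
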
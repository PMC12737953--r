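#' Select subgenome-diagnostic variant positions
#'
#' A position is diagnostic when reads from the A-subgenome source reach
#' consensus (>= 95% by default) on one allele, reads from the
#' B-subgenome source reach consensus on a *different* allele, and both
#' sources meet a minimum depth. Only such positions allow subgenome
#' copy number to be counted from allele depths.
#'
#' @param parent_variants Data frame with columns `chrom_set`,
#'   `position`, `a_allele`, `a_support` (consensus fraction among
#'   A-source reads), `a_depth`, `b_allele`, `b_support`, `b_depth`.
#' @param consensus Minimum consensus fraction (default 0.95).
#' @param min_depth Minimum source depth (default 1).
#' @return The retained rows (possibly zero of them).
#' @export
select_sites <- function(parent_variants, consensus = 0.95, min_depth = 1) {
  keep <- parent_variants$a_support >= consensus &
    parent_variants$b_support >= consensus &
    parent_variants$a_allele != parent_variants$b_allele &
    parent_variants$a_depth >= min_depth &
    parent_variants$b_depth >= min_depth
  keep[is.na(keep)] <- FALSE
  out <- parent_variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize allele depths against the synthetic-tetraploid baseline
#'
#' Raw allele counts vary site-to-site with mappability and allele bias.
#' Dividing by the counts of the synthetic tetraploid — a 1:1 in-silico
#' A:B combination whose true copy numbers are (2, 2) everywhere —
#' cancels those site effects: `norm_a = 2 * s * raw_a / baseline_a`
#' (and likewise for B), where the per-sample scalar `s` sets the
#' genome-wide median of `(norm_a + norm_b) / 2` to the euploid value 2.
#' The scalar absorbs overall depth differences between samples, so the
#' classification is invariant to uniform depth rescaling. Sites with a
#' zero baseline count on either allele are masked.
#'
#' @param sample_counts Rows of a `ReadCountTable` for one sample.
#' @param baseline_counts Rows for the synthetic-tetraploid baseline.
#' @return Data frame with `chrom_set`, `position`, `norm_a`, `norm_b`.
#' @export
normalize_counts <- function(sample_counts, baseline_counts) {
  key_s <- paste(sample_counts$chrom_set, sample_counts$position)
  key_b <- paste(baseline_counts$chrom_set, baseline_counts$position)
  m <- match(key_s, key_b)
  shared <- !is.na(m)
  if (!any(shared)) stop("no diagnostic sites shared with the baseline")
  s_tab <- sample_counts[shared, , drop = FALSE]
  b_tab <- baseline_counts[m[shared], , drop = FALSE]
  usable <- b_tab$raw_a > 0 & b_tab$raw_b > 0
  s_tab <- s_tab[usable, , drop = FALSE]
  b_tab <- b_tab[usable, , drop = FALSE]
  u_a <- 2 * s_tab$raw_a / b_tab$raw_a
  u_b <- 2 * s_tab$raw_b / b_tab$raw_b
  med <- stats::median((u_a + u_b) / 2)
  if (!is.finite(med) || med <= 0)
    stop("cannot scale sample: degenerate genome-wide coverage")
  s <- 2 / med
  data.frame(chrom_set = s_tab$chrom_set, position = s_tab$position,
             norm_a = s * u_a, norm_b = s * u_b, stringsAsFactors = FALSE)
}

.window_targets <- function() {
  comp <- c("AABB", "ABBB", "AAAB", "AAAA", "BBBB",
            "DELETION_B", "DELETION_A", "TRISOMY_A", "TRISOMY_B")
  lab <- c("AABB", "ABBB", "AAAB", "AAAA", "BBBB",
           "AA_DELETION", "BB_DELETION", "TRISOMY_A", "TRISOMY_B")
  d <- expected_dosage(comp)
  data.frame(label = lab, a = d[, "a"], b = d[, "b"], stringsAsFactors = FALSE)
}

#' Classify genomic windows into genome compositions
#'
#' Normalized per-site copy estimates are aggregated into fixed windows
#' per chromosome set; the window's robust centre (median of `norm_a`,
#' median of `norm_b`) is matched to the nearest expected copy pair among
#' AABB (2,2), ABBB (1,3), AAAB (3,1), AAAA (4,0), BBBB (0,4), the
#' hemizygous deletions AA (2,0) and BB (0,2), and the trisomies (3,2)
#' and (2,3). The label is assigned only if both coordinates fall within
#' `tolerance` copies of the match (and at least `min_sites` sites
#' support the window); otherwise the window is `UNCLASSIFIED`.
#'
#' @param normalized A [normalize_counts()] result.
#' @param window_size Window width in base pairs (default 1 Mb).
#' @param min_sites Minimum diagnostic sites per window (default 20).
#' @param tolerance Maximum per-axis distance in copies (default 0.35).
#' @return Data frame of class `"WindowDosage"`: `chrom_set`, `start`,
#'   `end`, `n_sites`, `norm_a`, `norm_b`, `composition`.
#' @export
window_classify <- function(normalized, window_size = 1e6, min_sites = 20,
                            tolerance = 0.35) {
  if (window_size <= 0) stop("window_size must be positive")
  targets <- .window_targets()
  win <- floor(normalized$position / window_size)
  key <- interaction(normalized$chrom_set, win, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(normalized)), key), function(ii) {
    med_a <- stats::median(normalized$norm_a[ii])
    med_b <- stats::median(normalized$norm_b[ii])
    comp <- "UNCLASSIFIED"
    if (length(ii) >= min_sites) {
      d_a <- abs(targets$a - med_a)
      d_b <- abs(targets$b - med_b)
      j <- which.min(d_a^2 + d_b^2)
      if (d_a[j] <= tolerance && d_b[j] <= tolerance) comp <- targets$label[j]
    }
    data.frame(chrom_set = normalized$chrom_set[ii[1L]],
               start = floor(normalized$position[ii[1L]] / window_size) * window_size,
               n_sites = length(ii), norm_a = med_a, norm_b = med_b,
               composition = comp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom_set = integer(0), start = numeric(0),
                      n_sites = integer(0), norm_a = numeric(0),
                      norm_b = numeric(0), composition = character(0),
                      stringsAsFactors = FALSE)
  out$end <- out$start + window_size
  out <- out[order(out$chrom_set, out$start),
             c("chrom_set", "start", "end", "n_sites", "norm_a", "norm_b",
               "composition")]
  rownames(out) <- NULL
  class(out) <- c("WindowDosage", "data.frame")
  out
}

# array-call composition -> window labels that corroborate it
.array_wgs_match <- c(ABBB = "ABBB", AAAB = "AAAB", AAAA = "AAAA",
                      BBBB = "BBBB")

#' Reconcile array event calls with sequencing window classifications
#'
#' For each array event of a plant, overlapping classified windows vote
#' by majority. Agreement confirms the array call. Array calls that read
#' AAAB/AAAA (or are flagged `DELETION_CANDIDATE`) but sit over
#' AA-deletion windows are relabelled as a B-subgenome deletion — the
#' known array failure mode over hemizygous regions, where loss of the B
#' copies shifts theta toward pure A without the array registering the
#' halved copy number. The mirrored relabelling applies for A-subgenome
#' deletions.
#'
#' @param array_events Event calls (rows of a [call_runs()] /
#'   [trace_inheritance()] result) for one plant.
#' @param wgs_windows A [window_classify()] result for the same plant.
#' @param plant Plant label (used to subset `array_events` if it has a
#'   `plant` column with several plants).
#' @return Data frame with the array call columns plus
#'   `wgs_composition`, `final_call` and `agreement` (`"confirmed"`,
#'   `"relabelled"` or `"conflict"`).
#' @export
reconcile <- function(array_events, wgs_windows, plant = NULL) {
  if (!is.null(plant)) {
    if (!plant %in% array_events$plant)
      stop("plant ", plant, " absent from array calls")
    array_events <- array_events[array_events$plant == plant, , drop = FALSE]
  }
  if (nrow(wgs_windows) == 0) stop("no sequencing windows supplied")
  out <- array_events
  out$wgs_composition <- NA_character_
  out$final_call <- out$composition
  out$agreement <- "conflict"
  for (i in seq_len(nrow(out))) {
    ov <- wgs_windows$chrom_set == out$chrom_set[i] &
      .overlaps(wgs_windows$start, wgs_windows$end, out$start[i], out$end[i]) &
      wgs_windows$composition != "UNCLASSIFIED"
    if (!any(ov)) next
    votes <- table(wgs_windows$composition[ov])
    maj <- names(votes)[which.max(votes)]
    out$wgs_composition[i] <- maj
    arr <- out$composition[i]
    corroborates <- !is.na(.array_wgs_match[arr]) &&
      .array_wgs_match[arr] == maj
    if (corroborates) {
      out$agreement[i] <- "confirmed"
    } else if (maj == "AA_DELETION" &&
               arr %in% c("DELETION_CANDIDATE", "AAAB", "AAAA")) {
      out$final_call[i] <- "DELETION_B"
      out$agreement[i] <- "relabelled"
    } else if (maj == "BB_DELETION" &&
               arr %in% c("DELETION_CANDIDATE", "ABBB", "BBBB")) {
      out$final_call[i] <- "DELETION_A"
      out$agreement[i] <- "relabelled"
    }
  }
  out
}
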
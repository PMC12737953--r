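#' Lay out subgenome-diagnostic sites along chromosome sets
#'
#' Diagnostic sites are positions where the A- and B-subgenome alleles
#' differ, so subgenome copy number can be read directly from allele
#' depths. Sites are evenly spaced on the B-subgenome anchor; alleles are
#' drawn per site (always distinct).
#'
#' @param n_sets Number of chromosome sets.
#' @param sites_per_set Diagnostic sites per set.
#' @param set_length Chromosome-set length in base pairs.
#' @param seed Seed for allele assignment.
#' @return Data frame with `site_id`, `chrom_set`, `position` (0-based),
#'   `a_allele`, `b_allele`.
#' @export
make_diagnostic_sites <- function(n_sets = 10, sites_per_set = 2000,
                                  set_length = 10e6, seed = 1L) {
  stopifnot(n_sets >= 1, sites_per_set >= 1)
  pos <- as.integer(round(seq(0.5, sites_per_set - 0.5) /
                            sites_per_set * set_length))
  sites <- data.frame(
    site_id = paste0("s", rep(seq_len(n_sets), each = sites_per_set), "_",
                     rep(seq_len(sites_per_set), n_sets)),
    chrom_set = rep(seq_len(n_sets), each = sites_per_set),
    position = rep(pos, n_sets),
    stringsAsFactors = FALSE
  )
  set.seed(derive_seed(seed, "sites"))
  bases <- c("A", "C", "G", "T")
  b <- sample(bases, nrow(sites), replace = TRUE)
  shift <- sample.int(3, nrow(sites), replace = TRUE)
  a <- bases[(match(b, bases) - 1 + shift) %% 4 + 1]
  sites$a_allele <- a
  sites$b_allele <- b
  sites
}

#' Simulate whole-genome-sequencing allele depths at diagnostic sites
#'
#' For each sample and site with copy numbers `(a, b)`, the total read
#' count is `Poisson(depth * (a+b)/4)` and the A-allele count is
#' `Binomial(total, a/(a+b))` (degenerate when `a + b = 0`). A baseline
#' sample named `synthetic_tetraploid`, built from a 1:1 A:B combination
#' (composition AABB everywhere), is always included: it is the
#' normalization reference for [normalize_counts()].
#'
#' @param plants Character vector of plant labels to sequence.
#' @param implant An [implant_events()] result; carriers determine each
#'   plant's regional copy numbers.
#' @param sites A [make_diagnostic_sites()] result.
#' @param depth Haploid-genome-equivalent sequencing depth at euploid
#'   copy number (default 30, the study's coverage).
#' @param seed Master seed.
#' @return A long `data.frame` of class `"ReadCountTable"` with columns
#'   `sample`, `site_id`, `chrom_set`, `position`, `raw_a`, `raw_b`.
#' @export
simulate_wgs <- function(plants, implant, sites, depth = 30, seed = 1L) {
  stopifnot(depth > 0)
  if (nrow(sites) == 0) stop("empty diagnostic site list")
  set.seed(derive_seed(seed, "wgs"))
  samples <- c("synthetic_tetraploid", plants)
  out <- lapply(samples, function(pl) {
    if (pl == "synthetic_tetraploid") {
      ab <- cbind(a = rep(2, nrow(sites)), b = rep(2, nrow(sites)))
    } else {
      ab <- .copies_at(pl, sites$chrom_set, sites$position, implant)
    }
    tot <- stats::rpois(nrow(sites), depth * (ab[, "a"] + ab[, "b"]) / 4)
    p_a <- ifelse(ab[, "a"] + ab[, "b"] > 0,
                  ab[, "a"] / (ab[, "a"] + ab[, "b"]), 0)
    raw_a <- stats::rbinom(nrow(sites), tot, p_a)
    data.frame(sample = pl, site_id = sites$site_id,
               chrom_set = sites$chrom_set, position = sites$position,
               raw_a = raw_a, raw_b = tot - raw_a,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ReadCountTable", "data.frame")
  out
}
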
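#' Deterministic sub-seed derivation
#'
#' One user-facing seed governs a whole simulated experiment; each
#' stochastic stage derives its own sub-stream from that seed and a salt
#' string, so stages can be re-run independently and reproducibly.
#' @param seed Integer master seed.
#' @param salt Stage name.
#' @return An integer below 2^31 usable with [set.seed()].
#' @export
derive_seed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.double(seed) %% 2147483647 * 69069 + h * 1009) %% 2147483647)
}

#' Build a marker map over homeologous chromosome sets
#'
#' Markers are laid out at evenly spaced positions along each chromosome
#' set (coordinates on the B-subgenome anchor assembly, 0-based
#' half-open). A configurable fraction of markers is `B_high` oriented:
#' their raw score counts B alleles instead of A alleles, as on a real
#' array where probe design fixes an arbitrary reference allele.
#'
#' @param n_sets Number of chromosome sets.
#' @param markers_per_set Markers per set.
#' @param set_length Chromosome-set length in base pairs.
#' @param b_high_fraction Fraction of markers with `B_high` orientation.
#' @param seed Seed for the orientation draw.
#' @return Data frame with `marker_id`, `chrom_set`, `position`,
#'   `orientation`.
#' @export
make_marker_map <- function(n_sets = 10, markers_per_set = 140,
                            set_length = 10e6, b_high_fraction = 0.5,
                            seed = 1L) {
  stopifnot(n_sets >= 1, n_sets <= 10, markers_per_set >= 1,
            b_high_fraction >= 0, b_high_fraction <= 1)
  pos <- as.integer(round(seq(0.5, markers_per_set - 0.5) /
                            markers_per_set * set_length))
  map <- data.frame(
    marker_id = paste0("m", rep(seq_len(n_sets), each = markers_per_set), "_",
                       rep(seq_len(markers_per_set), n_sets)),
    chrom_set = rep(seq_len(n_sets), each = markers_per_set),
    position = rep(pos, n_sets),
    stringsAsFactors = FALSE
  )
  set.seed(derive_seed(seed, "marker_map"))
  map$orientation <- ifelse(stats::runif(nrow(map)) < b_high_fraction,
                            "B_high", "A_high")
  map
}

#' Array noise model parameters
#'
#' @param theta_sd Standard deviation of the A-signal fraction around its
#'   copy-number expectation (euploid clusters sit 0.25 apart, so the
#'   default 0.03 keeps cluster overlap negligible).
#' @param intensity_cv Coefficient of variation of total intensity.
#' @param mis_score_prob Per-marker probability of being mis-scored: every
#'   sample's theta is independently swapped to a random composition's
#'   expectation, emulating probes that cluster on the wrong dosage scale.
#' @param missing_rate Per-cell no-call probability.
#' @return A named list of parameters.
#' @export
noise_params <- function(theta_sd = 0.03, intensity_cv = 0.1,
                         mis_score_prob = 0.01, missing_rate = 0.005) {
  p <- list(theta_sd = theta_sd, intensity_cv = intensity_cv,
            mis_score_prob = mis_score_prob, missing_rate = missing_rate)
  if (any(unlist(p) < 0)) stop("noise parameters must be non-negative")
  if (mis_score_prob > 1 || missing_rate > 1)
    stop("probabilities must be at most 1")
  p
}

#' Sample sheet for a simulated array run
#'
#' Lineage plants plus the study's control structure: diploid A- and
#' B-ancestor accessions, 1:1 / 3:1 / 1:3 A:B DNA mixtures (emulating
#' AABB, AAAB and ABBB compositions), and duplicate extractions of every
#' generation-1 plant as replicate pairs.
#' @param pedigree A [generate_pedigree()] result.
#' @param n_a_parents,n_b_parents,n_mix Replicates per control group.
#' @return Data frame with `sample`, `role`, `plant`, `replicate_of`.
#' @export
array_sample_sheet <- function(pedigree, n_a_parents = 3, n_b_parents = 4,
                               n_mix = 2) {
  gen1 <- pedigree$label[pedigree$generation == 1L]
  ctrl <- function(role, n) data.frame(
    sample = paste0(role, "_", seq_len(n)), role = role,
    plant = NA_character_, replicate_of = NA_character_,
    stringsAsFactors = FALSE)
  rbind(
    data.frame(sample = pedigree$label, role = "lineage",
               plant = pedigree$label, replicate_of = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(sample = paste0(gen1, "_rep"), role = "replicate",
               plant = gen1, replicate_of = gen1, stringsAsFactors = FALSE),
    ctrl("A_parent", n_a_parents), ctrl("B_parent", n_b_parents),
    ctrl("mix_1_1", n_mix), ctrl("mix_3_1", n_mix), ctrl("mix_1_3", n_mix)
  )
}

.control_composition <- c(A_parent = "AAAA", B_parent = "BBBB",
                          mix_1_1 = "AABB", mix_3_1 = "AAAB",
                          mix_1_3 = "ABBB")

#' Simulate an SNP-array signal matrix for a pedigree with truth events
#'
#' Each (marker, sample) cell draws an A-signal fraction
#' `theta ~ Normal(a/(a+b), theta_sd)` clamped to `[0, 1]` and a total
#' intensity `~ Normal((a+b)/4, cv * (a+b)/4)`, where `(a, b)` are the
#' cell's A/B copy numbers given the implanted events. Control samples
#' follow their mixture composition. `B_high` markers emit `1 - theta`.
#'
#' When `deletion_miscall = TRUE`, hemizygous deletion regions are
#' rendered at the theta expectation of the neighbouring 3:1 state
#' (0.75 for a B-loss, 0.25 for an A-loss) while keeping half intensity —
#' reproducing the known failure mode of dosage genotyping over
#' deletions, which the sequencing module later resolves.
#'
#' @param pedigree A [generate_pedigree()] result.
#' @param implant An [implant_events()] result (truth ledger + carriers).
#' @param marker_map A [make_marker_map()] result.
#' @param noise A [noise_params()] list.
#' @param seed Master seed.
#' @param deletion_miscall Render deletions as 3:1-like theta runs.
#' @param samples Optional pre-built sample sheet
#'   (default [array_sample_sheet()]).
#' @return An object of class `"SignalMatrix"`: list with `theta` and
#'   `intensity` (markers x samples matrices), `markers` (the map) and
#'   `samples` (the sheet).
#' @export
simulate_array <- function(pedigree, implant, marker_map,
                           noise = noise_params(), seed = 1L,
                           deletion_miscall = FALSE,
                           samples = array_sample_sheet(pedigree)) {
  noise <- do.call(noise_params, noise)  # validate
  m <- nrow(marker_map); s <- nrow(samples)

  theta_exp <- matrix(NA_real_, m, s,
                      dimnames = list(marker_map$marker_id, samples$sample))
  inten_exp <- theta_exp
  for (j in seq_len(s)) {
    role <- samples$role[j]
    if (role %in% names(.control_composition)) {
      d <- expected_dosage(.control_composition[[role]])
      ab <- cbind(a = rep(d["a"], m), b = rep(d["b"], m))
    } else {
      ab <- .copies_at(samples$plant[j], marker_map$chrom_set,
                       marker_map$position, implant)
    }
    th <- ab[, "a"] / (ab[, "a"] + ab[, "b"])
    it <- (ab[, "a"] + ab[, "b"]) / 4
    if (deletion_miscall) {
      del_b <- ab[, "a"] == 2 & ab[, "b"] == 0
      del_a <- ab[, "a"] == 0 & ab[, "b"] == 2
      th[del_b] <- 0.75
      th[del_a] <- 0.25
    }
    theta_exp[, j] <- th
    inten_exp[, j] <- it
  }

  set.seed(derive_seed(seed, "array"))
  # mis-scored markers: per sample, theta jumps to a random dosage cluster
  if (noise$mis_score_prob > 0) {
    bad <- which(stats::runif(m) < noise$mis_score_prob)
    for (i in bad) {
      theta_exp[i, ] <- sample(c(0, 0.25, 0.5, 0.75, 1), s, replace = TRUE)
    }
  } else {
    bad <- integer(0)
  }

  theta <- theta_exp
  inten <- inten_exp
  if (noise$theta_sd > 0)
    theta <- matrix(stats::rnorm(m * s, theta_exp, noise$theta_sd), m, s,
                    dimnames = dimnames(theta_exp))
  theta <- pmin(pmax(theta, 0), 1)
  if (noise$intensity_cv > 0)
    inten <- matrix(stats::rnorm(m * s, inten_exp,
                                 noise$intensity_cv * inten_exp), m, s,
                    dimnames = dimnames(inten_exp))
  inten <- pmax(inten, 1e-6)  # attributes kept from first arg

  if (noise$missing_rate > 0) {
    drop <- matrix(stats::runif(m * s) < noise$missing_rate, m, s)
    theta[drop] <- NA_real_
    inten[drop] <- NA_real_
  }

  # B_high markers report the fraction of the *other* allele
  flip <- marker_map$orientation == "B_high"
  theta[flip, ] <- 1 - theta[flip, ]

  structure(list(theta = theta, intensity = inten,
                 markers = marker_map, samples = samples,
                 mis_scored = marker_map$marker_id[bad]),
            class = "SignalMatrix")
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat("SignalMatrix:", nrow(x$theta), "markers x", ncol(x$theta), "samples\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$samples$role)),
                                table(x$samples$role)), collapse = ", "), "\n")
  invisible(x)
}
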
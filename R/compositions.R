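#' Expected subgenome copy numbers per genome composition
#'
#' In an allotetraploid AABB nucleus each chromosome set carries two copies
#' from the A subgenome and two from the B subgenome. Homeologous exchange
#' and segmental loss produce unbalanced compositions whose expected
#' (A-copy, B-copy) pairs drive both the array signal model and the
#' read-depth classifier:
#' theta expectation = a/(a+b) and total-intensity expectation = (a+b)/4.
#'
#' @format A data frame with one row per composition and columns
#'   `composition`, `a_copies`, `b_copies`.
#' @examples
#' expected_dosage("ABBB")   # c(a = 1, b = 3)
#' @name expected_dosage
NULL

.composition_table <- data.frame(
  composition = c("AABB", "ABBB", "AAAB", "AAAA", "BBBB",
                  "DELETION_B", "DELETION_A", "TRISOMY_A", "TRISOMY_B"),
  a_copies = c(2, 1, 3, 4, 0, 2, 0, 3, 2),
  b_copies = c(2, 3, 1, 0, 4, 0, 2, 2, 3),
  stringsAsFactors = FALSE
)

#' Composition names understood by the package
#' @return Character vector of composition labels.
#' @export
compositions <- function() .composition_table$composition

#' Expected (A, B) copy numbers for a composition
#'
#' @param composition Character vector of composition labels (see
#'   [compositions()]).
#' @return For a single label, a named numeric vector `c(a =, b =)`;
#'   for several, a two-column matrix with one row per label.
#' @export
expected_dosage <- function(composition) {
  idx <- match(composition, .composition_table$composition)
  if (anyNA(idx)) {
    stop("unknown composition: ",
         paste(composition[is.na(idx)], collapse = ", "))
  }
  m <- cbind(a = .composition_table$a_copies[idx],
             b = .composition_table$b_copies[idx])
  if (length(composition) == 1L) m[1L, ] else m
}

#' Expected A-signal fraction (theta) for a composition
#'
#' theta is the fraction of array signal attributable to the A-subgenome
#' allele: a/(a+b).
#' @inheritParams expected_dosage
#' @return Numeric vector of expected theta values.
#' @export
expected_theta <- function(composition) {
  d <- expected_dosage(composition)
  if (is.null(dim(d))) d["a"] / sum(d) else d[, "a"] / rowSums(d)
}

#' Expected total signal intensity for a composition
#'
#' Scaled so that the euploid four-copy state (AABB) has intensity 1:
#' (a+b)/4. A hemizygous deletion region (two copies) has intensity 0.5.
#' @inheritParams expected_dosage
#' @return Numeric vector of expected intensities.
#' @export
expected_intensity <- function(composition) {
  d <- expected_dosage(composition)
  if (is.null(dim(d))) sum(d) / 4 else rowSums(d) / 4
}

#' Mirror a composition under an A/B subgenome relabelling
#'
#' Swapping the roles of the two subgenomes maps ABBB to AAAB,
#' AAAA to BBBB, a B-deletion to an A-deletion, and fixes AABB.
#' @inheritParams expected_dosage
#' @return Character vector of mirrored labels.
#' @export
mirror_composition <- function(composition) {
  mirror <- c(AABB = "AABB", ABBB = "AAAB", AAAB = "ABBB",
              AAAA = "BBBB", BBBB = "AAAA",
              DELETION_B = "DELETION_A", DELETION_A = "DELETION_B",
              TRISOMY_A = "TRISOMY_B", TRISOMY_B = "TRISOMY_A",
              AA_DELETION = "BB_DELETION", BB_DELETION = "AA_DELETION",
              DELETION_CANDIDATE = "DELETION_CANDIDATE",
              UNCLASSIFIED = "UNCLASSIFIED")
  out <- unname(mirror[composition])
  if (anyNA(out)) stop("unknown composition: ",
                       paste(composition[is.na(out)], collapse = ", "))
  out
}

# score (count of A alleles, 0..4) -> composition label for whole-set states
.score_composition <- c(`0` = "BBBB", `1` = "ABBB", `2` = "AABB",
                        `3` = "AAAB", `4` = "AAAA")

#' Map an A-counting dosage score to its whole-set composition label
#' @param score Integer vector with values in 0..4.
#' @return Character vector of composition labels.
#' @export
score_to_composition <- function(score) {
  if (any(!score %in% 0:4)) stop("dosage scores must be integers in 0..4")
  unname(.score_composition[as.character(score)])
}

# round half away from zero, the convention used for printed rates
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
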
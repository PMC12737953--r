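# Tab-separated writers/readers for the pipeline's tabular artifacts.
# All writers are plain write.table wrappers so outputs are byte-stable.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read a pedigree table
#' @param pedigree A [generate_pedigree()] result.
#' @param path Output file.
#' @return The path (writer) or a `Pedigree` data frame (reader).
#' @export
write_pedigree_tsv <- function(pedigree, path) .write_tsv(pedigree, path)

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  out <- .read_tsv(path)
  class(out) <- c("Pedigree", "data.frame")
  out
}

#' Write / read a dosage matrix as TSV
#'
#' The score table has one row per marker (`marker_id`, `chrom_set`,
#' `position`, `orientation`, then one integer/NA column per sample); the
#' sample sheet travels in a companion file `<path>.samples.tsv`.
#'
#' @param dosage A `DosageMatrix`.
#' @param path Output file for the score table.
#' @return The path (writer) or a `DosageMatrix` (reader; intensity
#'   flags and confidences are not round-tripped and reload as
#'   FALSE / 1).
#' @export
write_dosage_tsv <- function(dosage, path) {
  tab <- cbind(dosage$markers,
               as.data.frame(dosage$score, check.names = FALSE))
  .write_tsv(tab, path)
  .write_tsv(dosage$samples, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tab <- .read_tsv(path)
  samples <- .read_tsv(paste0(path, ".samples.tsv"))
  meta_cols <- intersect(c("marker_id", "chrom_set", "position", "orientation"),
                         names(tab))
  markers <- tab[, meta_cols, drop = FALSE]
  score <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  storage.mode(score) <- "integer"
  rownames(score) <- markers$marker_id
  structure(list(score = score,
                 low_intensity = matrix(FALSE, nrow(score), ncol(score),
                                        dimnames = dimnames(score)),
                 confidence = matrix(1, nrow(score), ncol(score),
                                     dimnames = dimnames(score)),
                 markers = markers, samples = samples),
            class = "DosageMatrix")
}

#' Write / read a signal matrix as long TSV
#' @param signals A `SignalMatrix`.
#' @param path Output file.
#' @return The path (writer) or a `SignalMatrix` (reader).
#' @export
write_signal_tsv <- function(signals, path) {
  long <- data.frame(
    marker_id = rep(rownames(signals$theta), times = ncol(signals$theta)),
    sample = rep(colnames(signals$theta), each = nrow(signals$theta)),
    theta = as.vector(signals$theta),
    intensity = as.vector(signals$intensity),
    stringsAsFactors = FALSE
  )
  .write_tsv(long, path)
  .write_tsv(signals$markers, paste0(path, ".markers.tsv"))
  .write_tsv(signals$samples, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' @rdname write_signal_tsv
#' @export
read_signal_tsv <- function(path) {
  long <- .read_tsv(path)
  markers <- .read_tsv(paste0(path, ".markers.tsv"))
  samples <- .read_tsv(paste0(path, ".samples.tsv"))
  theta <- matrix(long$theta, nrow = nrow(markers),
                  dimnames = list(markers$marker_id, samples$sample))
  inten <- matrix(long$intensity, nrow = nrow(markers),
                  dimnames = list(markers$marker_id, samples$sample))
  structure(list(theta = theta, intensity = inten, markers = markers,
                 samples = samples), class = "SignalMatrix")
}

#' Write / read an allele-depth read-count table as TSV
#' @param counts A `ReadCountTable`.
#' @param path Output file.
#' @return The path (writer) or a `ReadCountTable` (reader).
#' @export
write_counts_tsv <- function(counts, path) .write_tsv(counts, path)

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  out <- .read_tsv(path)
  class(out) <- c("ReadCountTable", "data.frame")
  out
}

.set_to_chrom <- function(chrom_set) sprintf("B%02d", chrom_set)
.chrom_to_set <- function(chrom) as.integer(sub("^B", "", chrom))

#' Write allele depths as a minimal VCF
#'
#' One biallelic record per diagnostic site on the B-subgenome anchor
#' (contigs `B01`..`B10`, 1-based positions): REF is the B-subgenome
#' allele, ALT the A-subgenome allele, and each sample carries an `AD`
#' field `ref,alt` = `raw_b,raw_a`.
#'
#' @param counts A `ReadCountTable` (long, possibly several samples).
#' @param sites The matching [make_diagnostic_sites()] table.
#' @param path Output `.vcf` file (uncompressed).
#' @return The path, invisibly.
#' @export
write_counts_vcf <- function(counts, sites, path) {
  samples <- unique(counts$sample)
  key <- paste(counts$chrom_set, counts$position)
  site_key <- paste(sites$chrom_set, sites$position)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", .set_to_chrom(sort(unique(sites$chrom_set))), ">"),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  ad <- vapply(samples, function(sm) {
    rows <- counts[counts$sample == sm, , drop = FALSE]
    m <- match(site_key, paste(rows$chrom_set, rows$position))
    ifelse(is.na(m), ".", paste0(rows$raw_b[m], ",", rows$raw_a[m]))
  }, character(nrow(sites)))
  ad <- matrix(ad, nrow = nrow(sites))
  body <- paste(.set_to_chrom(sites$chrom_set), sites$position + 1L,
                sites$site_id, sites$b_allele, sites$a_allele, ".", "PASS",
                ".", "AD", apply(ad, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read allele depths from a VCF with per-sample AD fields
#'
#' Uses vcfR; REF depth is taken as the B-subgenome count and ALT depth
#' as the A-subgenome count, matching [write_counts_vcf()].
#'
#' @param path A VCF file.
#' @return A `ReadCountTable`.
#' @export
read_counts_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("vcfR is required to read VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  ids <- vcfR::getID(v)
  out <- do.call(rbind, lapply(colnames(ad), function(sm) {
    parts <- strsplit(ad[, sm], ",", fixed = TRUE)
    raw_b <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
    raw_a <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[2L] else NA_character_, character(1))))
    data.frame(sample = sm, site_id = ids, chrom_set = .chrom_to_set(chrom),
               position = pos - 1L, raw_a = raw_a, raw_b = raw_b,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("ReadCountTable", "data.frame")
  out
}
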
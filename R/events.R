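#' Implant truth events into a pedigree
#'
#' A truth event is a large-scale structural change — a terminal deletion,
#' a homeologous-exchange composition (ABBB/AAAB), a tetrasomy
#' (AAAA/BBBB), or a trisomy — arising in one plant. Heritable events
#' propagate to every descendant of the origin plant; transient events
#' (e.g. arising in a somatic sector or lost in the next meiosis) are
#' carried by the origin plant alone. Events with origin plant `"T"`
#' (the founder) model the reference line's ancestral background
#' compositions: every plant in the cohort carries them.
#'
#' @param pedigree A [generate_pedigree()] result.
#' @param event_spec Either a data frame with columns `plant`, `kind`
#'   (a composition label from [compositions()]), `chrom_set`, `start`,
#'   `end`, `heritable`, or a list with elements `prob` (per-plant event
#'   probability), optional `kinds`, `heritable_prob`, `min_size` and
#'   `max_size` for random implantation.
#' @param seed Integer seed for random implantation mode.
#' @param n_sets Number of chromosome sets (homeologous pairs).
#' @param set_length Length of each chromosome set in base pairs.
#' @return A list with `events` (the truth ledger: one row per
#'   independent origin, with `event_id`, `plant`, `kind`, `chrom_set`,
#'   `start`, `end`, `heritable`, `origin_generation`) and `carriers`
#'   (one row per event per carrier plant).
#' @export
implant_events <- function(pedigree, event_spec, seed = 1L,
                           n_sets = 10, set_length = 10e6) {
  if (is.data.frame(event_spec)) {
    ev <- event_spec
  } else {
    stopifnot(is.list(event_spec), !is.null(event_spec$prob))
    p <- event_spec$prob
    stopifnot(p >= 0, p <= 1)
    kinds <- event_spec$kinds %||%
      c("DELETION_B", "DELETION_A", "ABBB", "AAAB", "AAAA", "BBBB")
    hp <- event_spec$heritable_prob %||% 0.5
    min_size <- event_spec$min_size %||% 1e6
    max_size <- event_spec$max_size %||% set_length
    set.seed(as.integer(seed))
    hit <- stats::runif(nrow(pedigree)) < p
    n <- sum(hit)
    if (n == 0) {
      ev <- data.frame(plant = character(0), kind = character(0),
                       chrom_set = integer(0), start = numeric(0),
                       end = numeric(0), heritable = logical(0),
                       stringsAsFactors = FALSE)
    } else {
      len <- stats::runif(n, min_size, max_size)
      # events anchor at a chromosome-set end (terminal), matching the
      # terminal bias of observed exchanges and deletions
      at_top <- stats::runif(n) < 0.5
      ev <- data.frame(
        plant = pedigree$label[hit],
        kind = sample(kinds, n, replace = TRUE),
        chrom_set = sample.int(n_sets, n, replace = TRUE),
        start = ifelse(at_top, 0, pmax(0, set_length - len)),
        end = ifelse(at_top, pmin(set_length, len), set_length),
        heritable = stats::runif(n) < hp,
        stringsAsFactors = FALSE
      )
    }
  }
  if (nrow(ev) > 0) {
    bad_kind <- !ev$kind %in% compositions()
    if (any(bad_kind)) stop("unknown event kind: ",
                            paste(unique(ev$kind[bad_kind]), collapse = ", "))
    if (any(ev$chrom_set < 1 | ev$chrom_set > n_sets))
      stop("event chromosome set outside 1..", n_sets)
    if (any(ev$start < 0 | ev$end > set_length | ev$start >= ev$end))
      stop("event interval outside chromosome set [0, ", set_length, ")")
    known <- ev$plant %in% c("T", pedigree$label)
    if (!all(known)) stop("event plant not in pedigree: ",
                          paste(unique(ev$plant[!known]), collapse = ", "))
  }
  ev$event_id <- if (nrow(ev) > 0) paste0("ev", seq_len(nrow(ev))) else character(0)
  ev$origin_generation <- integer(nrow(ev))
  nonfounder <- which(ev$plant != "T")
  if (length(nonfounder) > 0)
    ev$origin_generation[nonfounder] <-
      parse_plant_id(ev$plant[nonfounder])$generation
  carriers <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    pl <- ev$plant[i]
    carry <- if (pl == "T") pedigree$label
             else if (ev$heritable[i]) c(pl, pedigree_descendants(pedigree, pl))
             else pl
    data.frame(event_id = ev$event_id[i], plant = carry,
               stringsAsFactors = FALSE)
  }))
  if (is.null(carriers))
    carriers <- data.frame(event_id = character(0), plant = character(0),
                           stringsAsFactors = FALSE)
  ev <- ev[, c("event_id", "plant", "kind", "chrom_set", "start", "end",
               "heritable", "origin_generation")]
  list(events = ev, carriers = carriers)
}

#' The study's three spontaneous instability events as a truth ledger
#'
#' Emulates the observed cohort: a heritable terminal deletion of the B
#' chromosome in set 01 arising at a generation-4 plant, a whole-set ABBB
#' on set 02 in one of that lineage's generation-7 plants, and a
#' transient whole-set ABBB on set 05 in a generation-6 plant whose
#' progeny do not carry it.
#'
#' @param set_length Chromosome-set length in base pairs.
#' @param deletion_span Length of the terminal deletion at the top of
#'   set 01.
#' @return A data frame suitable as `event_spec` for [implant_events()].
#' @export
default_truth_events <- function(set_length = 10e6, deletion_span = 2e6) {
  data.frame(
    plant = c("T.3.3.1.1_G1", "T.3.3.1.1.1.1.11_G1", "T.3.5.1.1.1.1_G2"),
    kind = c("DELETION_B", "ABBB", "ABBB"),
    chrom_set = c(1L, 2L, 5L),
    start = c(0, 0, 0),
    end = c(deletion_span, set_length, set_length),
    heritable = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# (a, b) copy pair per (plant, chrom_set, position), given implanted events.
# Later events in ledger order overwrite earlier ones where they overlap.
.copies_at <- function(plant, chrom_set, position, implant) {
  a <- rep(2, length(position)); b <- rep(2, length(position))
  ev <- implant$events
  if (nrow(ev) == 0) return(cbind(a = a, b = b))
  mine <- ev$event_id %in% implant$carriers$event_id[implant$carriers$plant == plant]
  for (i in which(mine)) {
    sel <- chrom_set == ev$chrom_set[i] &
      position >= ev$start[i] & position < ev$end[i]
    if (any(sel)) {
      d <- expected_dosage(ev$kind[i])
      a[sel] <- d["a"]; b[sel] <- d["b"]
    }
  }
  cbind(a = a, b = b)
}
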
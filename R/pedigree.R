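#' Default branch plan emulating the seven-generation selfing experiment
#'
#' The study design starts from one selfed founder, grows six
#' generation-1 seeds split over two greenhouses, branches early (several
#' seeds per generation-1 plant), then advances lines by single-seed
#' descent; at generation 6 two named plants are expanded to 16 progeny
#' each for phenotyping while the rest continue by single seed. The
#' default plan reproduces the cohort size of 233 plants over seven
#' generations.
#'
#' @param generations Number of generations (default 7).
#' @return A list with `gen_sizes` (plants per generation) and
#'   `expansions` (per-plant progeny overrides applied at the following
#'   generation).
#' @export
default_branch_plan <- function(generations = 7) {
  stopifnot(generations >= 1)
  sizes <- c(6, 32, 33, 33, 33, 33, 63)[seq_len(min(generations, 7))]
  if (generations > 7) sizes <- c(sizes, rep(sizes[7], generations - 7))
  expansions <- list()
  if (generations >= 7) {
    expansions <- list(
      list(parent = "T.2.5.1.1.1.1_G1", n = 16),
      list(parent = "T.3.3.1.1.1.1_G1", n = 16)
    )
  }
  list(gen_sizes = sizes, expansions = expansions)
}

#' Generate a single-seed-descent pedigree
#'
#' Builds the lineage forest deterministically from a branch plan: the
#' founder's seeds form generation 1 (split as evenly as possible between
#' greenhouses G1 and G2, numbered T.1, T.2, ... within each), and each
#' later generation distributes its planned seed count over the previous
#' generation's plants — every surviving lineage gets at least one seed,
#' with extras assigned to the earliest plants in pedigree order.
#' Expansion entries override the seed count of named parents (used for
#' the generation-6 expansion to 16 progeny).
#'
#' @param n_founder_seeds Seeds taken from the founder (generation-1
#'   size); must match `branch_plan$gen_sizes[1]`.
#' @param generations Number of generations to grow.
#' @param branch_plan Plan as returned by [default_branch_plan()].
#' @param seed Unused (generation is fully deterministic); accepted so all
#'   generator entry points share one signature.
#' @return A `data.frame` of class `"Pedigree"` with columns `label`,
#'   `parent_label` (`NA` for generation 1, whose parent is the founder),
#'   `generation` and `greenhouse`.
#' @examples
#' ped <- generate_pedigree()
#' nrow(ped)  # 233
#' @export
generate_pedigree <- function(n_founder_seeds = 6, generations = 7,
                              branch_plan = default_branch_plan(generations),
                              seed = 1L) {
  stopifnot(generations >= 1, n_founder_seeds >= 1)
  sizes <- branch_plan$gen_sizes
  if (length(sizes) != generations)
    stop("branch_plan$gen_sizes must have one entry per generation")
  if (sizes[1] != n_founder_seeds)
    stop("branch_plan generation-1 size (", sizes[1],
         ") disagrees with n_founder_seeds (", n_founder_seeds, ")")
  gh <- rep(c("G1", "G2"), each = ceiling(n_founder_seeds / 2))[seq_len(n_founder_seeds)]
  idx <- stats::ave(seq_len(n_founder_seeds), gh, FUN = seq_along)
  plants <- data.frame(
    label = mapply(function(i, g) format_plant_id(i, g), idx, gh),
    parent_label = NA_character_,
    generation = 1L,
    greenhouse = gh,
    stringsAsFactors = FALSE
  )
  prev <- plants

  expansions <- branch_plan$expansions %||% list()
  exp_parents <- vapply(expansions, `[[`, character(1), "parent")
  exp_n <- vapply(expansions, `[[`, numeric(1), "n")

  for (g in seq_len(generations)[-1]) {
    n_parents <- nrow(prev)
    counts <- rep(1L, n_parents)
    is_exp <- prev$label %in% exp_parents
    counts[is_exp] <- as.integer(exp_n[match(prev$label[is_exp], exp_parents)])
    remaining <- sizes[g] - sum(counts[is_exp])
    n_free <- sum(!is_exp)
    if (n_free > 0) {
      if (remaining < n_free)
        stop("invalid branch plan: generation ", g, " allots zero offspring ",
             "to a surviving lineage (", remaining, " seeds for ", n_free,
             " lineages)")
      base <- remaining %/% n_free
      extra <- remaining %% n_free
      free_counts <- rep(base, n_free)
      if (extra > 0) free_counts[seq_len(extra)] <- base + 1L
      counts[!is_exp] <- free_counts
    } else if (remaining != 0) {
      stop("invalid branch plan: generation ", g, " size does not match ",
           "expansion totals")
    }
    parent_path <- parse_plant_id(prev$label)$path
    rows <- lapply(seq_len(n_parents), function(i) {
      k <- counts[i]
      labs <- vapply(seq_len(k), function(j)
        format_plant_id(c(parent_path[[i]], j), prev$greenhouse[i]),
        character(1))
      data.frame(label = labs, parent_label = prev$label[i],
                 generation = g, greenhouse = prev$greenhouse[i],
                 stringsAsFactors = FALSE)
    })
    nxt <- do.call(rbind, rows)
    plants <- rbind(plants, nxt)
    prev <- nxt
  }
  rownames(plants) <- NULL
  class(plants) <- c("Pedigree", "data.frame")
  plants
}

#' All descendants of a plant within a pedigree
#'
#' @param pedigree A [generate_pedigree()] result.
#' @param label Identifier of the ancestor plant.
#' @return Character vector of descendant labels (the plant itself
#'   excluded), in pedigree order.
#' @export
pedigree_descendants <- function(pedigree, label) {
  stopifnot(label %in% pedigree$label)
  out <- character(0)
  frontier <- label
  while (length(frontier) > 0) {
    kids <- pedigree$label[pedigree$parent_label %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
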
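#' Parse single-seed-descent plant identifiers
#'
#' Lineage plants are named `T.<d1>.<d2>..._G<k>`: `T` is the founder,
#' each dotted integer adds one generation of selfed single-seed descent,
#' and the `_G1`/`_G2` suffix records the greenhouse of cultivation.
#' `T.3.3.1.1_G1` is therefore a generation-4 plant whose parent is
#' `T.3.3.1_G1`.
#'
#' @param label Character vector of identifiers.
#' @return A data frame with one row per label and columns `label`,
#'   `generation` (number of path elements), `greenhouse` (`"G1"` or
#'   `"G2"`) and `path` (list column of integer vectors).
#' @examples
#' parse_plant_id("T.3.3.1.1.1.1.11_G1")
#' @export
parse_plant_id <- function(label) {
  stopifnot(is.character(label), length(label) >= 1L)
  re <- "^T(\\.[0-9]+)+_G[0-9]+$"
  bad <- !grepl(re, label)
  if (any(bad)) {
    b <- label[bad][1L]
    # report the first offending character position to ease debugging
    ok_prefix <- regmatches(b, regexpr("^T(\\.[0-9]+)*", b))
    pos <- if (length(ok_prefix) == 0) 1L else nchar(ok_prefix) + 1L
    stop(sprintf("malformed plant identifier '%s' (parse failed at position %d)",
                 b, pos))
  }
  core <- sub("_G[0-9]+$", "", label)
  gh <- sub("^.*_(G[0-9]+)$", "\\1", label)
  if (any(!gh %in% c("G1", "G2"))) {
    stop("greenhouse suffix must be _G1 or _G2: ",
         paste(unique(label[!gh %in% c("G1", "G2")]), collapse = ", "))
  }
  path <- lapply(strsplit(core, ".", fixed = TRUE),
                 function(p) as.integer(p[-1L]))
  out <- data.frame(label = label,
                    generation = lengths(path),
                    greenhouse = gh,
                    stringsAsFactors = FALSE)
  out$path <- path
  out
}

#' Format a descent path and greenhouse as a plant identifier
#'
#' Inverse of [parse_plant_id()]: `format_plant_id(path, greenhouse)`
#' round-trips exactly.
#'
#' @param path Integer vector of per-generation seed indices (one element
#'   per generation), all positive.
#' @param greenhouse `"G1"` or `"G2"`.
#' @return A single identifier string.
#' @export
format_plant_id <- function(path, greenhouse) {
  stopifnot(length(path) >= 1L, all(path >= 1), greenhouse %in% c("G1", "G2"))
  paste0("T.", paste(as.integer(path), collapse = "."), "_", greenhouse)
}

#' Identifier of a plant's parent in the descent
#'
#' Dropping the final path element gives the parent; generation-1 plants
#' descend from the founder and return `NA`.
#' @param label Character vector of identifiers.
#' @return Character vector of parent identifiers (`NA` for generation 1).
#' @export
parent_plant_id <- function(label) {
  p <- parse_plant_id(label)
  vapply(seq_len(nrow(p)), function(i) {
    path <- p$path[[i]]
    if (length(path) == 1L) NA_character_
    else format_plant_id(path[-length(path)], p$greenhouse[i])
  }, character(1))
}
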
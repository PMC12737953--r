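# Builders for hand-sized fixtures and an independent rule-by-rule oracle
# for the marker-filter cascade. The oracle is deliberately written as
# plain per-marker loops, sharing no code with the package's vectorized
# cascade.

# Construct a DosageMatrix directly from a score matrix and sample roles.
make_dosage <- function(score, roles, plants = NULL, replicate_of = NULL,
                        low_intensity = NULL, markers = NULL) {
  score <- as.matrix(score)
  storage.mode(score) <- "integer"
  n_m <- nrow(score); n_s <- ncol(score)
  if (is.null(rownames(score))) rownames(score) <- paste0("m", seq_len(n_m))
  if (is.null(colnames(score))) colnames(score) <- paste0("s", seq_len(n_s))
  if (is.null(plants))
    plants <- ifelse(roles %in% c("lineage", "replicate"),
                     colnames(score), NA_character_)
  if (is.null(replicate_of)) replicate_of <- rep(NA_character_, n_s)
  if (is.null(low_intensity))
    low_intensity <- matrix(FALSE, n_m, n_s, dimnames = dimnames(score))
  if (is.null(markers))
    markers <- data.frame(marker_id = rownames(score),
                          chrom_set = 1L,
                          position = seq_len(n_m) * 1000,
                          orientation = "A_high",
                          stringsAsFactors = FALSE)
  structure(list(score = score, low_intensity = low_intensity,
                 confidence = matrix(1, n_m, n_s, dimnames = dimnames(score)),
                 markers = markers,
                 samples = data.frame(sample = colnames(score), role = roles,
                                      plant = plants,
                                      replicate_of = replicate_of,
                                      stringsAsFactors = FALSE)),
            class = "DosageMatrix")
}

# Most-frequent value, ties toward 2 (re-stated independently).
oracle_modal <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_integer_)
  tab <- table(v)
  best <- as.integer(names(tab)[tab == max(tab)])
  if (2L %in% best) 2L else best[order(abs(best - 2L), best)][1]
}

# Rule-by-rule retained set, computed marker by marker with explicit loops.
oracle_cascade_retained <- function(dosage, marker_map) {
  sc <- dosage$score
  roles <- dosage$samples$role
  lin <- which(roles == "lineage")
  retained <- rownames(sc)

  # stage 1: complete over lineages
  retained <- Filter(function(m) !anyNA(sc[m, lin]), retained)

  # stage 2: controls
  ctrl <- list(A_parent = which(roles == "A_parent"),
               B_parent = which(roles == "B_parent"),
               mix_1_1 = which(roles == "mix_1_1"),
               mix_3_1 = which(roles == "mix_3_1"),
               mix_1_3 = which(roles == "mix_1_3"))
  retained <- Filter(function(m) {
    vals <- lapply(ctrl, function(cc) unique(sc[m, cc]))
    if (any(vapply(vals, function(v) length(v) != 1 || anyNA(v), TRUE)))
      return(FALSE)
    a <- vals$A_parent; b <- vals$B_parent
    abs(a - b) >= 2 && vals$mix_3_1 != vals$mix_1_3 && vals$mix_1_1 == 2
  }, retained)

  # stage 3: replicate concordance
  reps <- which(!is.na(dosage$samples$replicate_of))
  retained <- Filter(function(m) {
    for (r in reps) {
      mate <- which(dosage$samples$sample == dosage$samples$replicate_of[r])
      x <- sc[m, r]; y <- sc[m, mate]
      if (is.na(x) || is.na(y) || x != y) return(FALSE)
    }
    TRUE
  }, retained)

  # stage 4: modal rule with same-direction consecutive runs
  idx <- match(retained, rownames(sc))
  modal <- vapply(idx, function(i) oracle_modal(sc[i, lin]), integer(1))
  keep4 <- logical(length(idx))
  for (k in seq_along(idx)) {
    if (is.na(modal[k])) next
    if (modal[k] == 2L) { keep4[k] <- TRUE; next }
    cs <- marker_map$chrom_set[idx[k]]
    same_set <- which(marker_map$chrom_set[idx] == cs)
    pos_in_set <- match(k, same_set)
    dir_k <- if (modal[k] > 2) 1 else -1
    same_dir <- function(kk) {
      !is.na(modal[kk]) && modal[kk] != 2L &&
        (if (modal[kk] > 2) 1 else -1) == dir_k
    }
    prev_ok <- pos_in_set > 1 && same_dir(same_set[pos_in_set - 1])
    next_ok <- pos_in_set < length(same_set) && same_dir(same_set[pos_in_set + 1])
    keep4[k] <- prev_ok || next_ok
  }
  retained <- retained[keep4]

  # stage 5: orientation (drop unorientable)
  retained <- Filter(function(m) {
    a <- oracle_modal(sc[m, ctrl$A_parent])
    b <- oracle_modal(sc[m, ctrl$B_parent])
    !is.na(a) && !is.na(b) && a != b
  }, retained)

  unlist(retained)
}

# Small filter-stress cohort: n_clean good markers plus one marker
# violating each cascade rule, all on one chromosome set.
filter_stress_dosage <- function(n_clean = 20, seed = 1) {
  set.seed(seed)
  n_lin <- 8
  roles <- c(rep("lineage", n_lin), "replicate",
             rep("A_parent", 2), rep("B_parent", 2),
             rep("mix_1_1", 2), rep("mix_3_1", 2), rep("mix_1_3", 2))
  n_s <- length(roles)
  good_row <- function() c(rep(2L, n_lin), 2L, 4L, 4L, 0L, 0L,
                           2L, 2L, 3L, 3L, 1L, 1L)
  rows <- lapply(seq_len(n_clean), function(i) good_row())
  bad <- list(
    incomplete = { r <- good_row(); r[2] <- NA_integer_; r },
    ctrl_nonuniform = { r <- good_row(); r[10] <- 2L; r },      # A_parent split
    ctrl_close = { r <- good_row(); r[10:11] <- 1L; r[12:13] <- 0L; r },
    ctrl_mix_equal = { r <- good_row(); r[16:17] <- 3L; r[18:19] <- 3L; r },
    ctrl_mix11 = { r <- good_row(); r[14:15] <- 3L; r },
    replicate_discord = { r <- good_row(); r[9] <- 3L; r },
    isolated_modal = { r <- good_row(); r[1:n_lin] <- 3L; r }
  )
  score <- do.call(rbind, c(rows, bad))
  rownames(score) <- c(paste0("clean", seq_len(n_clean)), names(bad))
  reps <- rep(NA_character_, n_s); reps[9] <- colnames(score)[1] %||% "s1"
  d <- make_dosage(score, roles, replicate_of = reps)
  d$samples$replicate_of[9] <- d$samples$sample[1]
  d$samples$plant[9] <- d$samples$sample[1]
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
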
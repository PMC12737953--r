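test_that("each implanted rule violation is dropped by its stage", {
  d <- filter_stress_dosage()
  expect_false(filter_complete(d)[["incomplete"]])
  fc <- filter_controls(d)
  expect_false(fc[["ctrl_nonuniform"]])
  expect_false(fc[["ctrl_close"]])      # ancestor separation 1 < 2
  expect_false(fc[["ctrl_mix_equal"]])  # 3:1 equals 1:3
  expect_false(fc[["ctrl_mix11"]])      # 1:1 modal is not 2
  expect_true(fc[["clean1"]])
  expect_false(filter_replicates(d)[["replicate_discord"]])
  fm <- filter_modal_rule(d, d$markers)
  expect_false(fm[["isolated_modal"]])
  expect_true(fm[["clean1"]])
})

test_that("adjacent same-direction modal deviations survive; opposite do not", {
  n_lin <- 6
  roles <- c(rep("lineage", n_lin))
  base <- rep(2L, n_lin)
  score <- rbind(base, base + 1L, base + 2L, base, base + 1L, base - 1L, base)
  rownames(score) <- paste0("m", 1:7)
  d <- make_dosage(score, roles)
  keep <- filter_modal_rule(d, d$markers)
  # rows 2-3 deviate toward A consecutively -> kept; rows 5 (A) and 6 (B)
  # deviate in opposite directions -> both isolated -> dropped
  expect_equal(unname(keep), c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("orientation standardization enforces A-counting everywhere", {
  d <- filter_stress_dosage()
  # flip markers clean1..clean5 to B-counting by mirroring all scores
  flip_rows <- paste0("clean", 1:5)
  d$score[flip_rows, ] <- 4L - d$score[flip_rows, , drop = FALSE]
  # the A-counting postcondition is guaranteed for control-passing markers
  d <- dosage_subset(d, markers = which(filter_controls(d)))
  ori <- standardize_orientation(d)
  sc <- ori$dosage$score
  a_col <- which(ori$dosage$samples$role == "A_parent")
  b_col <- which(ori$dosage$samples$role == "B_parent")
  m31 <- which(ori$dosage$samples$role == "mix_3_1")
  m13 <- which(ori$dosage$samples$role == "mix_1_3")
  expect_true(all(sc[, a_col] > sc[, b_col]))
  expect_true(all(sc[, m31[1]] > sc[, m13[1]]))
  expect_true(all(ori$flipped[flip_rows]))
  # unorientable marker (equal ancestor scores) is dropped with a reason
  d2 <- filter_stress_dosage()
  d2$score["clean1", d2$samples$role %in% c("A_parent", "B_parent")] <- 2L
  ori2 <- standardize_orientation(d2)
  expect_false(ori2$retained[["clean1"]])
})

test_that("the cascade matches the independent rule-by-rule oracle", {
  d <- filter_stress_dosage(n_clean = 30, seed = 3)
  res <- run_cascade(d, exclude_samples = FALSE)
  expect_setequal(rownames(res$dosage$score),
                  oracle_cascade_retained(d, d$markers))
})

test_that("cascade counts telescope and the cascade is idempotent", {
  d <- filter_stress_dosage()
  res <- run_cascade(d, exclude_samples = FALSE)
  rep <- res$report
  expect_equal(rep$n_in[-1], rep$n_out[-nrow(rep)])
  expect_equal(rep$n_in[1], nrow(d$score))
  res2 <- run_cascade(res$dosage, res$marker_map, exclude_samples = FALSE)
  expect_identical(res2$dosage$score, res$dosage$score)
  expect_equal(res2$report$n_in, res2$report$n_out)
})

test_that("cascade is symmetric under a global A/B relabelling", {
  d <- filter_stress_dosage(n_clean = 25, seed = 11)
  d_m <- d
  d_m$score <- 4L - d_m$score
  # swap ancestor-control and mixture roles along with the scores
  swap <- c(A_parent = "B_parent", B_parent = "A_parent",
            mix_3_1 = "mix_1_3", mix_1_3 = "mix_3_1")
  hit <- d_m$samples$role %in% names(swap)
  d_m$samples$role[hit] <- unname(swap[d_m$samples$role[hit]])
  r1 <- run_cascade(d, exclude_samples = FALSE)
  r2 <- run_cascade(d_m, exclude_samples = FALSE)
  expect_setequal(rownames(r1$dosage$score), rownames(r2$dosage$score))
  m <- rownames(r1$dosage$score)
  expect_equal(r2$dosage$score[m, ], 4L - r1$dosage$score[m, ])
})

test_that("missing-rate attrition of complete markers is binomial", {
  ped <- generate_pedigree(4, 2, list(gen_sizes = c(4L, 8L),
                                      expansions = list()))
  tr <- implant_events(ped, list(prob = 0))
  map <- make_marker_map(n_sets = 5, markers_per_set = 200, seed = 6)
  rate <- 0.02
  sig <- simulate_array(ped, tr, map,
                        noise = noise_params(0, 0, 0, missing_rate = rate),
                        seed = 6)
  d <- call_dosage(sig)
  keep <- filter_complete(d)
  n_lin <- sum(d$samples$role == "lineage")
  p_keep <- (1 - rate)^n_lin
  se <- sqrt(p_keep * (1 - p_keep) / length(keep))
  expect_lt(abs(mean(keep) - p_keep), 3 * se)
})

test_that("mis-scored markers are flushed out by the cascade", {
  ped <- generate_pedigree(4, 2, list(gen_sizes = c(4L, 8L),
                                      expansions = list()))
  tr <- implant_events(ped, list(prob = 0))
  map <- make_marker_map(n_sets = 4, markers_per_set = 150, seed = 13)
  sig <- simulate_array(ped, tr, map,
                        noise = noise_params(0, 0, mis_score_prob = 0.05, 0),
                        seed = 13)
  d <- call_dosage(sig)
  res <- run_cascade(d, map, exclude_samples = FALSE)
  bad <- sig$mis_scored
  expect_gt(length(bad), 10)
  expect_length(intersect(rownames(res$dosage$score), bad), 0)
  clean_kept <- setdiff(rownames(d$score), bad)
  expect_gte(mean(clean_kept %in% rownames(res$dosage$score)), 0.99)
})

test_that("sample exclusion flags scattered-noise samples, not event carriers", {
  ped <- generate_pedigree()
  tr <- implant_events(ped, default_truth_events())
  map <- make_marker_map(markers_per_set = 60, seed = 21)
  sig <- simulate_array(ped, tr, map, noise = noise_params(0, 0, 0, 0),
                        seed = 21, deletion_miscall = TRUE)
  # corrupt one plant with scattered random scores (low-quality DNA)
  victim <- which(sig$samples$sample == "T.1.1.1.1.1.1.1_G1")
  set.seed(1)
  cells <- sample(nrow(sig$theta), 60)
  sig$theta[cells, victim] <- sample(c(0, 0.25, 0.75, 1), 60, replace = TRUE)
  d <- call_dosage(sig)
  flagged <- flag_noisy_samples(d, map)
  expect_identical(flagged, "T.1.1.1.1.1.1.1_G1")
})
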
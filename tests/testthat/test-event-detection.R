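# cohort with an oriented dosage matrix built directly: 3 plants x 2 sets
runs_fixture <- function() {
  score <- matrix(2L, 20, 3,
                  dimnames = list(paste0("m", 1:20), c("p1", "p2", "p3")))
  map <- data.frame(marker_id = rownames(score),
                    chrom_set = rep(1:2, each = 10),
                    position = rep(seq_len(10) * 1e6 - 5e5, 2),
                    orientation = "A_high")
  make_dosage(score, roles = rep("lineage", 3), markers = map)
}

test_that("maximal same-score runs become one call each", {
  d <- runs_fixture()
  d$score[11:20, "p2"] <- 1L                   # whole-set ABBB on set 2
  d$score[3, "p3"] <- 4L                       # isolated cell: no call
  calls <- call_runs(d)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$plant, "p2")
  expect_equal(calls$chrom_set, 2L)
  expect_equal(calls$composition, "ABBB")
  expect_equal(calls$n_markers, 10L)
  expect_equal(calls$start, 5e5)
  expect_equal(calls$end, 9.5e6 + 1)
  # an all-euploid matrix yields no calls
  expect_equal(nrow(call_runs(runs_fixture())), 0L)
})

test_that("low-intensity score runs become deletion candidates", {
  d <- runs_fixture()
  d$score[1:4, "p1"] <- 3L
  d$low_intensity[1:4, "p1"] <- c(TRUE, TRUE, TRUE, FALSE)  # 75% flagged
  calls <- call_runs(d)
  expect_equal(calls$composition, "DELETION_CANDIDATE")
  expect_equal(calls$array_composition, "AAAB")
  # below half flagged the run stays an ordinary composition call
  d$low_intensity[1:4, "p1"] <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(call_runs(d)$composition, "AAAB")
})

test_that("interrupted or short runs respect min_run", {
  d <- runs_fixture()
  d$score[c(1, 3), "p1"] <- 3L                 # not consecutive
  expect_equal(nrow(call_runs(d)), 0L)
  d$score[1:3, "p1"] <- c(3L, 3L, 4L)          # 3,3 run + isolated 4
  calls <- call_runs(d)
  expect_equal(calls$composition, "AAAB")
  expect_equal(calls$n_markers, 2L)
  expect_equal(nrow(call_runs(d, min_run = 3)), 0L)
})

test_that("cohort-wide compositions are background, rare ones candidates", {
  d <- runs_fixture()
  d$score[1:2, ] <- 4L                         # terminal AAAA in all plants
  d$score[15:16, "p2"] <- 1L                   # ABBB unique to p2
  calls <- classify_background(call_runs(d))
  expect_equal(sum(calls$status == "background"), 3L)
  cand <- calls[calls$status == "candidate", ]
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$plant, "p2")
  expect_equal(cand$composition, "ABBB")
  # reference-profile mode gives the same split
  ref <- data.frame(chrom_set = 1L, start = 0, end = 2e6,
                    composition = "AAAA")
  calls2 <- classify_background(call_runs(d), reference = ref)
  expect_equal(calls$status, calls2$status)
})

test_that("inheritance tracing counts each independent origin once", {
  ped <- generate_pedigree()
  tr <- implant_events(ped, default_truth_events())
  map <- make_marker_map(seed = 31)
  sig <- simulate_array(ped, tr, map, noise = noise_params(0, 0, 0, 0),
                        seed = 31, deletion_miscall = TRUE)
  casc <- run_cascade(call_dosage(sig), map)
  calls <- classify_background(call_runs(casc$dosage, casc$marker_map))
  traced <- trace_inheritance(calls, ped)
  org <- traced$origins
  expect_equal(nrow(org), 3L)
  # deletion lineage: novel at the generation-4 plant, inherited below
  del <- org[org$chrom_set == 1, ]
  expect_equal(del$plant, "T.3.3.1.1_G1")
  expect_equal(del$origin_generation, 4L)
  expect_equal(del$n_carriers, 19L)
  expect_false(del$transient)
  inherited <- traced$calls[traced$calls$status == "inherited" &
                              traced$calls$chrom_set == 1, ]
  expect_setequal(inherited$plant, pedigree_descendants(ped, "T.3.3.1.1_G1"))
  # transient set-05 event: sole carrier, progeny exists without the call
  t5 <- org[org$chrom_set == 5, ]
  expect_equal(t5$plant, "T.3.5.1.1.1.1_G2")
  expect_true(t5$transient)
  expect_equal(t5$n_carriers, 1L)
  # novel-call count equals ledger size; inherited calls never add origins
  expect_equal(sum(traced$calls$status == "novel"), nrow(org))
})

test_that("the same composition in disjoint subtrees counts twice", {
  ped <- generate_pedigree()
  spec <- data.frame(plant = c("T.1.2_G1", "T.2.3_G2"), kind = "ABBB",
                     chrom_set = 4L, start = 0, end = 10e6, heritable = TRUE)
  tr <- implant_events(ped, spec)
  map <- make_marker_map(markers_per_set = 40, seed = 17)
  sig <- simulate_array(ped, tr, map, noise = noise_params(0, 0, 0, 0),
                        seed = 17)
  casc <- run_cascade(call_dosage(sig), map)
  traced <- trace_inheritance(
    classify_background(call_runs(casc$dosage, casc$marker_map)), ped)
  expect_equal(nrow(traced$origins), 2L)
  expect_setequal(traced$origins$plant, spec$plant)
})

test_that("plants missing from the pedigree are rejected", {
  d <- runs_fixture()
  d$score[1:5, "p1"] <- 1L
  calls <- classify_background(call_runs(d))
  ped <- generate_pedigree()
  expect_error(trace_inheritance(calls, ped), "not in pedigree")
})

test_that("rate arithmetic reproduces printed study rates exactly", {
  expect_equal(compute_rate(3, 233)$rate_percent, 1.3)
  expect_equal(compute_rate(9, 166)$rate_percent, 5.4)
  expect_equal(compute_rate(2, 202)$rate_percent, 1.0)
  expect_equal(compute_rate(8, 202)$rate_percent, 4.0)
  expect_equal(compute_rate(0, 100)$rate_percent, 0.0)
  expect_error(compute_rate(1, 0), "positive")
  expect_equal(analyzed_cohort(233, c(2, 4)), 227)
})
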
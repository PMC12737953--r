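ped_small <- generate_pedigree(4, 3, list(gen_sizes = c(4L, 8L, 8L),
                                          expansions = list()))

test_that("noise-free array signals equal their dosage expectations", {
  tr <- implant_events(ped_small, list(prob = 0))
  map <- make_marker_map(n_sets = 2, markers_per_set = 10,
                         b_high_fraction = 0, seed = 2)
  sig <- simulate_array(ped_small, tr, map, noise = noise_params(0, 0, 0, 0),
                        seed = 2)
  lin <- which(sig$samples$role == "lineage")
  expect_true(all(sig$theta[, lin] == 0.5))
  expect_true(all(sig$intensity[, lin] == 1.0))
  # control mixtures: 3:1 A:B emulates AAAB, theta 0.75
  expect_true(all(sig$theta[, sig$samples$role == "mix_3_1"] == 0.75))
  expect_true(all(sig$theta[, sig$samples$role == "mix_1_3"] == 0.25))
  expect_true(all(sig$theta[, sig$samples$role == "A_parent"] == 1))
})

test_that("deletion regions emit half intensity, pure-A theta (or the miscall)", {
  spec <- data.frame(plant = "T.1.1_G1", kind = "DELETION_B", chrom_set = 1L,
                     start = 0, end = 10e6, heritable = TRUE)
  tr <- implant_events(ped_small, spec)
  map <- make_marker_map(n_sets = 2, markers_per_set = 10,
                         b_high_fraction = 0, seed = 2)
  sig <- simulate_array(ped_small, tr, map, noise = noise_params(0, 0, 0, 0),
                        seed = 2)
  col <- which(sig$samples$sample == "T.1.1_G1")
  del_rows <- sig$markers$chrom_set == 1
  expect_true(all(sig$theta[del_rows, col] == 1.0))
  expect_true(all(sig$intensity[del_rows, col] == 0.5))

  mis <- simulate_array(ped_small, tr, map, noise = noise_params(0, 0, 0, 0),
                        seed = 2, deletion_miscall = TRUE)
  expect_true(all(mis$theta[del_rows, col] == 0.75))
  expect_true(all(mis$intensity[del_rows, col] == 0.5))
})

test_that("B_high markers report the complementary signal fraction", {
  tr <- implant_events(ped_small, list(prob = 0))
  map <- make_marker_map(n_sets = 1, markers_per_set = 20,
                         b_high_fraction = 0.5, seed = 9)
  sig <- simulate_array(ped_small, tr, map, noise = noise_params(0, 0, 0, 0),
                        seed = 2)
  a_col <- which(sig$samples$role == "A_parent")[1]
  flip <- sig$markers$orientation == "B_high"
  expect_true(all(sig$theta[flip, a_col] == 0))
  expect_true(all(sig$theta[!flip, a_col] == 1))
})

test_that("array simulation is deterministic under a fixed seed", {
  tr <- implant_events(ped_small, list(prob = 0))
  map <- make_marker_map(n_sets = 1, markers_per_set = 15, seed = 4)
  s1 <- simulate_array(ped_small, tr, map, seed = 11)
  s2 <- simulate_array(ped_small, tr, map, seed = 11)
  expect_identical(s1$theta, s2$theta)
  expect_identical(s1$intensity, s2$intensity)
  s3 <- simulate_array(ped_small, tr, map, seed = 12)
  expect_false(identical(s1$theta, s3$theta))
})

test_that("negative noise parameters are rejected", {
  expect_error(noise_params(theta_sd = -0.1), "non-negative")
  expect_error(noise_params(mis_score_prob = 1.5), "at most 1")
})

test_that("read sampling matches the Poisson-binomial model", {
  # single plant with an AAAA set and a DELETION_B set; many sites
  spec <- data.frame(plant = c("T.1.1_G1", "T.1.1_G1"),
                     kind = c("AAAA", "DELETION_B"),
                     chrom_set = c(1L, 2L), start = 0, end = 10e6,
                     heritable = FALSE)
  tr <- implant_events(ped_small, spec)
  sites <- make_diagnostic_sites(n_sets = 3, sites_per_set = 4000, seed = 3)
  cnt <- simulate_wgs("T.1.1_G1", tr, sites, depth = 30, seed = 3)
  smp <- cnt[cnt$sample == "T.1.1_G1", ]
  expect_true(all(smp$raw_b[smp$chrom_set == 1] == 0))      # AAAA: no B reads
  expect_true(all(smp$raw_b[smp$chrom_set == 2] == 0))      # B deleted
  # DELETION_B halves total coverage: E[total] = depth/2
  tot2 <- smp$raw_a[smp$chrom_set == 2] + smp$raw_b[smp$chrom_set == 2]
  se <- sd(tot2) / sqrt(length(tot2))
  expect_lt(abs(mean(tot2) - 15), 3 * se)
  # euploid set: E[raw_a] = E[raw_b] = depth/2
  a3 <- smp$raw_a[smp$chrom_set == 3]; b3 <- smp$raw_b[smp$chrom_set == 3]
  expect_lt(abs(mean(a3) - 15), 3 * sd(a3) / sqrt(length(a3)))
  expect_lt(abs(mean(b3) - 15), 3 * sd(b3) / sqrt(length(b3)))
  # the synthetic-tetraploid baseline is always present
  expect_true("synthetic_tetraploid" %in% cnt$sample)
  expect_error(simulate_wgs("T.1.1_G1", tr, sites[0, ], 30), "empty")
})

test_that("normalized read counts converge to expected copies with depth", {
  # the per-site ratio estimator carries an O(1/depth) bias (ratio of two
  # counts), so convergence is checked with a depth-scaled allowance that
  # shrinks fourfold between the two depths
  kinds <- c("ABBB", "AAAB", "BBBB", "TRISOMY_A")
  spec <- data.frame(plant = "T.1.1_G1", kind = kinds,
                     chrom_set = seq_along(kinds), start = 0, end = 10e6,
                     heritable = FALSE)
  tr <- implant_events(ped_small, spec)
  sites <- make_diagnostic_sites(n_sets = 6, sites_per_set = 1500, seed = 8)
  for (depth in c(200, 800)) {
    cnt <- simulate_wgs("T.1.1_G1", tr, sites, depth = depth, seed = 8)
    nm <- normalize_counts(cnt[cnt$sample == "T.1.1_G1", ],
                           cnt[cnt$sample == "synthetic_tetraploid", ])
    for (k in seq_along(kinds)) {
      d <- expected_dosage(kinds[k])
      sel <- nm$chrom_set == k
      for (ax in c("a", "b")) {
        v <- nm[[paste0("norm_", ax)]][sel]
        se <- sd(v) / sqrt(length(v))
        bias_allowance <- (8 / depth) * max(d[ax], 1)
        expect_lt(abs(mean(v) - d[ax]), 3 * se + bias_allowance)
      }
    }
  }
})
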
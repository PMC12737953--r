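test_that("diagnostic-site selection applies consensus and depth gates", {
  pv <- data.frame(
    chrom_set = 1L, position = c(100, 200, 300, 400, 500),
    a_allele = c("G", "G", "G", "G", "G"),
    a_support = c(1.0, 0.90, 1.0, 0.96, 1.0),
    a_depth = c(10, 10, 10, 10, 0),
    b_allele = c("T", "T", "G", "T", "T"),
    b_support = c(1.0, 1.0, 1.0, 0.95, 1.0),
    b_depth = c(8, 8, 8, 8, 8)
  )
  kept <- select_sites(pv)
  expect_equal(kept$position, c(100, 400))   # 0.90 consensus, same-allele and
  expect_equal(nrow(select_sites(pv, min_depth = 11)), 0L)  # zero-depth fail
})

test_that("a sample normalized against itself sits at (2, 2) everywhere", {
  set.seed(4)
  base <- data.frame(sample = "synthetic_tetraploid", site_id = paste0("s", 1:300),
                     chrom_set = 1L, position = seq_len(300) * 1000,
                     raw_a = rpois(300, 15) + 1L, raw_b = rpois(300, 15) + 1L)
  nm <- normalize_counts(base, base)
  expect_true(all(abs(nm$norm_a - 2) < 1e-12))
  expect_true(all(abs(nm$norm_b - 2) < 1e-12))
  disjoint <- base
  disjoint$position <- disjoint$position + 0.5
  expect_error(normalize_counts(disjoint, base), "no diagnostic sites")
})

test_that("windows classify to the nearest expected copy pair", {
  mk <- function(a, b) data.frame(
    chrom_set = 1L, position = seq_len(50) * 1000,
    norm_a = rep(a, 50), norm_b = rep(b, 50))
  expect_equal(window_classify(mk(2.01, 1.98))$composition, "AABB")
  expect_equal(window_classify(mk(1.95, 0.04))$composition, "AA_DELETION")
  expect_equal(window_classify(mk(1.02, 2.97))$composition, "ABBB")
  expect_equal(window_classify(mk(3.05, 1.94))$composition, "TRISOMY_A")
  # out of tolerance on one axis -> unclassified
  expect_equal(window_classify(mk(2.5, 2.0))$composition, "UNCLASSIFIED")
  # too few supporting sites -> unclassified
  expect_equal(window_classify(mk(2, 2), min_sites = 60)$composition,
               "UNCLASSIFIED")
  expect_error(window_classify(mk(2, 2), window_size = 0), "positive")
})

test_that("classification mirrors under an A/B swap of the raw counts", {
  ped <- generate_pedigree(2, 2, list(gen_sizes = c(2L, 4L),
                                      expansions = list()))
  spec <- data.frame(plant = "T.1_G1", kind = c("ABBB", "DELETION_B", "AAAA"),
                     chrom_set = 1:3, start = 0, end = 10e6, heritable = FALSE)
  tr <- implant_events(ped, spec)
  sites <- make_diagnostic_sites(n_sets = 4, sites_per_set = 2000, seed = 23)
  cnt <- simulate_wgs("T.1_G1", tr, sites, depth = 30, seed = 23)
  base <- cnt[cnt$sample == "synthetic_tetraploid", ]
  smp <- cnt[cnt$sample == "T.1_G1", ]
  win <- window_classify(normalize_counts(smp, base))
  swap <- function(x) { tmp <- x$raw_a; x$raw_a <- x$raw_b; x$raw_b <- tmp; x }
  win_m <- window_classify(normalize_counts(swap(smp), swap(base)))
  expect_equal(win_m$composition, mirror_composition(win$composition))
})

test_that("event windows at 30x recover the implanted composition", {
  ped <- generate_pedigree(2, 2, list(gen_sizes = c(2L, 4L),
                                      expansions = list()))
  spec <- data.frame(plant = "T.1_G1",
                     kind = c("ABBB", "DELETION_B", "BBBB"),
                     chrom_set = 1:3,
                     start = c(0, 0, 4e6), end = c(10e6, 6e6, 10e6),
                     heritable = FALSE)
  tr <- implant_events(ped, spec)
  sites <- make_diagnostic_sites(n_sets = 4, seed = 29)
  cnt <- simulate_wgs("T.1_G1", tr, sites, depth = 30, seed = 29)
  nm <- normalize_counts(cnt[cnt$sample == "T.1_G1", ],
                         cnt[cnt$sample == "synthetic_tetraploid", ])
  win <- window_classify(nm)
  truth_of <- function(cs, s, e) {
    hit <- spec$chrom_set == cs & spec$start <= s & spec$end >= e
    if (any(hit)) {
      k <- spec$kind[hit][1]
      if (k == "DELETION_B") "AA_DELETION" else k
    } else "AABB"
  }
  want <- mapply(truth_of, win$chrom_set, win$start, win$end)
  expect_gte(mean(win$composition == want), 0.99)
})

test_that("reconciliation confirms exchanges and relabels miscalled deletions", {
  arr <- data.frame(plant = "p", chrom_set = c(1L, 2L, 3L),
                    start = c(0, 0, 0), end = c(2e6, 10e6, 1e6),
                    composition = c("AAAB", "ABBB", "AAAB"),
                    status = "novel")
  win <- rbind(
    data.frame(chrom_set = 1L, start = (0:1) * 1e6, end = (1:2) * 1e6,
               n_sites = 100, norm_a = 2, norm_b = 0,
               composition = "AA_DELETION"),
    data.frame(chrom_set = 2L, start = (0:9) * 1e6, end = (1:10) * 1e6,
               n_sites = 100, norm_a = 1, norm_b = 3, composition = "ABBB")
  )
  rec <- reconcile(arr, win, plant = "p")
  expect_equal(rec$agreement, c("relabelled", "confirmed", "conflict"))
  expect_equal(rec$final_call[1], "DELETION_B")
  expect_equal(rec$final_call[2], "ABBB")
  expect_equal(rec$final_call[3], "AAAB")   # no overlap: kept, flagged
  expect_error(reconcile(arr, win, plant = "absent"), "absent")
  expect_error(reconcile(arr, win[0, ], plant = "p"), "windows")
})
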
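test_that("mirna_record validates intervals against the precursor", {
  pre <- strrep("ACGT", 15L)  # 60 nt
  rec <- mirna_record("syn-mir-a", pre, mature = c(6, 27), star = c(34, 55))
  expect_identical(rec$mature$start, 6L)
  expect_identical(rec$star$end, 55L)
  expect_error(mirna_record("x", pre, mature = c(0, 20)), "outside")
  expect_error(mirna_record("x", pre, mature = c(50, 61)), "outside")
  expect_error(mirna_record("x", pre, mature = c(6, 27), star = c(20, 40)),
               "overlap")
  expect_error(mirna_record("x", pre, mature = NULL), "mature")
  # RNA-alphabet precursors are stored as DNA
  rec2 <- mirna_record("x", "ACGUACGUACGUACGUACGUA", mature = c(1, 10))
  expect_false(grepl("U", rec2$precursor))
})

test_that("arm_sums pools starts over tile-start positions inside each arm", {
  pre <- random_reference(60L, seed = 91L)
  # block of signal inside the mature arm only
  starts <- rep(0L, 41L)
  starts[6:8] <- 10L
  prof <- manual_profile(starts, k = 20, n = 60, query = pre)
  rec <- mirna_record("syn-mir-b", pre, mature = c(6, 27), star = c(34, 55))
  s <- arm_sums(prof, rec)
  expect_identical(s, list(N_m = 30L, N_s = 0L, total = 30L))

  # uniform profile: the 3' star arm loses the k-1 trailing positions that
  # have no tile start
  prof_u <- manual_profile(rep(1L, 41L), k = 20, n = 60, query = pre)
  rec_u <- mirna_record("syn-mir-c", pre, mature = c(1, 20), star = c(41, 60))
  s_u <- arm_sums(prof_u, rec_u)
  expect_identical(s_u, list(N_m = 20L, N_s = 1L, total = 41L))

  # zero profile
  s0 <- arm_sums(manual_profile(rep(0L, 41L), 20, 60, query = pre), rec)
  expect_identical(s0, list(N_m = 0L, N_s = 0L, total = 0L))

  expect_error(arm_sums(manual_profile(rep(1L, 30L), 20, 49), rec), "length")
})

test_that("arm_sums is additive over split intervals and pools 5p/3p matures", {
  pre <- random_reference(60L, seed = 92L)
  starts <- sample(0:5, 41L, replace = TRUE)
  prof <- manual_profile(starts, k = 20, n = 60, query = pre)
  whole <- mirna_record("m", pre, mature = c(6, 27))
  split <- mirna_record("m", pre, mature = list(c(6, 15), c(16, 27)))
  expect_identical(arm_sums(prof, whole)$N_m, arm_sums(prof, split)$N_m)
  both_arms <- mirna_record("m", pre, mature = list(c(6, 27), c(34, 55)))
  expect_identical(arm_sums(prof, both_arms)$N_m,
                   arm_sums(prof, mirna_record("m", pre, mature = c(6, 27),
                                               star = c(34, 55)))$N_m +
                   arm_sums(prof, mirna_record("m", pre, mature = c(34, 55),
                                               star = c(6, 27)))$N_m)
})

test_that("the mis-annotation flag uses a strict 95% arm-share threshold", {
  pre <- random_reference(120L, seed = 93L)
  rec <- mirna_record("syn-mir-d", pre, mature = c(1, 22), star = c(60, 81))
  k <- 20L
  n_tiles <- 120L - k + 1L
  profile_with_share <- function(arm_hits, off_hits) {
    starts <- rep(0L, n_tiles)
    starts[1L] <- arm_hits        # inside mature
    starts[40L] <- off_hits       # in the loop, outside both arms
    manual_profile(starts, k, 120L, query = pre)
  }
  # all signal on the arms
  a <- assess_annotation(profile_with_share(100L, 0L), rec)
  expect_identical(a$arm_fraction, 1)
  expect_false(a$flagged)
  # 90% share: flagged
  expect_true(assess_annotation(profile_with_share(90L, 10L), rec)$flagged)
  # exactly 95%: strict inequality, not flagged
  at_thr <- assess_annotation(profile_with_share(95L, 5L), rec)
  expect_identical(at_thr$arm_fraction, 0.95)
  expect_false(at_thr$flagged)
  # just below
  expect_true(assess_annotation(profile_with_share(9499L, 501L), rec)$flagged)
  # zero total: indeterminate, never TRUE
  z <- assess_annotation(profile_with_share(0L, 0L), rec)
  expect_true(is.na(z$flagged))
  expect_true(is.na(z$arm_fraction))
  # custom threshold
  expect_false(assess_annotation(profile_with_share(90L, 10L), rec,
                                 threshold = 0.9)$flagged)
  expect_error(assess_annotation(profile_with_share(1L, 0L), rec,
                                 threshold = 0), "threshold")
})

test_that("the flag is a step function of arm share and is scale-invariant", {
  pre <- random_reference(120L, seed = 94L)
  rec <- mirna_record("syn-mir-e", pre, mature = c(1, 22), star = c(60, 81))
  total <- 1000L
  for (arm in seq(0L, total, by = 50L)) {
    starts <- rep(0L, 101L)
    starts[1L] <- arm
    starts[40L] <- total - arm
    share <- arm / total
    for (mult in c(1L, 7L)) {
      a <- assess_annotation(manual_profile(starts * mult, 20, 120, query = pre),
                             rec)
      expect_identical(a$flagged, share < 0.95)
      expect_equal(a$arm_fraction, share)
    }
  }
})

test_that("canonical arm-only libraries pass and uniform hairpins are flagged at k = 20", {
  for (seed in c(5L, 17L)) {
    can <- mirna_fixture("canonical", seed = seed)
    a_can <- assess_annotation(
      tile_query(build_index(can$library), can$record$precursor, 20L),
      can$record)
    expect_false(a_can$flagged)
    expect_identical(a_can$arm_fraction, 1)

    uni <- mirna_fixture("uniform", seed = seed)
    a_uni <- assess_annotation(
      tile_query(build_index(uni$library), uni$record$precursor, 20L),
      uni$record)
    expect_true(a_uni$flagged)
    expect_lt(a_uni$arm_fraction, 0.95)
  }
})

test_that("mirna_summary ranks miRNAs by total hits with deterministic tie-breaks", {
  fx <- mirna_fixture("canonical", seed = 23L)
  # decoy precursors sharing no reads with the library
  decoy1 <- mirna_record("syn-mir-z1", random_reference(72L, seed = 101L),
                         mature = c(6, 27), star = c(42, 63))
  decoy2 <- mirna_record("syn-mir-z2", random_reference(72L, seed = 102L),
                         mature = c(6, 27), star = c(42, 63))
  short <- mirna_record("syn-mir-short", random_reference(15L, seed = 103L),
                        mature = c(1, 10))
  idx <- build_index(fx$library)
  rep_ <- mirna_summary(idx, list(decoy2, fx$record, decoy1, short), k = 20L)
  expect_identical(rep_$mirna_id[1L], fx$record$mirna_id)
  expect_gt(rep_$total[1L], 0L)
  # zero-total decoys: tie broken by id, flags indeterminate
  expect_identical(rep_$mirna_id[2:3], c("syn-mir-z1", "syn-mir-z2"))
  expect_identical(rep_$total[2:3], c(0L, 0L))
  expect_true(all(is.na(rep_$flagged[2:3])))
  # precursor shorter than k is reported, not a crash
  shrt <- rep_[rep_$mirna_id == "syn-mir-short", ]
  expect_false(shrt$evaluated)
  expect_true(is.na(shrt$total))
  # equal totals order by mirna_id
  rep_tie <- mirna_summary(idx, list(decoy2, decoy1), k = 20L)
  expect_identical(rep_tie$mirna_id, c("syn-mir-z1", "syn-mir-z2"))
})

test_that("libraries_expressing returns libraries by mature-arm hits", {
  fx <- mirna_fixture("canonical", seed = 29L)
  planted_idx <- build_index(fx$library)
  barren_idx <- build_index(read_library(
    random_reads(10L, len_range = c(18L, 22L)), "barren"))
  idxs <- list(planted = planted_idx, barren = barren_idx)
  hits <- libraries_expressing(idxs, fx$record, k = 20L, min_hits = 1L)
  expect_identical(hits$library_id, "planted")
  expect_gt(hits$mature_hits[1L], 0L)
  # min_hits above any library's N_m
  none <- libraries_expressing(idxs, fx$record, k = 20L, min_hits = 10^6)
  expect_identical(nrow(none), 0L)
  # identical content: stable order by library_id on tied N_m
  twins <- list(b_lib = planted_idx, a_lib = planted_idx)
  tied <- libraries_expressing(twins, fx$record, k = 20L)
  expect_identical(tied$library_id, c("a_lib", "b_lib"))
  expect_identical(tied$mature_hits[1L], tied$mature_hits[2L])
  expect_error(libraries_expressing(idxs, fx$record, min_hits = 0L),
               "min_hits")
  empty <- libraries_expressing(list(), fx$record)
  expect_identical(nrow(empty), 0L)
})

test_that("miRNA records round-trip through the TSV and FASTA+TSV readers", {
  pre1 <- random_reference(72L, seed = 111L)
  pre2 <- random_reference(80L, seed = 112L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "mirna_id\tspecies\tprecursor_seq\tmature_intervals\tstar_intervals",
    sprintf("syn-mir-1\tsynthetic\t%s\t6-27\t42-63", pre1),
    sprintf("syn-mir-2\tsynthetic\t%s\t3-24,50-71\t", pre2)), tsv)
  recs <- read_mirna_tsv(tsv)
  expect_length(recs, 2L)
  expect_identical(recs[[1L]]$precursor, pre1)
  expect_identical(recs[[2L]]$mature$start, c(3L, 50L))
  expect_identical(nrow(recs[[2L]]$star), 0L)

  fa <- withr::local_tempfile(fileext = ".fa")
  iv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">syn-mir-1 desc", pre1), fa)
  writeLines(c("mirna_id\tarm\tstart\tend",
               "syn-mir-1\tmature\t6\t27",
               "syn-mir-1\tstar\t42\t63"), iv)
  recs2 <- read_mirna_fasta(fa, iv, species = "synthetic")
  expect_identical(recs2[[1L]]$mature, recs[[1L]]$mature)
  expect_identical(recs2[[1L]]$star$start, 42L)

  writeLines(c("mirna_id\tarm\tstart\tend", "syn-mir-1\tloop\t30\t40"), iv)
  expect_error(read_mirna_fasta(fa, iv), "arm")
})
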
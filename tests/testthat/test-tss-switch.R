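# two-TSS plus-strand locus with known segment signal: seg1 [100,600) at
# 10 cov, seg2 [600,1100) at 14 cov (10 read-through + 4 from TSS2)
two_tss_tx <- function(strand = "+") {
  if (strand == "+") {
    tibble::tibble(
      transcript_id = c("L_TV1", "L_TV2"), locus_id = "L",
      chrom = "chr1", start = c(100, 600), end = 1100, strand = "+",
      tss = c(100, 600)
    )
  } else {
    # mirror through position 1200: TSSs at 1099 and 599, shared 3' end at 0
    tibble::tibble(
      transcript_id = c("L_TV1", "L_TV2"), locus_id = "L",
      chrom = "chr1", start = 100, end = c(1100, 600), strand = "-",
      tss = c(1099, 599)
    )
  }
}

test_that("unique segments tile a plus-strand locus from each TSS", {
  segs <- tss_segments(two_tss_tx("+"))
  expect_equal(segs$start, c(100, 600))
  expect_equal(segs$end, c(600, 1100))
  expect_equal(segs$tv, c(1, 2))
})

test_that("minus-strand loci mirror the plus-strand segmentation", {
  segs <- tss_segments(two_tss_tx("-"))
  # TV1 = most upstream in transcription direction = highest coordinate
  expect_equal(segs$tv, c(1, 2))
  expect_equal(segs$start, c(600, 100))
  expect_equal(segs$end, c(1100, 600))
  # same segment lengths as the reflected plus-strand locus
  plus <- tss_segments(two_tss_tx("+"))
  expect_equal(segs$end - segs$start, plus$end - plus$start)
})

test_that("unequal 3' ends are an annotation error", {
  bad <- dplyr::mutate(two_tss_tx("+"), end = c(1100, 1000))
  expect_error(tss_segments(bad), "3' end")
})

test_that("more than six TSSs warns", {
  k <- 7
  tx <- tibble::tibble(
    transcript_id = sprintf("L_TV%d", 1:k), locus_id = "L", chrom = "chr1",
    start = seq(0, by = 100, length.out = k), end = 1000, strand = "+",
    tss = seq(0, by = 100, length.out = k)
  )
  expect_warning(tss_segments(tx), "2-6")
})

test_that("profiles carry the adjacent-difference statistic and activities", {
  tx <- two_tss_tx("+")
  runs <- tibble::tibble(chrom = "chr1", start = c(100, 600),
                         end = c(600, 1100), value = c(10, 14),
                         strand = "+")
  tracks <- list(s1 = signal_track(runs, library_size = 1e6))
  samples <- tibble::tibble(sample = "s1", group = "g1")
  prof <- build_tss_profiles(tx, tracks, samples)
  # segment FPKM: 10*500/(0.5kb*1M/1e6) = 10000 etc.
  expect_equal(prof$segment_fpkm, c(10000, 14000))
  expect_equal(prof$delta, c(10000 - 14000, NA))
  # initiation: TSS1 10000, TSS2 = 14000 - 10000 (read-through removed)
  expect_equal(prof$activity, c(10000, 4000))
  expect_equal(prof$dominant, c(TRUE, FALSE))
})

test_that("minus-strand profiles equal the coordinate-reflected plus profiles", {
  runs_p <- tibble::tibble(chrom = "chr1", start = c(100, 600),
                           end = c(600, 1100), value = c(10, 14),
                           strand = "+")
  runs_m <- tibble::tibble(chrom = "chr1", start = c(1200 - 600, 1200 - 1100),
                           end = c(1200 - 100, 1200 - 600),
                           value = c(10, 14), strand = "-")
  samples <- tibble::tibble(sample = "s1", group = "g1")
  prof_p <- build_tss_profiles(
    two_tss_tx("+"), list(s1 = signal_track(runs_p, library_size = 1e6)),
    samples)
  tx_m <- tibble::tibble(
    transcript_id = c("L_TV1", "L_TV2"), locus_id = "L", chrom = "chr1",
    start = 100, end = c(1100, 600), strand = "-", tss = c(1099, 599)
  )
  prof_m <- build_tss_profiles(
    tx_m, list(s1 = signal_track(runs_m, library_size = 1e6)), samples)
  expect_equal(prof_m$segment_fpkm, prof_p$segment_fpkm)
  expect_equal(prof_m$activity, prof_p$activity)
})

test_that("uncentered correlation distance has its closed-form values", {
  expect_equal(uncentered_corr_distance(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(uncentered_corr_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(uncentered_corr_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2))
  expect_equal(uncentered_corr_distance(c(1, 2), c(-1, -2)), 2)
  expect_error(uncentered_corr_distance(c(0, 0), c(1, 2)), "zero")
  expect_error(uncentered_corr_distance(c(1, 2, 3), c(1, 2)), "length")
})

test_that("UPGMA merge heights equal the naive O(n^3) oracle", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(4:10, 1)
    mat <- matrix(rnorm(n * 6), n)
    rownames(mat) <- sprintf("v%d", seq_len(n))
    hc <- average_linkage_cluster(mat)
    want <- brute_linkage_heights(uncentered_dist(mat), "average")
    expect_equal(sort(hc$height), want, tolerance = 1e-10)
  }
})

test_that("identical vectors merge at height zero and permutation is isomorphic", {
  mat <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 1, 0))
  hc <- average_linkage_cluster(mat)
  expect_equal(min(hc$height), 0)
  set.seed(4)
  mat2 <- matrix(rnorm(8 * 5), 8, dimnames = list(letters[1:8], NULL))
  perm <- sample(8)
  h1 <- average_linkage_cluster(mat2)
  h2 <- average_linkage_cluster(mat2[perm, ])
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-12)
  # same leaf partition at every height
  expect_equal(
    lapply(1:7, function(k) unname(sort(vapply(split(rownames(mat2),
      stats::cutree(h1, k)), function(m) paste(sort(m), collapse = "+"), "")))),
    lapply(1:7, function(k) unname(sort(vapply(split(rownames(mat2)[perm],
      stats::cutree(h2, k)), function(m) paste(sort(m), collapse = "+"), ""))))
  )
})

test_that("switch calls require a dominant flip above the activity floor", {
  prof <- tibble::tibble(
    locus_id = "L", group = rep(c("A", "B"), each = 2), tv = c(1, 2, 1, 2),
    k = 2, segment_fpkm = c(10, 11, 1, 11), delta = NA_real_,
    activity = c(10, 1, 1, 10), dominant = c(TRUE, FALSE, FALSE, TRUE)
  )
  sw <- detect_tss_switching(prof)
  expect_true(sw$switching)
  expect_equal(sw$dom_A, 1)
  expect_equal(sw$dom_B, 2)

  same_dom <- dplyr::mutate(prof,
    activity = c(10, 1, 8, 2), dominant = c(TRUE, FALSE, TRUE, FALSE))
  expect_false(detect_tss_switching(same_dom)$switching)

  weak <- dplyr::mutate(prof, activity = c(10, 1, 0.2, 0.9),
                        dominant = c(TRUE, FALSE, FALSE, TRUE))
  expect_false(detect_tss_switching(weak)$switching)
  expect_error(detect_tss_switching(dplyr::filter(prof, group == "A")),
               "2 groups")
})

test_that("segment tiling conserves whole-locus signal", {
  b <- shared_bundle()
  tx <- dplyr::filter(b$transcripts, class == "pri_miRNA_TV")
  segs <- tss_segments(tx)
  tr <- b$tracks[[1]]
  seg_q <- quantify(dplyr::rename(segs, feature_id = segment_id), tr)
  loci <- tx |>
    dplyr::group_by(locus_id) |>
    dplyr::summarise(chrom = chrom[1], start = min(start), end = max(end),
                     strand = strand[1])
  loc_q <- quantify(dplyr::rename(loci, feature_id = locus_id), tr)
  agg <- tapply(seg_q$count, segs$locus_id, sum)
  expect_equal(as.numeric(agg[loc_q$feature_id]), loc_q$count)
})

test_that("planted dominant-TSS flips are recovered without false calls", {
  b <- shared_bundle()
  prof <- build_tss_profiles(
    dplyr::filter(b$transcripts, class == "pri_miRNA_TV"),
    b$tracks, b$samples)
  sw <- detect_tss_switching(prof)
  truth <- b$truth |>
    dplyr::filter(class == "pri_miRNA_TV") |>
    dplyr::distinct(locus_id, switching, dom_iPSC, dom_PHH)
  cmp <- dplyr::left_join(sw, truth, by = "locus_id",
                          suffix = c("_call", "_truth"))
  expect_true(all(cmp$switching_call == cmp$switching_truth))
  expect_equal(cmp$dom_iPSC_call, cmp$dom_iPSC_truth)
  expect_equal(cmp$dom_PHH_call, cmp$dom_PHH_truth)
})

test_that("delta vectors are invariant under uniform library rescaling", {
  b <- shared_bundle()
  tx <- dplyr::filter(b$transcripts, class == "pri_miRNA_TV")
  prof1 <- build_tss_profiles(tx, b$tracks[1:2],
                              b$samples[1:2, c("sample", "group")])
  scaled_tracks <- lapply(b$tracks[1:2], function(t) {
    signal_track(t$runs, library_size = t$library_size * 7)
  })
  prof2 <- build_tss_profiles(tx, scaled_tracks,
                              b$samples[1:2, c("sample", "group")])
  expect_equal(prof2$delta, prof1$delta / 7)
  expect_equal(prof2$dominant, prof1$dominant)
})
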
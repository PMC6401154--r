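consensus_pwm <- function(cons, p = 0.97) {
  bases <- c("A", "C", "G", "T")
  w <- nchar(cons)
  m <- matrix((1 - p) / 3, 4, w, dimnames = list(bases, NULL))
  m[cbind(match(strsplit(cons, "")[[1]], bases), seq_len(w))] <- p
  m
}

test_that("the consensus sequence scores the closed-form maximum", {
  pwm <- consensus_pwm("ACGTAC")
  hits <- scan_pwm("ACGTAC", pwm)
  expect_equal(nrow(hits[hits$strand == "+", ]), 1)
  expect_equal(hits$score[hits$strand == "+"], 6 * log2(0.97 / 0.25))
  # and the reverse complement scores the same on the minus strand
  rc_hits <- scan_pwm(revcomp("ACGTAC"), pwm)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$score, 6 * log2(0.97 / 0.25))
})

test_that("N-containing windows and short sequences yield no hits", {
  pwm <- consensus_pwm("ACGTAC")
  expect_equal(nrow(scan_pwm("NNNNNNNNNN", pwm)), 0)
  expect_equal(nrow(scan_pwm("ACG", pwm)), 0)
  expect_equal(nrow(scan_pwm("ACGNACGTAC", pwm)), 1)  # only the clean window
})

test_that("vectorized scanning equals the naive two-strand oracle", {
  set.seed(61)
  for (rep in 1:10) {
    pwm <- random_pwm(sample(4:8, 1))
    seq <- random_dna(300)
    # permissive threshold so both hit and non-hit windows are compared
    th <- 0.5 * sum(apply(log2(pwm / 0.25), 2, max))
    got <- scan_pwm(seq, pwm, threshold = th)
    want <- brute_scan(seq, pwm, threshold = th)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
  set.seed(62)
  pwm <- random_pwm(6)
  seq <- random_dna(200)
  th <- 0.4 * sum(apply(log2(pwm / 0.25), 2, max))
  fwd <- scan_pwm(seq, pwm, threshold = th)
  rev <- scan_pwm(revcomp(seq), pwm, threshold = th)
  remapped <- tibble::tibble(
    position = 200 - 6 - rev$position,
    strand = ifelse(rev$strand == "+", "-", "+"),
    score = rev$score
  )
  remapped <- remapped[order(remapped$position, remapped$strand), ]
  expect_equal(as.data.frame(remapped),
               as.data.frame(fwd[, c("position", "strand", "score")]))
})

test_that("planted enrichment reaches the exact hypergeometric tail", {
  set.seed(63)
  pwm <- list(M = consensus_pwm("ACGTACGT", 0.91))
  plant <- function(n, frac) {
    vapply(seq_len(n), function(i) {
      s <- random_dna(100)
      if (i <= n * frac) substr(s, 40, 47) <- "ACGTACGT"
      s
    }, "")
  }
  target <- stats::setNames(plant(50, 0.9), paste0("t", 1:50))
  backg <- stats::setNames(plant(500, 0.05), paste0("b", 1:500))
  res <- motif_enrichment(target, backg, pwm, set_name = "up")
  expect_lt(res$p_value, 1e-10)
  expect_gte(res$target_pct, 90)
  expect_lte(res$background_pct, 10)
  # p agrees with direct phyper on the counted hits
  expect_equal(res$p_value,
               phyper(res$k - 1, res$K, res$N - res$K, res$n,
                      lower.tail = FALSE))
})

test_that("a motif absent everywhere gives fractions 0 and p = 1", {
  pwm <- list(M = consensus_pwm("ACGTACGT", 0.97))
  target <- stats::setNames(rep("TTTTTTTTTTTTTTTT", 5), paste0("t", 1:5))
  backg <- stats::setNames(rep("TTTTTTTTTTTTTTTT", 5), paste0("b", 1:5))
  res <- motif_enrichment(target, backg, pwm)
  expect_equal(res$target_pct, 0)
  expect_equal(res$background_pct, 0)
  expect_equal(res$p_value, 1)
})

test_that("enrichment is invariant to sequence order within sets", {
  set.seed(64)
  pwm <- list(M = random_pwm(6))
  target <- stats::setNames(vapply(1:20, function(i) random_dna(80), ""),
                            paste0("t", 1:20))
  backg <- stats::setNames(vapply(1:40, function(i) random_dna(80), ""),
                           paste0("b", 1:40))
  r1 <- motif_enrichment(target, backg, pwm)
  r2 <- motif_enrichment(sample(target), sample(backg), pwm)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$target_pct, r2$target_pct)
})

test_that("disjointness and empty targets are enforced", {
  pwm <- list(M = random_pwm(6))
  s <- stats::setNames(c("ACGTACGTACGT"), "x")
  expect_error(motif_enrichment(character(), s, pwm), "empty")
  expect_error(motif_enrichment(s, s, pwm), "disjoint")
})

test_that("monotone TF expression vs motif enrichment gives rho = +/-1", {
  tf <- tibble::tibble(tf_id = c("TFA", "TFB"),
                       s1 = c(1, 8), s2 = c(2, 6), s3 = c(5, 3), s4 = c(9, 2))
  mo <- tibble::tibble(motif = c("MA", "MB"),
                       s1 = c(10, 50), s2 = c(20, 40), s3 = c(30, 30),
                       s4 = c(80, 10))
  map <- tibble::tibble(tf_id = c("TFA", "TFB"), motif = c("MA", "MB"))
  res <- tf_motif_correlation(tf, mo, map)
  expect_equal(res$pairs$rho, c(1, 1))
  # anti-monotone pairing
  map2 <- tibble::tibble(tf_id = c("TFA", "TFB"), motif = c("MB", "MA"))
  res2 <- tf_motif_correlation(tf, mo, map2)
  expect_equal(res2$pairs$rho, c(-1, -1))
  # unmapped TF and too few sets are errors
  expect_error(tf_motif_correlation(tf, mo, map[1, ]), "without a motif")
  expect_error(tf_motif_correlation(tf[, 1:3], mo[, 1:3], map), "3 condition")
})

test_that("complete-linkage Spearman clustering matches the naive oracle", {
  set.seed(65)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    mat <- matrix(rnorm(n * 5), n, dimnames = list(sprintf("r%d", 1:n), NULL))
    d <- nascentscape:::spearman_dist(mat)
    hc <- hclust(d, method = "complete")
    expect_equal(sort(hc$height), brute_linkage_heights(d, "complete"),
                 tolerance = 1e-10)
  }
})

test_that("planted TF-motif concordance yields positive rho on the bundle", {
  b <- shared_bundle()
  es <- shared_expression()
  tr <- b$truth
  # condition sets: the four up/down x group quadrants built from group
  # means; expression side uses the TF genes, enrichment side their motifs
  gm <- group_means(es)
  tf_ids <- tr$feature_id[tr$is_tf]
  tf_expr <- dplyr::rename(gm[gm$feature_id %in% tf_ids, ], tf_id = feature_id)
  lnc <- dplyr::filter(b$transcripts, class == "lncRNA")
  sets <- list(
    iPSC_high = tr$feature_id[tr$class == "lncRNA" & tr$de_status == "down"],
    PHH_high = tr$feature_id[tr$class == "lncRNA" & tr$de_status == "up"]
  )
  win <- function(ids) {
    extract_tss_windows(b$motifs_go$genome,
                        dplyr::rename(dplyr::filter(lnc, transcript_id %in% ids),
                                      feature_id = transcript_id))
  }
  ns_win <- win(tr$feature_id[tr$class == "lncRNA" & tr$de_status == "ns"])
  enr <- dplyr::bind_rows(lapply(names(sets), function(s) {
    tibble::as_tibble(motif_enrichment(win(sets[[s]]), ns_win,
                                       b$motifs_go$pwms, set_name = s))
  }))
  motif_wide <- tidyr::pivot_wider(enr[, c("motif", "set", "target_pct")],
                                   names_from = set, values_from = target_pct)
  # expression per condition set: iPSC mean for the iPSC-high set etc.
  tf_sets <- tibble::tibble(tf_id = tf_expr$tf_id,
                            iPSC_high = tf_expr$iPSC, PHH_high = tf_expr$PHH)
  # with two condition sets Spearman is a sign check: compute directly
  dir_expr <- sign(tf_sets$PHH_high - tf_sets$iPSC_high)
  m <- match(b$motifs_go$tf2motif$motif[match(tf_sets$tf_id,
                                              b$motifs_go$tf2motif$tf_id)],
             motif_wide$motif)
  dir_enr <- sign(motif_wide$PHH_high[m] - motif_wide$iPSC_high[m])
  expect_gte(mean(dir_expr == dir_enr), 0.9)
})
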
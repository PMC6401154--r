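#' Scan a sequence with a PWM on both strands
#'
#' Log-odds score per window: `sum(log2(p_base / q_base))` against the
#' background base composition, on the forward sequence and its reverse
#' complement (reported as minus-strand hits at the forward-strand window
#' start). Windows containing `N` are skipped. A window is a hit iff its
#' score reaches `threshold`; the default is 80% of the PWM's maximum
#' achievable score.
#'
#' @param sequence A character scalar over `A,C,G,T,N`.
#' @param pwm 4 x width probability matrix (rows A,C,G,T).
#' @param background Background base probabilities (default uniform).
#' @param threshold Score threshold in bits; `NULL` uses
#'   `0.8 * max score`.
#' @return Tibble `position` (0-based window start), `strand`, `score`,
#'   sorted by position; empty when the sequence is shorter than the PWM.
#' @export
scan_pwm <- function(sequence, pwm, background = rep(0.25, 4),
                     threshold = NULL) {
  validate_pwm(pwm)
  w <- ncol(pwm)
  lo <- log2(pwm / background)
  threshold <- threshold %||% (0.8 * sum(apply(lo, 2, max)))
  seq_up <- toupper(sequence)
  L <- nchar(seq_up)
  empty <- tibble(position = integer(), strand = character(), score = double())
  if (L < w) return(empty)
  code <- match(strsplit(seq_up, "")[[1]], c("A", "C", "G", "T"))
  n_win <- L - w + 1
  score_with <- function(mat_lo) {
    s <- rep(0, n_win)
    ok <- rep(TRUE, n_win)
    for (j in seq_len(w)) {
      b <- code[j:(j + n_win - 1)]
      ok <- ok & !is.na(b)
      s <- s + ifelse(is.na(b), 0, mat_lo[cbind(b, j)])
    }
    s[!ok] <- -Inf
    s
  }
  fwd <- score_with(lo)
  # minus strand: score the reverse complement of each window, equivalent to
  # scanning with the reverse-complemented PWM
  lo_rc <- lo[4:1, w:1, drop = FALSE]
  rev_s <- score_with(lo_rc)
  hits <- bind_rows(
    tibble(position = which(fwd >= threshold) - 1L, strand = "+",
           score = fwd[fwd >= threshold]),
    tibble(position = which(rev_s >= threshold) - 1L, strand = "-",
           score = rev_s[rev_s >= threshold])
  )
  arrange(hits, .data$position, .data$strand)
}

#' Extract TSS-window sequences from a genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @param features Tibble with `chrom, tss` and an id column
#'   (`feature_id`/first column).
#' @param flank Half-window in bp (default 200, core-promoter scale).
#' @return Named character vector of `2*flank` windows (clipped at
#'   chromosome ends), plus-strand orientation.
#' @export
extract_tss_windows <- function(genome, features, flank = 200) {
  id <- col_or(features, "feature_id", features[[1]])
  seqs <- vapply(seq_len(nrow(features)), function(i) {
    chrom_seq <- genome[[features$chrom[i]]]
    if (is.null(chrom_seq)) abort(sprintf("chrom %s absent from genome",
                                          features$chrom[i]))
    a <- max(0, features$tss[i] - flank)
    b <- min(nchar(chrom_seq), features$tss[i] + flank)
    substr(chrom_seq, a + 1, b)
  }, "")
  stats::setNames(seqs, id)
}

#' Motif enrichment in target vs background TSS windows
#'
#' For each PWM, the fraction of sequences with at least one hit is computed
#' in the target and background sets, and over-representation of
#' hit-containing sequences in the target among the union is tested with an
#' upper-tail hypergeometric p, BH-adjusted across motifs. `count_level =
#' TRUE` switches the reported percentages to hits per 100 sequences (the
#' p-value stays sequence-level).
#'
#' @param target_seqs,background_seqs Named character vectors of sequences;
#'   the two sets must be disjoint.
#' @param pwms Named list of PWMs.
#' @param set_name Label stored in the result (e.g. "up", "down").
#' @param threshold,background Passed to [scan_pwm()].
#' @param count_level Report hit-count percentages instead of
#'   sequence-level percentages.
#' @return A `motif_enrichment` tibble: `motif, set, target_pct,
#'   background_pct, k, n, K, N, p_value, adj_p`.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwms,
                             set_name = "target", threshold = NULL,
                             background = rep(0.25, 4),
                             count_level = FALSE) {
  if (length(target_seqs) == 0) abort("empty target set")
  if (length(intersect(names(target_seqs), names(background_seqs))) > 0) {
    abort("target and background sets must be disjoint")
  }
  res <- lapply(names(pwms), function(m) {
    hit_n <- function(seqs) {
      vapply(seqs, function(s) {
        nrow(scan_pwm(s, pwms[[m]], background = background,
                      threshold = threshold))
      }, 0L)
    }
    th <- hit_n(target_seqs)
    bh <- hit_n(background_seqs)
    k <- sum(th > 0)
    K <- k + sum(bh > 0)
    n <- length(target_seqs)
    N <- length(target_seqs) + length(background_seqs)
    tibble(
      motif = m, set = set_name,
      target_pct = if (count_level) 100 * sum(th) / n else 100 * k / n,
      background_pct = if (count_level) {
        100 * sum(bh) / max(1, length(background_seqs))
      } else {
        100 * sum(bh > 0) / max(1, length(background_seqs))
      },
      k = k, n = n, K = K, N = N,
      p_value = if (K == 0) 1 else phyper(k - 1, K, N - K, n,
                                          lower.tail = FALSE)
    )
  })
  out <- bind_rows(res) |>
    mutate(adj_p = bh_adjust(.data$p_value))
  structure(out, class = c("motif_enrichment", class(out)))
}

#' Correlate TF expression with motif enrichment across condition sets
#'
#' Both inputs are wide tibbles over the same ordered condition sets
#' (columns): TF expression rows (RPKM per set) and motif enrichment rows
#' (hit percentage per set). Each is min-max scaled to \[-1, 1\] per row
#' ([row_normalize()]); each TF-motif pair from the mapping gets a Spearman
#' rank correlation across sets; rows and columns of both matrices are
#' clustered with complete linkage on `1 - Spearman rho`.
#'
#' @param tf_expr Wide tibble: `tf_id` + one column per condition set.
#' @param motif_enr Wide tibble: `motif` + one column per condition set
#'   (same order).
#' @param tf2motif Tibble `tf_id, motif` (many-to-many allowed).
#' @return List with `pairs` (tf_id, motif, rho), `tf_scaled`,
#'   `motif_scaled`, and leaf orders `tf_order`, `motif_order`,
#'   `set_order`.
#' @export
tf_motif_correlation <- function(tf_expr, motif_enr, tf2motif) {
  sets <- names(tf_expr)[-1]
  if (!identical(sets, names(motif_enr)[-1])) {
    abort("tf_expr and motif_enr must share the same ordered condition sets")
  }
  if (length(sets) < 3) abort("need >= 3 condition sets for correlation")
  unmapped <- setdiff(tf_expr[[1]], tf2motif$tf_id)
  if (length(unmapped) > 0) {
    abort(paste("TFs without a motif mapping:", paste(unmapped, collapse = ", ")))
  }
  tf_s <- row_normalize(tf_expr)
  mo_s <- row_normalize(motif_enr)
  tmat <- as.matrix(tf_s[, -1]); rownames(tmat) <- tf_s[[1]]
  mmat <- as.matrix(mo_s[, -1]); rownames(mmat) <- mo_s[[1]]
  pairs <- tf2motif |>
    filter(.data$tf_id %in% rownames(tmat), .data$motif %in% rownames(mmat))
  pairs$rho <- vapply(seq_len(nrow(pairs)), function(i) {
    suppressWarnings(cor(tmat[pairs$tf_id[i], ], mmat[pairs$motif[i], ],
                         method = "spearman"))
  }, 0)
  cluster_rows <- function(mat) {
    if (nrow(mat) < 2) return(rownames(mat))
    d <- spearman_dist(mat)
    hc <- hclust(d, method = "complete")
    rownames(mat)[hc$order]
  }
  list(
    pairs = as_tibble(pairs),
    tf_scaled = tf_s, motif_scaled = mo_s,
    tf_order = cluster_rows(tmat),
    motif_order = cluster_rows(mmat),
    set_order = if (length(sets) >= 2) {
      hc <- hclust(spearman_dist(t(tmat)), method = "complete")
      sets[hc$order]
    } else {
      sets
    }
  )
}

# 1 - Spearman rho distance between rows; constant rows get rho 0
spearman_dist <- function(mat) {
  cc <- suppressWarnings(cor(t(mat), method = "spearman"))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  as.dist(1 - cc)
}

#' Heatmap of row-scaled values with clustered orders
#' @param mat Wide tibble (id + condition-set columns), typically
#'   `tf_scaled`/`motif_scaled` from [tf_motif_correlation()].
#' @param row_order,col_order Optional orders from the clustering.
#' @return A ggplot.
#' @export
plot_scaled_heatmap <- function(mat, row_order = NULL, col_order = NULL) {
  id_col <- names(mat)[1]
  long <- pivot_longer(mat, -1, names_to = "set", values_to = "value")
  if (!is.null(row_order)) {
    long[[id_col]] <- factor(long[[id_col]], levels = row_order)
  }
  if (!is.null(col_order)) long$set <- factor(long$set, levels = col_order)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$set, y = .data[[id_col]],
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2c6fbb", high = "#c0392b",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled") +
    ggplot2::theme_minimal()
}
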
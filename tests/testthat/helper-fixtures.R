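# shared fixtures and independent oracles for the suite

# one modestly sized synthetic study, built once per run
.fixture_env <- new.env(parent = emptyenv())

shared_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- simulate_bundle(sim_config(seed = 421), NULL)
  }
  .fixture_env$bundle
}

shared_expression <- function() {
  if (is.null(.fixture_env$es)) {
    b <- shared_bundle()
    .fixture_env$es <- quantify_matrix(
      dplyr::rename(b$transcripts, feature_id = transcript_id),
      b$tracks, b$samples
    )
  }
  .fixture_env$es
}

# random non-overlapping run-length track on a toy genome (valid bedGraph)
random_track_runs <- function(chrom_len = 1000, chroms = "chr1",
                              strands = c("+", "-"), density = 0.4) {
  out <- list()
  for (ch in chroms) {
    for (st in strands) {
      cuts <- sort(sample.int(chrom_len - 1, max(2, rpois(1, 20))))
      starts <- c(0, cuts)
      ends <- c(cuts, chrom_len)
      vals <- sample(0:5, length(starts), replace = TRUE,
                     prob = c(1 - density, rep(density / 5, 5)))
      keep <- vals > 0
      if (!any(keep)) next
      out[[paste(ch, st)]] <- tibble::tibble(
        chrom = ch, start = starts[keep], end = ends[keep],
        value = as.numeric(vals[keep]), strand = st
      )
    }
  }
  nascentscape:::merge_runs(dplyr::bind_rows(out))
}

# random (possibly overlapping) intervals, for features/queries
random_runs <- function(n_runs, chrom_len = 1000, chroms = "chr1",
                       strands = c("+", "-")) {
  out <- lapply(seq_len(n_runs), function(i) {
    ch <- sample(chroms, 1)
    st <- sample(strands, 1)
    a <- sample.int(chrom_len - 2, 1) - 1
    b <- a + sample.int(min(50, chrom_len - a - 1), 1)
    tibble::tibble(chrom = ch, start = a, end = b,
                   value = sample(1:9, 1), strand = st)
  })
  dplyr::bind_rows(out)
}

# per-base expansion of a run tibble (oracle for coverage arithmetic)
runs_to_basevec <- function(runs, chrom, strand, len) {
  v <- numeric(len)
  r <- runs[runs$chrom == chrom & runs$strand == strand, ]
  for (i in seq_len(nrow(r))) {
    idx <- (r$start[i] + 1):r$end[i]
    v[idx] <- v[idx] + r$value[i]
  }
  v
}

# O(n*m) interval-overlap oracle
brute_overlap <- function(query, subject, same_strand = FALSE) {
  hits <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] != subject$chrom[j]) next
      ov <- min(query$end[i], subject$end[j]) -
        max(query$start[i], subject$start[j])
      if (ov < 1) next
      if (same_strand) {
        qs <- query$strand[i]; ss <- subject$strand[j]
        if (qs != ss && qs != "." && ss != ".") next
      }
      hits[[length(hits) + 1]] <- c(i, j, ov)
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(query_idx = integer(), subject_idx = integer(),
                          overlap_bp = double()))
  }
  m <- do.call(rbind, hits)
  out <- tibble::tibble(query_idx = m[, 1], subject_idx = m[, 2],
                        overlap_bp = m[, 3])
  out[order(out$query_idx, out$subject_idx), ]
}

# textbook step-up BH, written independently of stats::p.adjust
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, (m / i) * p[o[i]])
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# conditional distribution of the group-1 sum given the grand total, built by
# explicit numeric convolution of per-replicate NB (or Poisson) pmfs
brute_nb_conditional_p <- function(counts_g1, counts_g2, phi) {
  s1 <- sum(counts_g1)
  total <- s1 + sum(counts_g2)
  grid <- 0:total
  pmf_sum <- function(n) {
    one <- if (phi == 0) {
      stats::dpois(grid, total / (length(counts_g1) + length(counts_g2)))
    } else {
      stats::dnbinom(grid, size = 1 / phi,
                     mu = total / (length(counts_g1) + length(counts_g2)))
    }
    acc <- one
    for (i in seq_len(n - 1)) {
      acc <- vapply(grid, function(t) {
        sum(acc[1:(t + 1)] * one[(t + 1):1])
      }, 0)
    }
    acc
  }
  p1 <- pmf_sum(length(counts_g1))
  p2 <- pmf_sum(length(counts_g2))
  joint <- p1 * rev(p2)
  cond <- joint / sum(joint)
  obs <- cond[s1 + 1]
  sum(cond[cond <= obs * (1 + 1e-7)])
}

# naive O(n^3) agglomerative clustering; returns sorted merge heights
brute_linkage_heights <- function(d, method = c("average", "complete")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1)) {
        ia <- active[a]; ib <- active[b]
        dd <- dist_between(members[[ia]], members[[ib]], d, method)
        if (dd < bh - 1e-12) {
          bh <- dd; best <- c(ib, ia)
        }
      }
    }
    heights <- c(heights, bh)
    i <- best[1]; j <- best[2]
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
  }
  sort(heights)
}

dist_between <- function(mi, mj, d, method) {
  vals <- d[mi, mj, drop = FALSE]
  if (method == "average") mean(vals) else max(vals)
}

# naive two-strand PWM scanner
revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

brute_scan <- function(sequence, pwm, background = rep(0.25, 4),
                       threshold = NULL) {
  w <- ncol(pwm)
  lo <- log2(pwm / background)
  if (is.null(threshold)) threshold <- 0.8 * sum(apply(lo, 2, max))
  L <- nchar(sequence)
  hits <- list()
  if (L >= w) {
    for (pos in 0:(L - w)) {
      win <- substr(sequence, pos + 1, pos + w)
      if (grepl("N", win)) next
      for (str in c("+", "-")) {
        s <- if (str == "+") win else revcomp(win)
        b <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
        sc <- sum(lo[cbind(b, seq_len(w))])
        if (sc >= threshold) {
          hits[[length(hits) + 1]] <-
            tibble::tibble(position = pos, strand = str, score = sc)
        }
      }
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(position = integer(), strand = character(),
                          score = double()))
  }
  out[order(out$position, out$strand), ]
}

# random probability PWM
random_pwm <- function(w = 6) {
  m <- matrix(stats::rexp(4 * w), 4, w)
  m <- sweep(m, 2, colSums(m), `/`)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# minimal single-strand signal track from explicit runs
toy_track <- function(..., library_size = NULL) {
  signal_track(tibble::tibble(...), library_size = library_size)
}
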
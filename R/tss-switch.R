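#' Unique TSS segments of multi-TSS loci
#'
#' For each locus with `k >= 2` transcript variants (TVs) sharing a 3'
#' terminus, orders the TVs 5' to 3' in transcription direction (TV1 = most
#' upstream TSS) and returns the unique segment of each TV: the interval
#' between its TSS and the next TSS downstream, the last TV taking the
#' remainder to the shared 3' end. Segments tile the locus without overlap.
#' Loci whose TVs do not share a 3' end raise an annotation error; loci with
#' more than 6 TVs warn (multi-TSS pri-miRNA loci carry 2-6 alternatives).
#'
#' @param transcripts Transcript tibble (needs `transcript_id, locus_id,
#'   chrom, start, end, strand, tss`); only loci with >= 2 transcripts are
#'   used.
#' @return Tibble `segment_id, locus_id, tv, chrom, start, end, strand`.
#' @export
tss_segments <- function(transcripts) {
  multi <- transcripts |>
    group_by(.data$locus_id) |>
    filter(dplyr::n() >= 2) |>
    ungroup()
  if (nrow(multi) == 0) {
    return(tibble(segment_id = character(), locus_id = character(),
                  tv = integer(), chrom = character(), start = double(),
                  end = double(), strand = character()))
  }
  segs <- multi |>
    group_by(.data$locus_id) |>
    group_modify(function(d, key) {
      if (length(unique(d$strand)) != 1 || length(unique(d$chrom)) != 1) {
        abort(sprintf("locus %s: TVs must share chrom and strand", key$locus_id))
      }
      plus <- d$strand[1] == "+"
      if (plus) {
        if (length(unique(d$end)) != 1) {
          abort(sprintf("locus %s: TVs must share the 3' end", key$locus_id))
        }
        d <- arrange(d, .data$tss)
        bounds <- c(d$tss, d$end[1])
      } else {
        if (length(unique(d$start)) != 1) {
          abort(sprintf("locus %s: TVs must share the 3' end", key$locus_id))
        }
        d <- arrange(d, dplyr::desc(.data$tss))
        bounds <- c(d$tss + 1, d$start[1])
      }
      k <- nrow(d)
      if (k > 6) {
        warn(sprintf("locus %s has %d TVs (expected 2-6)", key$locus_id, k))
      }
      tibble(
        tv = seq_len(k),
        chrom = d$chrom[1],
        start = if (plus) bounds[seq_len(k)] else bounds[seq_len(k) + 1],
        end = if (plus) bounds[seq_len(k) + 1] else bounds[seq_len(k)],
        strand = d$strand[1]
      )
    }) |>
    ungroup() |>
    mutate(segment_id = sprintf("%s_seg%d", .data$locus_id, .data$tv)) |>
    select("segment_id", "locus_id", "tv", "chrom", "start", "end", "strand")
  segs
}

#' Per-group TSS-variant activity profiles
#'
#' Quantifies each TV's unique segment (or, with `full_span = TRUE`, its full
#' nested span) in every sample, averages FPKM per group and derives:
#'
#' * `delta`: the adjacent-difference statistic, segment FPKM of TV i minus
#'   TV i+1 (length k-1, `NA` on the last TV);
#' * `activity`: the per-TSS initiation estimate. Nascent signal accumulates
#'   downstream across TSSs (every upstream TV covers the segments below its
#'   TSS), so the initiation attributable to TSS i is the upstream-adjacent
#'   difference of unique-segment FPKMs: `seg_1` for TV1, `seg_i - seg_{i-1}`
#'   after that. With `full_span = TRUE` it is the downstream difference of
#'   full-span FPKMs instead;
#' * `dominant`: TRUE for the group's highest-activity TV.
#'
#' @param transcripts Transcript tibble (see [tss_segments()]).
#' @param tracks Named list of [signal_track()] per sample.
#' @param samples Tibble `sample, group`.
#' @param full_span Quantify full nested TV spans instead of unique segments.
#' @return A `tss_profiles` tibble: `locus_id, group, tv, k, segment_fpkm,
#'   delta, activity, dominant`.
#' @export
build_tss_profiles <- function(transcripts, tracks, samples,
                               full_span = FALSE) {
  segs <- tss_segments(transcripts)
  if (nrow(segs) == 0) abort("no multi-TSS loci in the annotation")
  feats <- if (full_span) {
    transcripts |>
      semi_join(segs, by = "locus_id") |>
      mutate(ord = ifelse(.data$strand == "+", .data$tss, -.data$tss)) |>
      group_by(.data$locus_id) |>
      arrange(.data$ord, .by_group = TRUE) |>
      mutate(tv = dplyr::row_number()) |>
      ungroup() |>
      mutate(segment_id = sprintf("%s_seg%d", .data$locus_id, .data$tv)) |>
      select("segment_id", "locus_id", "tv", "chrom", "start", "end", "strand")
  } else {
    segs
  }
  es <- quantify_matrix(rename(feats, feature_id = "segment_id"),
                        tracks, samples)
  prof <- tidy(es) |>
    left_join(select(feats, feature_id = "segment_id", "locus_id", "tv"),
              by = "feature_id") |>
    group_by(.data$locus_id, .data$group, .data$tv) |>
    summarise(segment_fpkm = mean(.data$fpkm), .groups = "drop") |>
    arrange(.data$locus_id, .data$group, .data$tv) |>
    group_by(.data$locus_id, .data$group) |>
    mutate(
      k = dplyr::n(),
      delta = .data$segment_fpkm - dplyr::lead(.data$segment_fpkm),
      activity = if (full_span) {
        dplyr::coalesce(.data$segment_fpkm - dplyr::lead(.data$segment_fpkm),
                        .data$segment_fpkm)
      } else {
        .data$segment_fpkm -
          dplyr::lag(.data$segment_fpkm, default = 0)
      },
      dominant = .data$tv == .data$tv[which.max(.data$activity)]
    ) |>
    ungroup()
  structure(prof, class = c("tss_profiles", class(prof)),
            full_span = full_span)
}

#' Uncentered correlation distance
#'
#' `d(x, y) = 1 - sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`, the
#' cosine-type distance computed without mean-centering; it lies in
#' \[0, 2\] and is 0 iff the vectors are proportional with positive sign.
#'
#' @param x,y Numeric vectors of equal length, neither all-zero.
#' @return Distance in \[0, 2\].
#' @export
#' @examples
#' uncentered_corr_distance(c(1, 1), c(1, 0))  # 1 - 1/sqrt(2)
uncentered_corr_distance <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    abort("uncentered correlation distance is undefined for a zero vector")
  }
  1 - sum(x * y) / (nx * ny)
}

#' Pairwise uncentered-correlation distance matrix
#' @param mat Numeric matrix, observations in rows (no all-zero rows).
#' @return A `dist` object.
#' @export
uncentered_dist <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) {
    abort("uncentered correlation distance is undefined for a zero vector")
  }
  sim <- (mat %*% t(mat)) / outer(norms, norms)
  as.dist(1 - sim)
}

#' Average-linkage (UPGMA) clustering under a chosen distance
#'
#' @param mat Numeric matrix, observations in rows; rownames become labels.
#' @param distance `"uncentered"` (default) or a precomputed `dist`.
#' @return An `hclust` object.
#' @export
average_linkage_cluster <- function(mat, distance = "uncentered") {
  d <- if (inherits(distance, "dist")) distance else uncentered_dist(mat)
  hclust(d, method = "average")
}

#' Cluster loci by their differential TSS-activity profiles
#'
#' The clustering input is, per locus, the concatenated per-group
#' adjacent-difference (delta) vectors, min-max scaled to \[-1, 1\] per
#' locus, compared with uncentered correlation distance under average
#' linkage. Loci with a constant profile (zero vector after scaling) are
#' dropped with a warning.
#'
#' @param profiles A `tss_profiles` tibble.
#' @return List with `hclust`, `leaf_order` (locus ids) and the scaled
#'   `matrix`.
#' @export
cluster_tss_profiles <- function(profiles) {
  wide <- profiles |>
    filter(!is.na(.data$delta)) |>
    mutate(col = paste(.data$group, .data$tv, sep = "_d")) |>
    select("locus_id", "col", "delta") |>
    pivot_wider(names_from = "col", values_from = "delta")
  # loci differ in TV count: absent adjacent differences contribute nothing
  wide[is.na(wide)] <- 0
  if (nrow(wide) < 2) abort("need at least 2 loci to cluster")
  scaled <- row_normalize(wide)
  mat <- as.matrix(scaled[, -1, drop = FALSE])
  rownames(mat) <- scaled$locus_id
  keep <- rowSums(mat^2) > 0
  if (any(!keep)) {
    warn(sprintf("dropping %d constant-profile loci from clustering",
                 sum(!keep)))
    mat <- mat[keep, , drop = FALSE]
  }
  hc <- average_linkage_cluster(mat)
  list(hclust = hc, leaf_order = rownames(mat)[hc$order], matrix = mat)
}

#' Export an hclust dendrogram as a Newick string
#' @param hc An `hclust`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
export_newick <- function(hc, path = NULL) {
  nwk <- paste0(ape::write.tree(ape::as.phylo(hc)), "")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Call TSS-switching loci
#'
#' A locus switches iff its dominant (highest-activity) TV differs between
#' at least one pair of groups and every group's dominant-TV activity
#' exceeds `min_fpkm` (reusing the expressed-transcript FPKM cutoff so that
#' dominance is never decided on near-silent loci).
#'
#' @param profiles A `tss_profiles` tibble.
#' @param min_fpkm Dominance floor, default 1 FPKM.
#' @return Tibble `locus_id, k, switching` plus one `dom_<group>` column per
#'   group.
#' @export
detect_tss_switching <- function(profiles, min_fpkm = 1) {
  groups <- unique(profiles$group)
  if (length(groups) < 2) abort("switch detection needs >= 2 groups")
  profiles |>
    group_by(.data$locus_id) |>
    summarise(
      k = .data$k[1],
      n_dom = dplyr::n_distinct(.data$tv[.data$dominant]),
      all_active = all(.data$activity[.data$dominant] > min_fpkm),
      dom_map = list(stats::setNames(.data$tv[.data$dominant],
                                     paste0("dom_", .data$group[.data$dominant]))),
      .groups = "drop"
    ) |>
    mutate(switching = .data$n_dom > 1 & .data$all_active) |>
    tidyr::unnest_wider("dom_map") |>
    select(-"n_dom", -"all_active")
}
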
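#' Quantify features against one stranded signal track
#'
#' The count of a feature is the summed base-resolution coverage over its
#' span on the matching strand; features with strand `"."` sum both strands.
#' FPKM divides the count by feature length in kb and library size in
#' millions (RPKM is the same quantity; both terms are used for nascent
#' signal).
#'
#' @param features Tibble with `chrom,start,end,strand` and an id column
#'   (first column or `feature_id`).
#' @param track A [signal_track()] with `library_size > 0`.
#' @return Tibble `feature_id, count, fpkm`, in input order.
#' @export
#' @examples
#' tr <- signal_track(tibble::tibble(chrom = "chr1", start = 0, end = 4,
#'                                   value = 2, strand = "+"),
#'                    library_size = 1e6)
#' fx <- tibble::tibble(feature_id = "f", chrom = "chr1", start = 0,
#'                      end = 2000, strand = "+")
#' quantify(fx, tr)  # 8 units of signal on a 2 kb feature at 1e6 -> FPKM 4
quantify <- function(features, track) {
  if (track$library_size <= 0) abort("quantify: track library_size must be > 0")
  if (any(features$end <= features$start)) {
    abort("quantify: zero- or negative-length feature")
  }
  id <- col_or(features, "feature_id", features[[1]])
  counts <- rep(0, nrow(features))
  runs <- track$runs
  for (str in unique(runs$strand)) {
    keep <- which(features$strand == str | features$strand == ".")
    if (length(keep) == 0) next
    r <- filter(runs, .data$strand == str)
    hits <- overlap_intervals(features[keep, ], r)
    if (nrow(hits) == 0) next
    contrib <- hits$overlap_bp * r$value[hits$subject_idx]
    add <- tapply(contrib, hits$query_idx, sum)
    counts[keep[as.integer(names(add))]] <-
      counts[keep[as.integer(names(add))]] + as.numeric(add)
  }
  tibble(
    feature_id = id,
    count = counts,
    fpkm = counts / ((features$end - features$start) / 1000 *
                       track$library_size / 1e6)
  )
}

#' Quantify features across a set of samples into an expression set
#'
#' @param features Feature tibble (see [quantify()]).
#' @param tracks Named list of [signal_track()], one per sample.
#' @param samples Tibble `sample, group` (order defines column order);
#'   defaults to one group named "all".
#' @return An `expression_set`: list with `fpkm` and `counts` (wide tibbles,
#'   `feature_id` + one column per sample) and `samples` (with library
#'   sizes).
#' @export
quantify_matrix <- function(features, tracks, samples = NULL) {
  if (is.null(samples)) {
    samples <- tibble(sample = names(tracks), group = "all")
  }
  stopifnot(all(samples$sample %in% names(tracks)))
  per_sample <- lapply(samples$sample, function(s) quantify(features, tracks[[s]]))
  fpkm <- tibble(feature_id = per_sample[[1]]$feature_id)
  counts <- fpkm
  for (i in seq_along(per_sample)) {
    fpkm[[samples$sample[i]]] <- per_sample[[i]]$fpkm
    counts[[samples$sample[i]]] <- per_sample[[i]]$count
  }
  samples$library_size <- unname(vapply(
    samples$sample, function(s) tracks[[s]]$library_size, 0
  ))
  structure(list(fpkm = fpkm, counts = counts, samples = samples),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d features x %d samples (%s)\n",
              nrow(x$fpkm), nrow(x$samples),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.expression_set <- function(x, ...) {
  x$fpkm |>
    pivot_longer(-"feature_id", names_to = "sample", values_to = "fpkm") |>
    left_join(
      pivot_longer(x$counts, -"feature_id", names_to = "sample",
                   values_to = "count"),
      by = c("feature_id", "sample")
    ) |>
    left_join(x$samples, by = "sample")
}

#' Filter features expressed above an FPKM threshold
#'
#' A feature is retained iff its FPKM is strictly greater than `threshold`
#' in at least one sample (the standard "FPKM > 1 in at least one sample"
#' expressed-transcript filter).
#'
#' @param es An `expression_set` (or a wide FPKM tibble).
#' @param threshold FPKM cutoff, default 1.
#' @return The filtered `expression_set` (or tibble), same type as input.
#' @export
filter_expressed <- function(es, threshold = 1) {
  mat <- if (inherits(es, "expression_set")) es$fpkm else es
  keep <- apply(as.matrix(mat[, -1, drop = FALSE]), 1,
                function(v) any(v > threshold))
  if (inherits(es, "expression_set")) {
    es$fpkm <- es$fpkm[keep, ]
    es$counts <- es$counts[keep, ]
    es
  } else {
    mat[keep, ]
  }
}

#' Min-max scale each feature row to [-1, 1]
#'
#' `x' = 2 (x - min) / (max - min) - 1` per row; constant rows map to all
#' zeros. This is the "normalized RPKM values (-1 to 1)" heatmap scaling,
#' shared by the motif-enrichment heatmaps.
#'
#' @param mat Wide tibble: id column first, then numeric columns.
#' @return Tibble of the same shape with scaled values.
#' @export
row_normalize <- function(mat) {
  vals <- as.matrix(mat[, -1, drop = FALSE])
  scaled <- t(apply(vals, 1, function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep(0, length(v)))
    2 * (v - rng[1]) / (rng[2] - rng[1]) - 1
  }))
  out <- mat
  out[, -1] <- as_tibble(scaled, .name_repair = "minimal")
  out
}

#' Composition-corrected normalization of an expression set
#'
#' Rescales every sample by its median-of-ratios size factor (computed on
#' the raw counts, geometric-mean reference), the same normalization
#' [de_test()] applies internally. Plain per-library FPKM is distorted when
#' regulation is asymmetric or graded — strongly transcribed conditions
#' dilute every feature's FPKM — and this correction removes that
#' composition effect, which matters whenever group means are compared
#' directly (heatmaps, TF expression panels, correlation analyses).
#'
#' @param es An `expression_set`.
#' @return The `expression_set` with `fpkm` and `counts` rescaled per
#'   sample; size factors are stored in `samples$size_factor`.
#' @export
normalize_expression <- function(es) {
  raw <- counts_matrix(es$counts)
  sf <- median_ratio_factors(raw)
  for (i in seq_along(sf)) {
    s <- es$samples$sample[i]
    es$fpkm[[s]] <- es$fpkm[[s]] / sf[i]
    es$counts[[s]] <- es$counts[[s]] / sf[i]
  }
  es$samples$size_factor <- unname(sf)
  es
}

#' Group means of an expression set on the FPKM scale
#'
#' @param es An `expression_set`.
#' @return Wide tibble `feature_id` + one column per group.
#' @export
group_means <- function(es) {
  tidy(es) |>
    group_by(.data$feature_id, .data$group) |>
    summarise(fpkm = mean(.data$fpkm), .groups = "drop") |>
    pivot_wider(names_from = "group", values_from = "fpkm") |>
    arrange(match(.data$feature_id, es$fpkm$feature_id))
}
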
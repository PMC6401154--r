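#' Find overlapping interval pairs between two interval tables
#'
#' Intervals are 0-based half-open, so `[0,10)` and `[10,20)` do not overlap.
#' A pair is reported iff the intersection is at least `min_overlap` bases.
#' With `same_strand = TRUE` strands must match, with `"."` matching either.
#'
#' @param query,subject Tibbles with columns `chrom,start,end` and, if
#'   `same_strand` is used, `strand`.
#' @param same_strand Require matching strands?
#' @param min_overlap Minimum intersection length in bp (default 1).
#' @return Tibble with `query_idx`, `subject_idx` (row indices) and
#'   `overlap_bp`.
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
#' b <- tibble::tibble(chrom = "chr1", start = 9, end = 20)
#' overlap_intervals(a, b)
overlap_intervals <- function(query, subject, same_strand = FALSE,
                              min_overlap = 1L) {
  empty <- tibble(query_idx = integer(), subject_idx = integer(),
                  overlap_bp = double())
  if (nrow(query) == 0 || nrow(subject) == 0) return(empty)
  hits_by_chrom <- lapply(intersect(unique(query$chrom), unique(subject$chrom)),
    function(ch) {
      qi <- which(query$chrom == ch)
      si <- which(subject$chrom == ch)
      qr <- IRanges::IRanges(start = query$start[qi] + 1, end = query$end[qi])
      sr <- IRanges::IRanges(start = subject$start[si] + 1, end = subject$end[si])
      ov <- IRanges::findOverlaps(qr, sr, minoverlap = min_overlap)
      tibble(
        query_idx = qi[S4Vectors_from(ov)],
        subject_idx = si[S4Vectors_to(ov)]
      )
    })
  hits <- bind_rows(hits_by_chrom)
  if (nrow(hits) == 0) return(empty)
  hits$overlap_bp <- pmin(query$end[hits$query_idx], subject$end[hits$subject_idx]) -
    pmax(query$start[hits$query_idx], subject$start[hits$subject_idx])
  if (same_strand) {
    qs <- query$strand[hits$query_idx]
    ss <- subject$strand[hits$subject_idx]
    hits <- hits[qs == ss | qs == "." | ss == ".", , drop = FALSE]
  }
  arrange(as_tibble(hits), .data$query_idx, .data$subject_idx)
}

# thin indirection so the IRanges accessors stay in one place
S4Vectors_from <- function(hits) S4Vectors::queryHits(hits)
S4Vectors_to <- function(hits) S4Vectors::subjectHits(hits)

#' Nearest gene TSS for each query TSS
#'
#' Distance is signed `gene_tss - query_tss` on the same chromosome. Ties in
#' absolute distance break toward the smaller coordinate, then toward the
#' lexicographically smaller gene id. Queries on chromosomes without genes get
#' `NA`.
#'
#' @param query_tss Tibble with `chrom`, `tss` and an id column (`name`).
#' @param gene_tss Tibble with `chrom`, `tss`, `gene_id`.
#' @return `query_tss` with `nearest_gene` and `distance` columns appended.
#' @export
nearest_tss <- function(query_tss, gene_tss) {
  if (nrow(gene_tss) == 0) abort("nearest_tss: empty gene list")
  pick <- function(ch, pos) {
    g <- gene_tss[gene_tss$chrom == ch, ]
    if (nrow(g) == 0) return(tibble(nearest_gene = NA_character_,
                                    distance = NA_real_))
    d <- g$tss - pos
    ord <- order(abs(d), g$tss, g$gene_id)
    tibble(nearest_gene = g$gene_id[ord[1]], distance = d[ord[1]])
  }
  bind_cols(
    query_tss,
    bind_rows(map2(query_tss$chrom, query_tss$tss, pick))
  )
}
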
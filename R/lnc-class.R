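#' Flag lncRNAs already present in a reference annotation
#'
#' A transcript is "known" iff it overlaps a reference transcript by at
#' least 1 bp on the same strand; anything else is novel. An empty reference
#' makes everything novel.
#'
#' @param lncrnas Tibble with `chrom,start,end,strand` and an id column.
#' @param reference Reference transcript/BED tibble (same columns).
#' @return `lncrnas` with a logical `known` column.
#' @export
mark_known <- function(lncrnas, reference) {
  known <- rep(FALSE, nrow(lncrnas))
  if (nrow(reference) > 0) {
    hits <- overlap_intervals(lncrnas, reference, same_strand = TRUE)
    known[unique(hits$query_idx)] <- TRUE
  }
  mutate(lncrnas, known = known)
}

#' Pair divergent (bidirectional) lncRNAs
#'
#' Two transcripts are candidate partners iff they lie on opposite strands
#' in divergent orientation - each TSS upstream of the other's span, i.e.
#' the pair transcribes away from a shared origin - and their TSSs are at
#' most `window` bp apart. Each transcript gets at most one partner;
#' candidates are matched greedily, closest pair first (ties by smaller
#' row indices).
#'
#' @param lncrnas Tibble with `transcript_id, chrom, start, end, strand,
#'   tss`.
#' @param window Maximum TSS-to-TSS distance in bp (default 500, the
#'   standard divergent-eRNA scale).
#' @return `lncrnas` with a `partner_id` column (`NA` = unidirectional).
#' @export
pair_bidirectional <- function(lncrnas, window = 500) {
  n <- nrow(lncrnas)
  id <- col_or(lncrnas, "transcript_id", lncrnas[[1]])
  partner <- rep(NA_character_, n)
  if (n >= 2) {
    plus <- which(lncrnas$strand == "+")
    minus <- which(lncrnas$strand == "-")
    cand <- list()
    for (i in plus) {
      for (j in minus) {
        if (lncrnas$chrom[i] != lncrnas$chrom[j]) next
        d <- abs(lncrnas$tss[i] - lncrnas$tss[j])
        if (d > window) next
        # divergent: the minus TSS sits at or upstream (left) of the plus
        # TSS, so the two transcribe outward
        if (lncrnas$tss[j] > lncrnas$tss[i]) next
        cand[[length(cand) + 1]] <- c(i = min(i, j), j = max(i, j), d = d)
      }
    }
    if (length(cand) > 0) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand[, "d"], cand[, "i"], cand[, "j"]), ,
                   drop = FALSE]
      used <- rep(FALSE, n)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, "i"]; j <- cand[r, "j"]
        if (!used[i] && !used[j]) {
          partner[i] <- id[j]; partner[j] <- id[i]
          used[c(i, j)] <- TRUE
        }
      }
    }
  }
  mutate(lncrnas, partner_id = partner)
}

#' Classify lncRNA TSSs as promoter- or enhancer-associated
#'
#' Within +/- `tss_window` bp of the TSS, computes the base coverage of
#' H3K4me3 peaks (`c3`) and H3K4me1 peaks (`c1`). Promoter iff `c3 > 0` and
#' `c3 >= c1`; enhancer iff `c1 > 0` and `c1 > c3`; unclassified when
#' neither mark is present. Ties with both marks present go to promoter
#' (H3K4me3 is the more specific promoter mark).
#'
#' @param lncrnas Tibble with `chrom, tss` and an id column.
#' @param h3k4me3,h3k4me1 Peak interval tibbles (`chrom,start,end`).
#' @param tss_window Half-window around the TSS in bp (default 1000).
#' @return `lncrnas` with `c3`, `c1` and `chromatin_class` columns.
#' @export
classify_chromatin <- function(lncrnas, h3k4me3, h3k4me1, tss_window = 1000) {
  win <- tibble(
    chrom = lncrnas$chrom,
    start = pmax(0, lncrnas$tss - tss_window),
    end = lncrnas$tss + tss_window
  )
  cov_in <- function(peaks) {
    covered <- rep(0, nrow(win))
    if (nrow(peaks) > 0) {
      hits <- overlap_intervals(win, peaks)
      if (nrow(hits) > 0) {
        agg <- tapply(hits$overlap_bp, hits$query_idx, sum)
        covered[as.integer(names(agg))] <- as.numeric(agg)
      }
    }
    covered
  }
  c3 <- cov_in(h3k4me3)
  c1 <- cov_in(h3k4me1)
  mutate(lncrnas,
    c3 = c3, c1 = c1,
    chromatin_class = dplyr::case_when(
      c3 > 0 & c3 >= c1 ~ "promoter",
      c1 > 0 & c1 > c3 ~ "enhancer",
      .default = "unclassified"
    )
  )
}

#' Flag lncRNAs overlapping super-enhancer intervals
#'
#' Strand-agnostic >= 1 bp overlap of the transcript span with any SE
#' interval.
#'
#' @param lncrnas Tibble with `chrom,start,end`.
#' @param se Super-enhancer interval tibble.
#' @return `lncrnas` with a logical `se_flag` column.
#' @export
flag_super_enhancer <- function(lncrnas, se) {
  flag <- rep(FALSE, nrow(lncrnas))
  if (nrow(se) > 0) {
    hits <- overlap_intervals(lncrnas, se)
    flag[unique(hits$query_idx)] <- TRUE
  }
  mutate(lncrnas, se_flag = flag)
}

#' Full lncRNA categorization
#'
#' Runs [mark_known()], [pair_bidirectional()], [classify_chromatin()] and
#' [flag_super_enhancer()] and returns one table.
#'
#' @param lncrnas Tibble with `transcript_id, chrom, start, end, strand,
#'   tss`.
#' @param h3k4me3,h3k4me1,se Interval tibbles.
#' @param reference Optional reference annotation for the known/novel split.
#' @param tss_window,pair_window Window sizes in bp.
#' @return A `lnc_classes` tibble: input columns plus `known, partner_id,
#'   bidirectional, c3, c1, chromatin_class, se_flag`.
#' @export
classify_lncrnas <- function(lncrnas, h3k4me3, h3k4me1, se,
                             reference = NULL, tss_window = 1000,
                             pair_window = 500) {
  out <- lncrnas
  out <- if (is.null(reference)) {
    mutate(out, known = FALSE)
  } else {
    mark_known(out, reference)
  }
  out <- pair_bidirectional(out, window = pair_window)
  out <- mutate(out, bidirectional = !is.na(.data$partner_id))
  out <- classify_chromatin(out, h3k4me3, h3k4me1, tss_window = tss_window)
  out <- flag_super_enhancer(out, se)
  structure(out, class = c("lnc_classes", class(out)))
}

#' @export
glance.lnc_classes <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_known = sum(x$known),
    n_bidirectional = sum(x$bidirectional),
    n_promoter = sum(x$chromatin_class == "promoter"),
    n_enhancer = sum(x$chromatin_class == "enhancer"),
    n_unclassified = sum(x$chromatin_class == "unclassified"),
    n_se = sum(x$se_flag)
  )
}

#' Bar chart of lncRNA class composition
#' @param object A `lnc_classes` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lnc_classes <- function(object, ...) {
  df <- as_tibble(object) |>
    count(.data$chromatin_class, .data$se_flag)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chromatin_class, y = .data$n,
                                   fill = .data$se_flag)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "lncRNAs", fill = "SE overlap") +
    ggplot2::theme_minimal()
}
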
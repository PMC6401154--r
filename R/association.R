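#' Hypergeometric GO over-representation test
#'
#' For every term with at least one study hit: upper-tail hypergeometric
#' `P[X >= k]` with `k` study hits, `n` study genes, `K` population hits and
#' `N` population genes; BH adjustment across terms; enrichment factor
#' `(k/n) / (K/N)` and `-log2(p)` for heatmap display.
#'
#' @param study_genes Character vector, a subset of `population_genes`.
#' @param population_genes Character vector (the gene universe).
#' @param go_table Tibble `gene_id, term_id`.
#' @return A `go_enrichment` tibble: `term_id, k, n, K, N,
#'   enrichment_factor, p_value, adj_p, minus_log2_p`, ordered by p.
#' @export
#' @examples
#' go <- tibble::tibble(gene_id = paste0("g", 1:5), term_id = "T1")
#' hypergeom_enrich(paste0("g", 1:5), paste0("g", 1:10), go)  # p = 1/252
hypergeom_enrich <- function(study_genes, population_genes, go_table) {
  study_genes <- unique(study_genes)
  population_genes <- unique(population_genes)
  if (length(study_genes) == 0) abort("empty study set")
  if (!all(study_genes %in% population_genes)) {
    abort("study genes must be a subset of the population")
  }
  go_table <- filter(go_table, .data$gene_id %in% population_genes)
  n <- length(study_genes)
  N <- length(population_genes)
  res <- go_table |>
    group_by(term_id = .data$term_id) |>
    summarise(
      k = sum(unique(.data$gene_id) %in% study_genes),
      K = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    ) |>
    filter(.data$k > 0) |>
    mutate(
      n = n, N = N,
      enrichment_factor = (.data$k / n) / (.data$K / N),
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n,
                       lower.tail = FALSE)
    ) |>
    mutate(
      adj_p = bh_adjust(.data$p_value),
      minus_log2_p = -log2(.data$p_value)
    ) |>
    select("term_id", "k", "n", "K", "N", "enrichment_factor",
           "p_value", "adj_p", "minus_log2_p") |>
    arrange(.data$p_value, .data$term_id)
  structure(res, class = c("go_enrichment", class(res)))
}

#' Dot plot of a GO enrichment result
#' @param object A `go_enrichment` tibble.
#' @param top Number of terms to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.go_enrichment <- function(object, top = 15, ...) {
  df <- head(as_tibble(object), top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$enrichment_factor,
    y = stats::reorder(.data$term_id, -.data$p_value),
    size = .data$k, colour = .data$minus_log2_p
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "enrichment factor", y = NULL, size = "hits",
                  colour = "-log2 p") +
    ggplot2::theme_minimal()
}

#' Correlate lncRNA expression with the nearest coding gene
#'
#' Pearson correlation (default) of `log2(FPKM + 1)` profiles across
#' samples between each lncRNA and its nearest coding gene, plus mean
#' correlation per lncRNA category (categories may overlap: novel,
#' promoter, enhancer, SE). Zero-variance profiles give `NA` and are
#' excluded from category means.
#'
#' @param lnc_es,gene_es `expression_set`s sharing the same samples.
#' @param nearest Tibble `feature_id, nearest_gene` mapping each lncRNA to
#'   its nearest gene (see [nearest_tss()]).
#' @param categories Optional tibble `feature_id, category` (one row per
#'   membership).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `per_lncrna` (feature_id, nearest_gene, r) and
#'   `per_category` (category, mean_r, n).
#' @export
correlate_with_nearest_gene <- function(lnc_es, gene_es, nearest,
                                        categories = NULL,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  samples <- lnc_es$samples$sample
  if (!identical(sort(samples), sort(gene_es$samples$sample))) {
    abort("lncRNA and gene expression sets must share samples")
  }
  if (length(samples) < 3) abort("need >= 3 samples for correlation")
  lmat <- log2(as.matrix(lnc_es$fpkm[, samples, drop = FALSE]) + 1)
  rownames(lmat) <- lnc_es$fpkm$feature_id
  gmat <- log2(as.matrix(gene_es$fpkm[, samples, drop = FALSE]) + 1)
  rownames(gmat) <- gene_es$fpkm$feature_id
  per <- nearest |>
    filter(.data$feature_id %in% rownames(lmat),
           .data$nearest_gene %in% rownames(gmat))
  per$r <- vapply(seq_len(nrow(per)), function(i) {
    x <- lmat[per$feature_id[i], ]
    y <- gmat[per$nearest_gene[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    cor(x, y, method = method)
  }, 0)
  per_cat <- NULL
  if (!is.null(categories)) {
    per_cat <- categories |>
      inner_join(per, by = "feature_id") |>
      group_by(.data$category) |>
      summarise(mean_r = mean(.data$r, na.rm = TRUE),
                n = sum(!is.na(.data$r)), .groups = "drop")
  }
  list(per_lncrna = select(per, "feature_id", "nearest_gene", "r"),
       per_category = per_cat)
}

#' Transfer GO annotation to lncRNA categories by association
#'
#' Guilt-by-association: for each lncRNA category, assemble a study set of
#' coding genes - either every gene whose expression correlates with some
#' category member at `|r| >= r_min` (`mode = "correlation"`), or the
#' nearest genes of the category members (`mode = "nearest"`) - and run
#' [hypergeom_enrich()] on it against the full gene population.
#'
#' @param categories Tibble `feature_id, category`.
#' @param lnc_es,gene_es `expression_set`s sharing samples.
#' @param nearest Tibble `feature_id, nearest_gene`.
#' @param go_table Tibble `gene_id, term_id`.
#' @param mode `"nearest"` (default) or `"correlation"`.
#' @param r_min Absolute-correlation threshold for `mode = "correlation"`.
#' @param method Correlation flavour, as in [correlate_with_nearest_gene()].
#' @return Tibble of per-category enrichment rows (`category` + the
#'   `go_enrichment` columns); zero rows when every study set is empty.
#' @export
transfer_go_to_lncrnas <- function(categories, lnc_es, gene_es, nearest,
                                   go_table, mode = c("nearest", "correlation"),
                                   r_min = 0.7,
                                   method = c("pearson", "spearman")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  population <- gene_es$fpkm$feature_id
  out <- list()
  for (cat in unique(categories$category)) {
    members <- categories$feature_id[categories$category == cat]
    study <- if (mode == "nearest") {
      unique(nearest$nearest_gene[nearest$feature_id %in% members])
    } else {
      samples <- lnc_es$samples$sample
      lmat <- log2(as.matrix(lnc_es$fpkm[, samples, drop = FALSE]) + 1)
      rownames(lmat) <- lnc_es$fpkm$feature_id
      gmat <- log2(as.matrix(gene_es$fpkm[, samples, drop = FALSE]) + 1)
      rownames(gmat) <- gene_es$fpkm$feature_id
      members <- intersect(members, rownames(lmat))
      if (length(members) == 0) character() else {
        cc <- suppressWarnings(cor(t(gmat), t(lmat[members, , drop = FALSE]),
                                   method = method))
        population[apply(abs(cc) >= r_min, 1, any, na.rm = TRUE)]
      }
    }
    study <- intersect(study, population)
    if (length(study) == 0) next
    enr <- hypergeom_enrich(study, population, go_table)
    out[[cat]] <- mutate(as_tibble(enr), category = cat, .before = 1)
  }
  bind_rows(out)
}

#' Hub miRNAs of a miRNA-target interaction network
#'
#' Restricts the bipartite edge list to expressed miRNAs, computes per-miRNA
#' degree and calls hubs at `degree >= min_degree`.
#'
#' @param targets Tibble `mirna_id, gene_id`.
#' @param expressed_mirnas Character vector of expressed miRNA ids.
#' @param min_degree Hub degree threshold.
#' @return A `mirna_network`: list with `edges`, `degrees` (tibble
#'   `mirna_id, degree, hub`), `hubs` (ids) and `hub_targets` (union of hub
#'   target genes).
#' @export
hub_mirnas <- function(targets, expressed_mirnas, min_degree) {
  edges <- filter(targets, .data$mirna_id %in% expressed_mirnas) |>
    distinct()
  degrees <- edges |>
    count(.data$mirna_id, name = "degree") |>
    mutate(hub = .data$degree >= min_degree) |>
    arrange(dplyr::desc(.data$degree), .data$mirna_id)
  hubs <- degrees$mirna_id[degrees$hub]
  structure(
    list(
      edges = edges, degrees = degrees, hubs = hubs,
      hub_targets = sort(unique(edges$gene_id[edges$mirna_id %in% hubs]))
    ),
    class = "mirna_network"
  )
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf("<mirna_network> %d edges, %d miRNAs, %d hubs targeting %d genes\n",
              nrow(x$edges), nrow(x$degrees), length(x$hubs),
              length(x$hub_targets)))
  invisible(x)
}

#' @export
glance.mirna_network <- function(x, ...) {
  tibble(n_mirnas = nrow(x$degrees), n_edges = nrow(x$edges),
         n_hubs = length(x$hubs), n_hub_targets = length(x$hub_targets))
}
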
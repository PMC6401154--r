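#' Estimate a common negative-binomial dispersion
#'
#' Method-of-moments on within-group residuals, pooled across features: for
#' each feature with grand mean `m > 0` and pooled within-group variance
#' `s^2`, the moment estimate is `max(0, (s^2 - m) / m^2)`; the common
#' dispersion is the median over features. Simple by design: a single common
#' dispersion, no tagwise shrinkage.
#'
#' @param counts Numeric matrix or wide tibble (id column first), features x
#'   samples, of library-scaled counts.
#' @param groups Character/factor vector, one group per sample column.
#' @return Scalar dispersion `phi >= 0`.
#' @export
estimate_dispersion <- function(counts, groups) {
  mat <- counts_matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) abort("groups must match sample columns")
  if (all(table(groups) < 2)) {
    abort("all groups are singletons: cannot estimate dispersion, supply phi")
  }
  keep <- groups %in% names(which(table(groups) >= 2))
  mat <- mat[, keep, drop = FALSE]
  groups <- groups[keep]
  m <- rowMeans(mat)
  ss <- 0
  df <- 0
  dev <- matrix(0, nrow(mat), 0)
  for (g in unique(groups)) {
    sub <- mat[, groups == g, drop = FALSE]
    dev <- cbind(dev, sub - rowMeans(sub))
    df <- df + ncol(sub) - 1
  }
  s2 <- rowSums(dev^2) / df
  phi_f <- pmax(0, (s2 - m) / m^2)
  phi_f <- phi_f[m > 0]
  if (length(phi_f) == 0) return(0)
  stats::median(phi_f)
}

counts_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[, -1, drop = FALSE])
    rownames(m) <- counts[[1]]
    m
  } else {
    as.matrix(counts)
  }
}

#' Exact negative-binomial test for a two-group count difference
#'
#' Conditions on the grand total of the two group sums: under equal effective
#' library sizes, the first group's sum given the total follows the
#' distribution induced by two NB sums (sizes `n_g / phi`), Poisson-binomial
#' in the `phi = 0` limit. The two-sided p-value sums the probabilities of
#' all splits no more probable than the observed one (relative tolerance
#' 1e-7 on ties), so `p` is in (0, 1] and equals the exact binomial
#' two-sided p when `phi = 0`.
#'
#' @param counts_g1,counts_g2 Non-negative count vectors (replicates).
#' @param phi Common NB dispersion (>= 0).
#' @return Two-sided p-value.
#' @export
#' @examples
#' nb_exact_test(c(10, 12), c(11, 11), phi = 0.1)   # balanced -> p = 1
#' nb_exact_test(c(0, 1), c(20, 25), phi = 0)
nb_exact_test <- function(counts_g1, counts_g2, phi) {
  if (any(counts_g1 < 0) || any(counts_g2 < 0)) {
    abort("nb_exact_test: negative counts")
  }
  if (phi < 0) abort("nb_exact_test: phi must be >= 0")
  n1 <- length(counts_g1)
  n2 <- length(counts_g2)
  s1 <- round(sum(counts_g1))
  total <- s1 + round(sum(counts_g2))
  if (total == 0) return(1)
  s <- 0:total
  if (phi == 0) {
    logp <- dbinom(s, total, n1 / (n1 + n2), log = TRUE)
  } else {
    mu_hat <- total / (n1 + n2)
    logp <- dnbinom(s, size = n1 / phi, mu = n1 * mu_hat, log = TRUE) +
      dnbinom(total - s, size = n2 / phi, mu = n2 * mu_hat, log = TRUE)
    logp <- logp - log(sum(exp(logp - max(logp)))) - max(logp)
  }
  rel <- exp(logp - logp[s1 + 1])
  p <- sum(exp(logp)[rel <= 1 + 1e-7])
  min(1, p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, capped at 1 (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify features as up-, down-regulated or not significant
#'
#' `up` iff `log2fc > lfc` and `p < alpha` (both strict); `down` symmetric;
#' otherwise `ns`. The default thresholds are the headline regime
#' (log2FC > 2, adjusted p < 0.05); the secondary regime (log2FC > 1, raw
#' p < 0.05) is reached via the arguments.
#'
#' @param log2fc,p Numeric vectors.
#' @param lfc Log2 fold-change threshold (default 2).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector in `{"up", "down", "ns"}`.
#' @export
classify_de <- function(log2fc, p, lfc = 2, alpha = 0.05) {
  dplyr::case_when(
    log2fc > lfc & p < alpha ~ "up",
    log2fc < -lfc & p < alpha ~ "down",
    .default = "ns"
  )
}

#' Differential-transcription test between two groups of an expression set
#'
#' Counts are brought to equal effective library sizes by median-of-ratios
#' scaling (robust to composition shifts from asymmetric regulation), a
#' common dispersion is estimated unless supplied, each feature gets an
#' exact conditional NB p-value, BH adjustment is applied across features,
#' and features are classified with [classify_de()]. log2FC is computed on
#' pseudocounted (`+0.5`) group means of the scaled counts, group2 over
#' group1.
#'
#' @param es An `expression_set` from [quantify_matrix()].
#' @param group1,group2 Group names to compare (group1 is the baseline).
#' @param dispersion Optional common dispersion; estimated when `NULL`.
#' @param lfc,alpha Thresholds for [classify_de()].
#' @param use_adjusted Classify on BH-adjusted p-values (default) or raw.
#' @return A `de_result` tibble: `feature_id, base_mean_1, base_mean_2,
#'   log2fc, p_value, adj_p, status`, with the dispersion and thresholds in
#'   attributes.
#' @export
de_test <- function(es, group1, group2, dispersion = NULL,
                    lfc = 2, alpha = 0.05, use_adjusted = TRUE) {
  s1 <- es$samples$sample[es$samples$group == group1]
  s2 <- es$samples$sample[es$samples$group == group2]
  if (length(s1) == 0 || length(s2) == 0) {
    abort(sprintf("unknown group(s): %s / %s", group1, group2))
  }
  raw <- counts_matrix(es$counts[, c("feature_id", s1, s2)])
  sf <- median_ratio_factors(raw)
  norm <- sweep(raw, 2, sf, `/`)
  groups <- rep(c(group1, group2), c(length(s1), length(s2)))
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(norm, groups)
  }
  idx1 <- seq_along(s1)
  idx2 <- length(s1) + seq_along(s2)
  m1 <- rowMeans(norm[, idx1, drop = FALSE])
  m2 <- rowMeans(norm[, idx2, drop = FALSE])
  log2fc <- log2(m2 + 0.5) - log2(m1 + 0.5)
  pvals <- vapply(seq_len(nrow(norm)), function(i) {
    nb_exact_test(round(norm[i, idx1]), round(norm[i, idx2]), dispersion)
  }, 0)
  adj <- bh_adjust(pvals)
  res <- tibble(
    feature_id = rownames(raw),
    base_mean_1 = m1, base_mean_2 = m2,
    log2fc = log2fc, p_value = pvals, adj_p = adj,
    status = classify_de(log2fc, if (use_adjusted) adj else pvals,
                         lfc = lfc, alpha = alpha)
  )
  structure(res,
            class = c("de_result", class(res)),
            dispersion = dispersion, lfc = lfc, alpha = alpha,
            groups = c(group1, group2), use_adjusted = use_adjusted)
}

# DESeq-style median-of-ratios size factors, falling back to totals when the
# geometric-mean reference is degenerate
median_ratio_factors <- function(mat) {
  log_gm <- rowMeans(log(mat))
  use <- is.finite(log_gm)
  sf <- if (sum(use) >= 10) {
    apply(mat[use, , drop = FALSE], 2, function(col) {
      exp(stats::median(log(col[col > 0]) - log_gm[use][col > 0]))
    })
  } else {
    totals <- colSums(mat)
    totals / exp(mean(log(totals)))
  }
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

#' @export
tidy.de_result <- function(x, ...) as_tibble(x)

#' @export
glance.de_result <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_up = sum(x$status == "up"),
    n_down = sum(x$status == "down"),
    dispersion = attr(x, "dispersion"),
    lfc_threshold = attr(x, "lfc"),
    alpha = attr(x, "alpha")
  )
}

#' Volcano plot of a differential-transcription result
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(pmax(.data$adj_p, 1e-300)),
    colour = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2c6fbb", ns = "grey60")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
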
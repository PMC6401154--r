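test_that("hypergeometric enrichment has its closed-form values", {
  # all 5 study genes carry the term among 10 genes: p = 1/choose(10,5)
  go <- tibble::tibble(gene_id = paste0("g", 1:5), term_id = "T1")
  res <- hypergeom_enrich(paste0("g", 1:5), paste0("g", 1:10), go)
  expect_equal(res$p_value, 1 / 252)
  expect_equal(res$k, 5)
  expect_equal(res$K, 5)

  # enrichment factor (5/50)/(100/10000) = 10
  pop <- sprintf("g%05d", 1:10000)
  study <- pop[1:50]
  go2 <- tibble::tibble(gene_id = pop[c(1:5, 101:195)], term_id = "T2")
  res2 <- hypergeom_enrich(study, pop, go2)
  expect_equal(res2$enrichment_factor, 10)
  expect_equal(res2$minus_log2_p, -log2(res2$p_value))
})

test_that("enrichment p equals brute-force tail summation for N <= 60", {
  set.seed(41)
  for (rep in 1:30) {
    N <- sample(10:60, 1)
    pop <- sprintf("g%02d", seq_len(N))
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    carriers <- sample(pop, K)
    study <- sample(pop, n)
    go <- tibble::tibble(gene_id = carriers, term_id = "T")
    k <- length(intersect(study, carriers))
    if (k == 0) next
    res <- hypergeom_enrich(study, pop, go)
    want <- sum(vapply(k:min(n, K), function(x) {
      choose(K, x) * choose(N - K, n - x) / choose(N, n)
    }, 0))
    expect_equal(res$p_value, want, tolerance = 1e-12)
  }
  expect_error(hypergeom_enrich(character(), "g1",
                                tibble::tibble(gene_id = "g1", term_id = "T")),
               "empty")
})

test_that("the whole population as study set has enrichment factor 1", {
  set.seed(42)
  pop <- sprintf("g%03d", 1:200)
  go <- tibble::tibble(
    gene_id = sample(pop, 300, replace = TRUE),
    term_id = sample(c("A", "B", "C"), 300, replace = TRUE)
  )
  res <- hypergeom_enrich(pop, pop, go)
  expect_true(all(abs(res$enrichment_factor - 1) < 1e-12))
  expect_true(all(res$p_value == 1))
})

test_that("nearest-gene correlation handles proportional and flat profiles", {
  samples <- tibble::tibble(sample = paste0("s", 1:4), group = "g",
                            library_size = 1e6)
  mk_es <- function(vals) {
    m <- tibble::tibble(feature_id = names(vals))
    for (i in 1:4) m[[paste0("s", i)]] <- vapply(vals, `[`, 0, i)
    structure(list(fpkm = m, counts = m, samples = samples),
              class = "expression_set")
  }
  lnc_es <- mk_es(list(l1 = c(1, 3, 7, 15), l2 = c(2, 2, 2, 2)))
  gene_es <- mk_es(list(g1 = c(3, 7, 15, 31)))  # exactly 2x (l1+1) scale
  nearest <- tibble::tibble(feature_id = c("l1", "l2"),
                            nearest_gene = c("g1", "g1"))
  res <- correlate_with_nearest_gene(lnc_es, gene_es, nearest)
  expect_equal(res$per_lncrna$r[1], 1)
  expect_true(is.na(res$per_lncrna$r[2]))
  # flat profile excluded from category means
  cats <- tibble::tibble(feature_id = c("l1", "l2"), category = "novel")
  res2 <- correlate_with_nearest_gene(lnc_es, gene_es, nearest,
                                      categories = cats)
  expect_equal(res2$per_category$mean_r, 1)
  expect_equal(res2$per_category$n, 1)
})

test_that("correlation is invariant under per-sample library rescaling", {
  b <- shared_bundle()
  es <- shared_expression()
  lnc_ids <- b$truth$feature_id[b$truth$class == "lncRNA"]
  gene_ids <- b$truth$feature_id[b$truth$class == "coding"]
  sub <- function(es, ids) {
    keep <- es$fpkm$feature_id %in% ids
    structure(list(fpkm = es$fpkm[keep, ], counts = es$counts[keep, ],
                   samples = es$samples), class = "expression_set")
  }
  nearest <- tibble::tibble(
    feature_id = lnc_ids,
    nearest_gene = b$truth$neighbor_gene[match(lnc_ids, b$truth$feature_id)]
  )
  r1 <- correlate_with_nearest_gene(sub(es, lnc_ids), sub(es, gene_ids),
                                    nearest)$per_lncrna
  # rescale every sample's FPKM by its own factor: log2 shifts per sample
  # cancel in Pearson up to the +1 pseudocount, so require near-equality on
  # well-expressed pairs only
  scale_es <- function(x, f) {
    for (i in seq_along(f)) x$fpkm[[x$samples$sample[i]]] <-
        x$fpkm[[x$samples$sample[i]]] * f[i]
    x
  }
  f <- rep(4, nrow(es$samples))
  r2 <- correlate_with_nearest_gene(scale_es(sub(es, lnc_ids), f),
                                    scale_es(sub(es, gene_ids), f),
                                    nearest)$per_lncrna
  keep <- !is.na(r1$r) & abs(r1$r) > 0.5
  expect_equal(r2$r[keep], r1$r[keep], tolerance = 0.05)
})

test_that("co-regulated divergent neighbours correlate strongly", {
  b <- shared_bundle()
  es <- shared_expression()
  tr <- b$truth
  de_lnc <- tr$feature_id[tr$class == "lncRNA" & tr$de_status != "ns"]
  nearest <- tibble::tibble(
    feature_id = de_lnc,
    nearest_gene = tr$neighbor_gene[match(de_lnc, tr$feature_id)]
  )
  nearest <- nearest[!is.na(nearest$nearest_gene), ]
  sub <- function(ids) {
    keep <- es$fpkm$feature_id %in% ids
    structure(list(fpkm = es$fpkm[keep, ], counts = es$counts[keep, ],
                   samples = es$samples), class = "expression_set")
  }
  res <- correlate_with_nearest_gene(
    sub(nearest$feature_id),
    sub(unique(nearest$nearest_gene)), nearest)
  expect_gte(mean(res$per_lncrna$r, na.rm = TRUE), 0.7)
})

test_that("GO transfer modes behave at the degenerate settings", {
  b <- shared_bundle()
  es <- shared_expression()
  tr <- b$truth
  lnc_ids <- tr$feature_id[tr$class == "lncRNA"]
  gene_ids <- tr$feature_id[tr$class == "coding"]
  sub <- function(ids) {
    keep <- es$fpkm$feature_id %in% ids
    structure(list(fpkm = es$fpkm[keep, ], counts = es$counts[keep, ],
                   samples = es$samples), class = "expression_set")
  }
  lnc_es <- sub(lnc_ids); gene_es <- sub(gene_ids)
  nearest <- tibble::tibble(
    feature_id = lnc_ids,
    nearest_gene = tr$neighbor_gene[match(lnc_ids, tr$feature_id)]
  )
  go <- b$motifs_go$go

  # impossible correlation floor -> no rows
  cats <- tibble::tibble(feature_id = lnc_ids[1:5], category = "x")
  expect_equal(nrow(transfer_go_to_lncrnas(cats, lnc_es, gene_es, nearest,
                                           go, mode = "correlation",
                                           r_min = 1.01)), 0)
  # nearest mode with a single lncRNA studies exactly its nearest gene
  one <- tibble::tibble(feature_id = lnc_ids[1], category = "solo")
  res <- transfer_go_to_lncrnas(one, lnc_es, gene_es, nearest, go,
                                mode = "nearest")
  if (nrow(res) > 0) {
    expect_true(all(res$n == 1))
  }
})

test_that("the planted GO term ranks first for up-regulated lncRNA neighbours", {
  b <- shared_bundle()
  es <- shared_expression()
  tr <- b$truth
  up_lnc <- tr$feature_id[tr$class == "lncRNA" & tr$de_status == "up"]
  gene_ids <- tr$feature_id[tr$class == "coding"]
  sub <- function(ids) {
    keep <- es$fpkm$feature_id %in% ids
    structure(list(fpkm = es$fpkm[keep, ], counts = es$counts[keep, ],
                   samples = es$samples), class = "expression_set")
  }
  nearest <- tibble::tibble(
    feature_id = up_lnc,
    nearest_gene = tr$neighbor_gene[match(up_lnc, tr$feature_id)]
  )
  res <- transfer_go_to_lncrnas(
    tibble::tibble(feature_id = up_lnc, category = "up"),
    sub(up_lnc), sub(gene_ids), nearest, b$motifs_go$go, mode = "nearest")
  expect_equal(res$term_id[1], b$motifs_go$planted$go_up_term)
})

test_that("hub miRNAs are exactly the planted high-degree nodes", {
  edges <- tibble::tibble(
    mirna_id = c(rep("hub1", 5), rep("hub2", 4), "low1", "low2", "off1"),
    gene_id = sprintf("g%02d", 1:12)
  )
  net <- hub_mirnas(edges, c("hub1", "hub2", "low1", "low2"), min_degree = 4)
  expect_setequal(net$hubs, c("hub1", "hub2"))
  expect_false("off1" %in% net$degrees$mirna_id)  # not expressed
  expect_equal(nrow(net$edges), 11)

  all_hubs <- hub_mirnas(edges, unique(edges$mirna_id), min_degree = 1)
  expect_setequal(all_hubs$hubs, unique(edges$mirna_id))
  none <- hub_mirnas(edges, unique(edges$mirna_id), min_degree = 99)
  expect_equal(length(none$hubs), 0)

  b <- shared_bundle()
  planted <- b$motifs_go$planted
  net2 <- hub_mirnas(b$motifs_go$targets,
                     unique(b$motifs_go$targets$mirna_id),
                     min_degree = planted$hub_degree)
  expect_setequal(net2$hubs, planted$hub_mirnas)
})
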
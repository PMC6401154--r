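#' Assemble a pipeline run configuration
#'
#' Either `simulate` (a [sim_config()]) or `input_dir` (a directory laid out
#' like a [simulate_bundle()] output) must be given. Thresholds mirror the
#' stage functions' defaults: the expressed-transcript FPKM cutoff, the
#' differential-transcription thresholds, the classifier windows, the
#' guilt-by-association correlation floor and the hub degree.
#'
#' @param simulate Optional [sim_config()]; when set, inputs are generated.
#' @param input_dir Optional directory of existing inputs.
#' @param fpkm_min,lfc,alpha,tss_window,pair_window,r_min,min_degree,
#'   motif_flank Threshold overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, input_dir = NULL, fpkm_min = 1,
                       lfc = 2, alpha = 0.05, tss_window = 1000,
                       pair_window = 500, r_min = 0.7, min_degree = 10,
                       motif_flank = 200) {
  if (is.null(simulate) && is.null(input_dir)) {
    abort("run_config needs `simulate` or `input_dir`")
  }
  thr <- c(fpkm_min = fpkm_min, lfc = lfc, alpha = alpha,
           tss_window = tss_window, pair_window = pair_window,
           r_min = r_min, min_degree = min_degree, motif_flank = motif_flank)
  if (any(thr <= 0 & names(thr) != "fpkm_min")) abort("thresholds must be positive")
  structure(list(simulate = simulate, input_dir = input_dir,
                 thresholds = as.list(thr)),
            class = "run_config")
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

read_bundle <- function(dir) {
  need <- c("transcripts.tsv", "manifest.yaml", "h3k4me3.bed", "h3k4me1.bed",
            "superenhancers.bed", "motifs.pwm", "go.tsv", "targets.tsv",
            "tf2motif.tsv", "genome.fa")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      abort(sprintf("input missing: %s", file.path(dir, f)))
    }
  }
  manifest <- read_manifest(file.path(dir, "manifest.yaml"))
  tracks <- list()
  for (i in seq_len(nrow(manifest$samples))) {
    s <- manifest$samples[i, ]
    for (f in c(s$plus, s$minus)) {
      if (!file.exists(file.path(dir, f))) {
        abort(sprintf("input missing: %s", file.path(dir, f)))
      }
    }
    tracks[[s$sample]] <- read_signal_track(file.path(dir, s$plus),
                                            file.path(dir, s$minus))
  }
  list(
    transcripts = read_transcript_table(file.path(dir, "transcripts.tsv")),
    tracks = tracks,
    samples = select(manifest$samples, "sample", "group"),
    chromatin = list(
      h3k4me3 = read_bed(file.path(dir, "h3k4me3.bed")),
      h3k4me1 = read_bed(file.path(dir, "h3k4me1.bed")),
      superenhancers = read_bed(file.path(dir, "superenhancers.bed"))
    ),
    motifs_go = list(
      genome = read_fasta(file.path(dir, "genome.fa")),
      pwms = read_pwms(file.path(dir, "motifs.pwm")),
      go = read_mapping_table(file.path(dir, "go.tsv"),
                              c("gene_id", "term_id")),
      targets = read_mapping_table(file.path(dir, "targets.tsv"),
                                   c("mirna_id", "gene_id")),
      tf2motif = read_mapping_table(file.path(dir, "tf2motif.tsv"),
                                    c("tf_id", "motif"))
    ),
    manifest = manifest
  )
}

write_stage_tsv <- function(df, path, stage, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s; params: %s", stage, hash), con)
  writeLines(readr::format_tsv(df), con, sep = "")
  invisible(path)
}

#' Run the full nascent-transcriptome pipeline
#'
#' Stage order: input (simulate or load) -> quantification -> expression
#' filter -> differential transcription (each non-reference group vs the
#' first group, separately for coding genes and lncRNAs) -> TSS-switch
#' analysis of multi-TSS loci -> lncRNA classification -> nearest-gene
#' correlation, GO enrichment and transfer, hub miRNAs -> motif enrichment
#' at up/down lncRNA TSSs (plus TF-motif correlation when there are at
#' least 3 groups). Every stage TSV carries a header naming the stage and
#' the parameter hash; a rerun with the same config is byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list of in-memory stage results plus `files`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds
  hash <- substr(digest::digest(config), 1, 12)

  log_stage("input", "preparing inputs")
  bundle <- if (!is.null(config$simulate)) {
    simulate_bundle(config$simulate, NULL)
  } else {
    read_bundle(config$input_dir)
  }
  tx <- bundle$transcripts
  samples <- select(bundle$samples, "sample", "group")
  groups <- unique(samples$group)
  ref <- groups[1]

  log_stage("quantify", sprintf("%d features x %d samples",
                                nrow(tx), nrow(samples)))
  es <- quantify_matrix(rename(tx, feature_id = "transcript_id"),
                        bundle$tracks, samples)
  es_f <- filter_expressed(es, thr$fpkm_min)
  write_stage_tsv(es$fpkm, file.path(out_dir, "expression.tsv"),
                  "quantify", hash)

  classes_of <- function(cls) {
    tx$transcript_id[tx$class == cls & tx$transcript_id %in% es_f$fpkm$feature_id]
  }
  subset_es <- function(ids) {
    keep <- es_f$fpkm$feature_id %in% ids
    structure(list(fpkm = es_f$fpkm[keep, ], counts = es_f$counts[keep, ],
                   samples = es_f$samples), class = "expression_set")
  }

  log_stage("de", "differential transcription")
  de_for <- function(ids) {
    sub <- subset_es(ids)
    bind_rows(lapply(setdiff(groups, ref), function(g) {
      mutate(as_tibble(de_test(sub, ref, g, lfc = thr$lfc, alpha = thr$alpha)),
             comparison = paste0(g, "_vs_", ref), .before = 1)
    }))
  }
  de_coding <- de_for(classes_of("coding"))
  de_lnc <- de_for(classes_of("lncRNA"))
  write_stage_tsv(de_coding, file.path(out_dir, "de_coding.tsv"), "de", hash)
  write_stage_tsv(de_lnc, file.path(out_dir, "de_lncrna.tsv"), "de", hash)

  log_stage("tss", "TSS-variant profiles and switching")
  prof <- build_tss_profiles(filter(tx, .data$class == "pri_miRNA_TV"),
                             bundle$tracks, samples)
  switching <- detect_tss_switching(prof, min_fpkm = thr$fpkm_min)
  write_stage_tsv(switching, file.path(out_dir, "tss_switching.tsv"),
                  "tss", hash)
  clu <- tryCatch(cluster_tss_profiles(prof), error = function(e) NULL)
  if (!is.null(clu)) {
    export_newick(clu$hclust, file.path(out_dir, "tss_dendrogram.nwk"))
  }

  log_stage("classify", "lncRNA classes")
  lnc <- filter(tx, .data$class == "lncRNA")
  cls <- classify_lncrnas(
    lnc,
    bundle$chromatin$h3k4me3, bundle$chromatin$h3k4me1,
    bundle$chromatin$superenhancers,
    tss_window = thr$tss_window, pair_window = thr$pair_window
  )
  write_stage_tsv(as_tibble(cls), file.path(out_dir, "lncrna_classes.tsv"),
                  "classify", hash)

  log_stage("associate", "nearest genes, GO, hubs")
  genes <- filter(tx, .data$class == "coding")
  nearest <- nearest_tss(
    tibble(feature_id = lnc$transcript_id, chrom = lnc$chrom, tss = lnc$tss),
    tibble(gene_id = genes$transcript_id, chrom = genes$chrom, tss = genes$tss)
  ) |>
    select("feature_id", "nearest_gene", "distance")
  lnc_es <- subset_es(classes_of("lncRNA"))
  gene_es <- subset_es(classes_of("coding"))
  corr <- correlate_with_nearest_gene(
    lnc_es, gene_es, nearest,
    categories = lnc_categories(cls)
  )
  write_stage_tsv(corr$per_lncrna, file.path(out_dir, "lnc_gene_corr.tsv"),
                  "associate", hash)
  go_up <- de_coding |>
    filter(.data$status == "up") |>
    distinct(.data$feature_id)
  enr <- if (nrow(go_up) > 0) {
    mutate(as_tibble(hypergeom_enrich(go_up$feature_id,
                                      genes$transcript_id,
                                      bundle$motifs_go$go)),
           study = "up_coding", .before = 1)
  } else {
    tibble()
  }
  transfer <- transfer_go_to_lncrnas(
    lnc_categories(cls), lnc_es, gene_es, nearest, bundle$motifs_go$go,
    mode = "nearest", r_min = thr$r_min
  )
  go_out <- bind_rows(enr,
                      if (nrow(transfer) > 0) rename(transfer, study = "category"))
  write_stage_tsv(go_out, file.path(out_dir, "go_enrichment.tsv"),
                  "associate", hash)
  expressed_mirs <- unique(tx$locus_id[tx$class == "pri_miRNA_TV" &
                                         tx$transcript_id %in% es_f$fpkm$feature_id])
  net <- hub_mirnas(bundle$motifs_go$targets, expressed_mirs,
                    min_degree = thr$min_degree)
  write_stage_tsv(net$degrees, file.path(out_dir, "hubs.tsv"),
                  "associate", hash)

  log_stage("motifs", "PWM enrichment at lncRNA TSSs")
  first_cmp <- paste0(setdiff(groups, ref)[1], "_vs_", ref)
  de1 <- filter(de_lnc, .data$comparison == first_cmp)
  sets <- split(de1$feature_id, de1$status)
  win_of <- function(ids) {
    extract_tss_windows(bundle$motifs_go$genome,
                        filter(lnc, .data$transcript_id %in% ids) |>
                          rename(feature_id = "transcript_id"),
                        flank = thr$motif_flank)
  }
  bg <- win_of(sets$ns %||% character())
  menr <- bind_rows(lapply(c("up", "down"), function(st) {
    ids <- sets[[st]] %||% character()
    if (length(ids) == 0) return(NULL)
    as_tibble(motif_enrichment(win_of(ids), bg, bundle$motifs_go$pwms,
                               set_name = st))
  }))
  write_stage_tsv(menr, file.path(out_dir, "motif_enrichment.tsv"),
                  "motifs", hash)
  tfcor <- NULL
  if (length(groups) >= 3) {
    gm <- group_means(normalize_expression(gene_es))
    tf_expr <- filter(gm, .data$feature_id %in% bundle$motifs_go$tf2motif$tf_id) |>
      rename(tf_id = "feature_id")
    lnc_gm <- group_means(normalize_expression(lnc_es))
    dominant_grp <- names(lnc_gm)[-1][apply(as.matrix(lnc_gm[, -1]), 1, which.max)]
    enr_by_set <- bind_rows(lapply(groups, function(g) {
      ids <- lnc_gm$feature_id[dominant_grp == g]
      others <- setdiff(lnc_gm$feature_id, ids)
      if (length(ids) == 0) return(NULL)
      mutate(as_tibble(motif_enrichment(win_of(ids), win_of(others),
                                        bundle$motifs_go$pwms, set_name = g)),
             .keep = "all")
    }))
    motif_wide <- enr_by_set |>
      select("motif", "set", "target_pct") |>
      pivot_wider(names_from = "set", values_from = "target_pct")
    tf_expr <- tf_expr[, c("tf_id", names(motif_wide)[-1])]
    tfcor <- tf_motif_correlation(tf_expr, motif_wide,
                                  bundle$motifs_go$tf2motif)
    write_stage_tsv(tfcor$pairs, file.path(out_dir, "tf_motif_corr.tsv"),
                    "motifs", hash)
  }

  run_manifest <- list(
    params_hash = hash,
    thresholds = thr,
    n_samples = nrow(samples),
    groups = as.list(table(samples$group)),
    files = list.files(out_dir, pattern = "\\.(tsv|nwk)$")
  )
  jsonlite::write_json(run_manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("done", out_dir)
  invisible(list(
    expression = es, filtered = es_f, de_coding = de_coding,
    de_lncrna = de_lnc, profiles = prof, switching = switching,
    classes = cls, correlation = corr, go = go_out, network = net,
    motif_enrichment = menr, tf_motif = tfcor, files = run_manifest$files
  ))
}

# overlapping membership table used by association stages
lnc_categories <- function(cls) {
  bind_rows(
    tibble(feature_id = cls$transcript_id[!cls$known], category = "novel"),
    tibble(feature_id = cls$transcript_id[cls$chromatin_class == "promoter"],
           category = "promoter"),
    tibble(feature_id = cls$transcript_id[cls$chromatin_class == "enhancer"],
           category = "enhancer"),
    tibble(feature_id = cls$transcript_id[cls$se_flag], category = "SE")
  )
}

#' Summarize a completed pipeline run
#'
#' Recomputes headline counts from the stage TSVs on disk (never from
#' cached objects): expressed features, up/down differential calls per
#' comparison, switching loci, lncRNA class tallies and hub miRNAs.
#' Missing stages are reported as such, so a partial run still summarizes.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @return Character vector of report lines (also printed).
#' @export
summarize_run <- function(out_dir) {
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) return(NULL)
    readr::read_tsv(p, comment = "#", col_types = readr::cols(),
                    progress = FALSE)
  }
  lines <- c(sprintf("nascentscape run summary: %s", out_dir))
  expr <- rd("expression.tsv")
  lines <- c(lines, if (is.null(expr)) "quantify: MISSING" else
    sprintf("quantify: %d features x %d samples", nrow(expr), ncol(expr) - 1))
  for (f in c(coding = "de_coding.tsv", lncRNA = "de_lncrna.tsv")) {
    de <- rd(f)
    lines <- c(lines, if (is.null(de)) sprintf("%s: MISSING", f) else {
      if (nrow(de) == 0) sprintf("de (%s): 0 up, 0 down", f) else {
        paste(sprintf(
          "de (%s) %s: %d up, %d down",
          sub("de_(.*)\\.tsv", "\\1", f),
          unique(de$comparison),
          vapply(unique(de$comparison), function(cc)
            sum(de$status == "up" & de$comparison == cc), 0L),
          vapply(unique(de$comparison), function(cc)
            sum(de$status == "down" & de$comparison == cc), 0L)
        ), collapse = "; ")
      }
    })
  }
  sw <- rd("tss_switching.tsv")
  lines <- c(lines, if (is.null(sw)) "tss: MISSING" else
    sprintf("tss: %d multi-TSS loci, %d switching", nrow(sw),
            sum(sw$switching)))
  cls <- rd("lncrna_classes.tsv")
  lines <- c(lines, if (is.null(cls)) "classify: MISSING" else
    sprintf("classify: %d lncRNAs (%d promoter / %d enhancer / %d unclassified), %d bidirectional, %d SE",
            nrow(cls), sum(cls$chromatin_class == "promoter"),
            sum(cls$chromatin_class == "enhancer"),
            sum(cls$chromatin_class == "unclassified"),
            sum(!is.na(cls$partner_id)), sum(cls$se_flag)))
  hubs <- rd("hubs.tsv")
  lines <- c(lines, if (is.null(hubs)) "hubs: MISSING" else
    sprintf("hubs: %d expressed miRNAs, %d hubs", nrow(hubs), sum(hubs$hub)))
  menr <- rd("motif_enrichment.tsv")
  lines <- c(lines, if (is.null(menr)) "motifs: MISSING" else
    sprintf("motifs: %d motif x set tests, %d at adj p < 0.05", nrow(menr),
            sum(menr$adj_p < 0.05)))
  writeLines(lines)
  invisible(lines)
}
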
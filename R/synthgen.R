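#' Generate the synthetic annotation and its ground truth
#'
#' Lays out non-overlapping loci on the simulated genome and plants the full
#' ground truth for every downstream stage:
#'
#' * coding genes, a subset of which are TF genes (`TF_<motif>`) whose
#'   direction of regulation matches their motif's planted enrichment;
#' * lncRNAs, each placed next to a dedicated coding gene whose expression it
#'   shares (the guilt-by-association signal), a `frac_bidirectional` share
#'   of them with a divergent opposite-strand partner whose TSS lies 100-400
#'   bp upstream;
#' * pri-miRNA loci with `k` alternative TSSs (drawn from
#'   `tss_per_locus_range`) sharing one 3' terminus; a `frac_switching` share
#'   flips its dominant TSS (4-fold dominance) between the reference group
#'   and the others.
#'
#' Geometry guarantees: same-strand loci never overlap; chromatin peaks of
#' different loci are separated by more than the +/-1 kb TSS windows used by
#' the classifier; each lncRNA's nearest coding-gene TSS is its dedicated
#' neighbour.
#'
#' @param config A [sim_config()].
#' @return A list with `transcripts` (tibble: transcript_id, locus_id, class,
#'   chrom, start, end, strand, tss) and `truth` (one row per feature with
#'   planted rates `rate_<group>`, expected FPKM `mu_<group>`, DE status and
#'   log2 fold change, chromatin class, SE flag, partner and neighbour ids,
#'   dominant TSS per group, planted motif names).
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  grp <- names(config$groups)
  ref <- grp[1]
  n_tf <- length(config$motif_names)
  if (config$n_coding < config$n_lncrna + n_tf) {
    abort(sprintf(
      "n_coding (%d) must be >= n_lncrna + length(motif_names) (%d): each lncRNA needs a dedicated neighbour gene",
      config$n_coding, config$n_lncrna + n_tf
    ))
  }

  n_pair <- config$n_lncrna
  n_free <- config$n_coding - n_tf - n_pair
  gene_ids <- sprintf("gene_%04d", seq_len(config$n_coding - n_tf))
  tf_ids <- if (n_tf > 0) paste0("TF_", config$motif_names) else character()
  lnc_ids <- sprintf("lnc_%04d", seq_len(config$n_lncrna))
  mir_ids <- sprintf("mir_%03d", seq_len(config$n_primirna_loci))
  partnered <- rep(FALSE, n_pair)
  if (n_pair > 0 && config$frac_bidirectional > 0) {
    partnered[sample.int(n_pair, round(config$frac_bidirectional * n_pair))] <- TRUE
  }

  # ---- build blocks in local "+"-template coordinates ----------------------
  blocks <- list()
  for (i in seq_len(n_pair)) {
    glen <- sample(2000:6000, 1)
    hlen <- sample(600:2500, 1)
    D <- sample(1850:2300, 1)    # gene-TSS to lncRNA-TSS distance
    feats <- tibble(
      feature_id = c(gene_ids[i], lnc_ids[i]),
      locus_id = c(gene_ids[i], lnc_ids[i]),
      class = c("coding", "lncRNA"),
      start = c(0, glen - 1 + D),
      end = c(glen, glen - 1 + D + hlen),
      strand = c("-", "+"),
      tv_index = NA_integer_
    )
    if (partnered[i]) {
      d <- sample(100:400, 1)
      plen <- sample(400:1200, 1)
      htss <- glen - 1 + D
      feats <- bind_rows(feats, tibble(
        feature_id = paste0(lnc_ids[i], "_div"),
        locus_id = lnc_ids[i],
        class = "lncRNA",
        start = htss - d - plen + 1, end = htss - d + 1,
        strand = "-", tv_index = NA_integer_
      ))
    }
    blocks[[length(blocks) + 1]] <- list(width = max(feats$end), feats = feats)
  }
  for (id in c(tf_ids, if (n_free > 0) gene_ids[n_pair + seq_len(n_free)])) {
    glen <- sample(2000:6000, 1)
    blocks[[length(blocks) + 1]] <- list(
      width = glen,
      feats = tibble(
        feature_id = id, locus_id = id, class = "coding",
        start = 0, end = glen, strand = "+", tv_index = NA_integer_
      )
    )
  }
  for (j in seq_len(config$n_primirna_loci)) {
    r <- config$tss_per_locus_range
    k <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
    seg_len <- sample(500:1200, k, replace = TRUE)
    tss_local <- cumsum(c(0, seg_len[-k]))
    W <- sum(seg_len)
    blocks[[length(blocks) + 1]] <- list(
      width = W,
      feats = tibble(
        feature_id = paste0(mir_ids[j], "_TV", seq_len(k)),
        locus_id = mir_ids[j], class = "pri_miRNA_TV",
        start = tss_local, end = W, strand = "+",
        tv_index = seq_len(k)
      )
    )
  }

  # ---- place blocks on chromosomes with wide gaps --------------------------
  blocks <- blocks[sample.int(length(blocks))]
  orient <- sample(c("+", "-"), length(blocks), replace = TRUE)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  margin <- 1500  # flank so peaks/windows/motif plants stay off block edges
  cursor <- 0; ci <- 1
  placed <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    gap <- sample(2500:3500, 1)
    need <- gap + margin + blocks[[b]]$width + margin
    if (cursor + need > config$chrom_length) {
      ci <- ci + 1; cursor <- 0
      if (ci > config$n_chroms) {
        remaining <- sum(vapply(
          blocks[b:length(blocks)],
          function(x) x$width + 2 * margin + 5000, 0
        ))
        abort(sprintf(
          "genome too small: ~%d more bp needed to place the remaining %d loci",
          remaining, length(blocks) - b + 1
        ))
      }
    }
    offset <- cursor + gap + margin
    f <- blocks[[b]]$feats
    if (orient[b] == "-") {
      W <- blocks[[b]]$width
      f <- mutate(f,
        start2 = W - .data$end, end = W - .data$start,
        start = .data$start2,
        strand = ifelse(.data$strand == "+", "-", "+")
      ) |> select(-"start2")
    }
    f <- mutate(f, chrom = chroms[ci],
                start = .data$start + offset, end = .data$end + offset)
    placed[[b]] <- f
    cursor <- offset + blocks[[b]]$width + margin
  }
  tx <- bind_rows(placed) |>
    mutate(tss = ifelse(.data$strand == "-", .data$end - 1, .data$start),
           length = .data$end - .data$start) |>
    select("feature_id", "locus_id", "class", "chrom", "start", "end",
           "strand", "tss", "length", "tv_index")

  # ---- planted expression, DE, switching -----------------------------------
  truth <- tx
  truth$partner_id <- NA_character_
  truth$neighbor_gene <- NA_character_
  host <- match(paste0(lnc_ids, "_div"), truth$feature_id)
  has_div <- !is.na(host)
  truth$partner_id[match(lnc_ids[has_div], truth$feature_id)] <-
    paste0(lnc_ids[has_div], "_div")
  truth$partner_id[host[has_div]] <- lnc_ids[has_div]
  lnc_rows <- truth$class == "lncRNA"
  truth$neighbor_gene[match(lnc_ids, truth$feature_id)] <- gene_ids[seq_len(n_pair)]
  truth$neighbor_gene[host[has_div]] <- gene_ids[seq_len(n_pair)][has_div]

  lfc_mag <- log2(config$fold_change_planted)
  truth$de_status <- "ns"; truth$true_log2fc <- 0
  pick_de <- function(ids) {
    n_de <- round(config$frac_de * length(ids))
    chosen <- sample(ids, n_de)
    list(up = chosen[seq_len(ceiling(n_de / 2))],
         down = chosen[setdiff(seq_len(n_de), seq_len(ceiling(n_de / 2)))])
  }
  de_lnc <- pick_de(lnc_ids)
  free_ids <- if (n_free > 0) gene_ids[n_pair + seq_len(n_free)] else character()
  de_free <- pick_de(free_ids)
  up_tf <- tf_ids[seq_len(ceiling(n_tf / 2))]
  down_tf <- setdiff(tf_ids, up_tf)
  set_de <- function(truth, ids, status) {
    idx <- truth$feature_id %in% ids
    truth$de_status[idx] <- status
    truth$true_log2fc[idx] <- if (status == "up") lfc_mag else -lfc_mag
    truth
  }
  truth <- set_de(truth, de_lnc$up, "up") |>
    set_de(de_lnc$down, "down") |>
    set_de(de_free$up, "up") |> set_de(de_free$down, "down") |>
    set_de(up_tf, "up") |> set_de(down_tf, "down")
  # neighbour genes and divergent partners share the host lncRNA's regulation
  for (i in seq_len(n_pair)) {
    src <- match(lnc_ids[i], truth$feature_id)
    for (tgt in c(match(gene_ids[i], truth$feature_id), host[i])) {
      if (!is.na(tgt)) {
        truth$de_status[tgt] <- truth$de_status[src]
        truth$true_log2fc[tgt] <- truth$true_log2fc[src]
      }
    }
  }

  # pri-miRNA dominant-TSS structure
  truth$k <- NA_integer_; truth$switching <- NA
  dom <- matrix(NA_integer_, nrow(truth), length(grp),
                dimnames = list(NULL, paste0("dom_", grp)))
  n_sw <- round(config$frac_switching * config$n_primirna_loci)
  sw_loci <- if (n_sw > 0) sample(mir_ids, n_sw) else character()
  locus_base <- stats::setNames(
    config$base_expression * 2^runif(config$n_primirna_loci, -1, 1), mir_ids
  )
  for (m in mir_ids) {
    rows <- which(truth$locus_id == m)
    k <- length(rows)
    truth$k[rows] <- k
    truth$switching[rows] <- m %in% sw_loci
    if (m %in% sw_loci) {
      dd <- sample(k, 2)
      dom[rows, ] <- matrix(rep(c(dd[1], rep(dd[2], length(grp) - 1)),
                                each = k), nrow = k)
    } else {
      dom[rows, ] <- sample(k, 1)
    }
  }
  truth <- bind_cols(truth, as_tibble(dom))

  # planted per-group rates on the FPKM scale
  mu_raw <- config$base_expression * 2^runif(nrow(truth), -1.5, 1.5)
  partner_idx <- which(!is.na(truth$partner_id) & grepl("_div$", truth$feature_id))
  mu_raw[partner_idx] <-
    0.5 * mu_raw[match(truth$partner_id[partner_idx], truth$feature_id)]
  # non-reference groups get a graded share of the planted log2FC (a
  # differentiation gradient); with two groups this is the full effect
  rate <- matrix(mu_raw, nrow(truth), length(grp),
                 dimnames = list(NULL, paste0("rate_", grp)))
  for (g in seq_along(grp)[-1]) {
    frac <- (g - 1) / (length(grp) - 1)
    rate[, g] <- mu_raw * 2^(truth$true_log2fc * frac)
  }
  for (m in mir_ids) {
    rows <- which(truth$locus_id == m)
    for (g in seq_along(grp)) {
      dom_tv <- dom[rows[1], g]
      rate[rows, g] <- locus_base[m] *
        ifelse(truth$tv_index[rows] == dom_tv, 1, 0.25)
    }
  }
  # normalize so expected read count per sample equals the library size
  len_kb <- truth$length / 1000
  scale <- 1e6 / sum(rate[, 1] * len_kb)
  rate <- rate * scale
  totals <- colSums(rate * len_kb)  # per-group expected total, FPKM x kb
  mu <- sweep(rate, 2, 1e6 / totals, `*`)
  colnames(mu) <- paste0("mu_", grp)
  truth <- bind_cols(truth, as_tibble(rate), as_tibble(mu))

  # motif planting targets: DE lncRNA TSSs carry the direction's motifs
  truth$motifs <- ""
  if (n_tf > 0) {
    up_motifs <- config$motif_names[seq_len(ceiling(n_tf / 2))]
    down_motifs <- setdiff(config$motif_names, up_motifs)
    for (i in which(lnc_rows)) {
      pool <- if (truth$de_status[i] == "up") up_motifs
              else if (truth$de_status[i] == "down") down_motifs
              else character()
      keep <- pool[runif(length(pool)) < 0.9]
      truth$motifs[i] <- paste(keep, collapse = ";")
    }
  }

  # chromatin classes and super-enhancer flags (lncRNAs only);
  # divergent partners share their host's regulatory element
  truth$chromatin_class <- NA_character_
  truth$se_flag <- FALSE
  cls <- ifelse(runif(n_pair) < config$frac_enhancer, "enhancer", "promoter")
  se <- cls == "enhancer" & runif(n_pair) < config$frac_se
  truth$chromatin_class[match(lnc_ids, truth$feature_id)] <- cls
  truth$se_flag[match(lnc_ids, truth$feature_id)] <- se
  truth$chromatin_class[host[has_div]] <- cls[has_div]
  truth$se_flag[host[has_div]] <- se[has_div]
  truth$is_tf <- truth$feature_id %in% tf_ids

  list(
    transcripts = tx |> rename(transcript_id = "feature_id") |>
      select("transcript_id", "locus_id", "class", "chrom", "start", "end",
             "strand", "tss", "tv_index"),
    truth = truth
  )
}

#' Simulate stranded GRO-seq coverage for every sample
#'
#' Per feature and sample, a read count is drawn negative-binomially with
#' mean `rate * length_kb * library_size / 1e6` and dispersion
#' `nb_dispersion` (Poisson when 0), and the reads are placed uniformly over
#' the feature span on its strand at 1-bp resolution. Multi-TSS transcript
#' variants each cover their full span from their own TSS to the shared 3'
#' end, so downstream segments accumulate the initiation signal of all
#' upstream TSSs, as in nascent-transcription data.
#'
#' @param annotation Result of [generate_annotation()] (only `truth` is used).
#' @param truth The ground-truth tibble with `rate_<group>` columns.
#' @param config The [sim_config()].
#' @return A list with `tracks` (named list of [signal_track()], one per
#'   sample, library size = realized total coverage) and `samples` (tibble:
#'   sample, group, library_size).
#' @export
simulate_signal <- function(annotation, truth, config) {
  set.seed(config$seed + 1L)
  samples <- sim_samples(config)
  phi <- config$nb_dispersion
  len_kb <- truth$length / 1000
  tracks <- vector("list", nrow(samples))
  names(tracks) <- samples$sample
  for (s in seq_len(nrow(samples))) {
    mu_counts <- truth[[paste0("rate_", samples$group[s])]] * len_kb *
      samples$library_size[s] / 1e6
    counts <- if (phi > 0) {
      rnbinom(length(mu_counts), mu = mu_counts, size = 1 / phi)
    } else {
      rpois(length(mu_counts), mu_counts)
    }
    key <- paste(rep(truth$chrom, counts), rep(truth$strand, counts),
                 sep = "\r")
    p <- unlist(map(which(counts > 0), function(i) {
      truth$start[i] + sample.int(truth$length[i], counts[i],
                                  replace = TRUE) - 1L
    })) %||% integer()
    runs_list <- lapply(split(p, key), function(pp) {
      cov <- tabulate(pp + 1L, nbins = max(pp) + 1L)
      r <- rle(cov)
      ends <- cumsum(r$lengths)
      keep <- r$values > 0
      list(start = (ends - r$lengths)[keep], end = ends[keep],
           value = r$values[keep])
    })
    ks <- strsplit(names(runs_list), "\r", fixed = TRUE)
    runs <- tibble(
      chrom = rep(vapply(ks, `[`, "", 1),
                  vapply(runs_list, function(x) length(x$start), 0L)),
      start = unlist(lapply(runs_list, `[[`, "start")),
      end = unlist(lapply(runs_list, `[[`, "end")),
      value = unlist(lapply(runs_list, `[[`, "value")),
      strand = rep(vapply(ks, `[`, "", 2),
                   vapply(runs_list, function(x) length(x$start), 0L))
    )
    tracks[[s]] <- signal_track(runs)
  }
  samples$library_size <- unname(vapply(tracks, function(t) t$library_size, 0))
  list(tracks = tracks, samples = samples)
}

#' Generate H3K4me3/H3K4me1 peak sets and super-enhancer intervals
#'
#' H3K4me3 peaks cover every coding-gene TSS and every promoter-class lncRNA
#' TSS; H3K4me1 peaks cover enhancer-class lncRNA TSSs only. Super-enhancer
#' intervals span each SE-flagged lncRNA with a 1 kb flank. Peaks are 600 bp
#' wide, centred on the TSS, optionally shifted by a uniform jitter of up to
#' `peak_jitter * width` bp, and overlapping intervals within one mark are
#' merged.
#'
#' @inheritParams simulate_signal
#' @return List of interval tibbles `h3k4me3`, `h3k4me1`, `superenhancers`.
#' @export
generate_chromatin <- function(annotation, truth, config) {
  set.seed(config$seed + 2L)
  half <- 300L
  jitter_bp <- function(n) {
    if (config$peak_jitter <= 0) return(rep(0L, n))
    as.integer(round(runif(n, -1, 1) * config$peak_jitter * 2 * half))
  }
  peak_at <- function(rows, mark) {
    if (length(rows) == 0) {
      return(tibble(chrom = character(), start = double(), end = double(),
                    name = character()))
    }
    sh <- jitter_bp(length(rows))
    merge_intervals(tibble(
      chrom = truth$chrom[rows],
      start = pmax(0, truth$tss[rows] - half + sh),
      end = truth$tss[rows] + half + sh,
      name = mark
    ))
  }
  me3_rows <- which(truth$class == "coding" |
    (!is.na(truth$chromatin_class) & truth$chromatin_class == "promoter"))
  me1_rows <- which(!is.na(truth$chromatin_class) &
                      truth$chromatin_class == "enhancer")
  se_rows <- which(truth$se_flag)
  se <- if (length(se_rows) > 0) {
    merge_intervals(tibble(
      chrom = truth$chrom[se_rows],
      start = pmax(0, truth$start[se_rows] - 1000),
      end = truth$end[se_rows] + 1000,
      name = "SE"
    ))
  } else {
    tibble(chrom = character(), start = double(), end = double(),
           name = character())
  }
  list(
    h3k4me3 = peak_at(me3_rows, "H3K4me3"),
    h3k4me1 = peak_at(me1_rows, "H3K4me1"),
    superenhancers = se
  )
}

# merge overlapping/touching intervals per chromosome
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end), default = -Inf))) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              name = .data$name[1], .groups = "drop") |>
    mutate(name = sprintf("%s_%d", .data$name, dplyr::row_number())) |>
    select("chrom", "start", "end", "name")
}

#' Generate the genome sequence, PWMs, GO table and miRNA-target table
#'
#' The genome is uniform-composition random sequence (25% per base). Each
#' motif gets a width-8 consensus with 0.91/0.03 column probabilities; its
#' consensus string is written within +/-200 bp of each TSS the truth table
#' lists for it, at non-colliding positions. The GO table plants one term
#' enriched among up-regulated coding genes and one among down-regulated
#' genes, plus uniform background terms; the miRNA-target table plants
#' high-degree hub miRNAs.
#'
#' @inheritParams simulate_signal
#' @return List with `genome` (named character vector), `pwms` (named list of
#'   matrices), `consensus` (named character), `plants` (tibble of planted
#'   instances), `go` (gene_id, term_id), `targets` (mirna_id, gene_id),
#'   `tf2motif` (tf_id, motif), `planted` (list: go_up_term, go_down_term,
#'   hub_mirnas, hub_degree).
#' @export
generate_motifs_and_go <- function(annotation, truth, config) {
  set.seed(config$seed + 3L)
  bases <- c("A", "C", "G", "T")
  genome <- stats::setNames(
    vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(bases, config$chrom_length, replace = TRUE), collapse = "")
    }, ""),
    sprintf("chr%d", seq_len(config$n_chroms))
  )

  w <- 8L
  pwms <- list(); consensus <- character()
  for (m in config$motif_names) {
    cons <- sample(bases, w, replace = TRUE)
    mat <- matrix(0.03, 4, w, dimnames = list(bases, NULL))
    mat[cbind(match(cons, bases), seq_len(w))] <- 0.91
    pwms[[m]] <- mat
    consensus[m] <- paste(cons, collapse = "")
  }

  # plant consensus instances near TSSs, avoiding collisions between plants
  occupied <- list()
  plants <- list()
  plant_rows <- which(truth$motifs != "")
  for (i in plant_rows) {
    for (m in strsplit(truth$motifs[i], ";")[[1]]) {
      ch <- truth$chrom[i]
      occ <- occupied[[ch]] %||% integer()
      for (try in 1:50) {
        pos <- truth$tss[i] + sample((-200):(200 - w), 1)
        if (pos < 0 || pos + w > config$chrom_length) next
        if (!any(pos:(pos + w - 1) %in% occ)) break
      }
      occupied[[ch]] <- c(occ, pos:(pos + w - 1))
      substr(genome[[ch]], pos + 1, pos + w) <- consensus[m]
      plants[[length(plants) + 1]] <- tibble(
        feature_id = truth$feature_id[i], motif = m, chrom = ch, pos = pos
      )
    }
  }

  # GO table over coding genes: planted up/down terms plus background terms
  genes <- truth$feature_id[truth$class == "coding"]
  status <- truth$de_status[truth$class == "coding"]
  go <- list()
  add_term <- function(term, members) {
    if (length(members) > 0) tibble(gene_id = members, term_id = term)
  }
  go[[1]] <- add_term("GO:UP01", c(
    genes[status == "up"][runif(sum(status == "up")) < 0.8],
    genes[status != "up"][runif(sum(status != "up")) < 0.05]
  ))
  go[[2]] <- add_term("GO:DN01", c(
    genes[status == "down"][runif(sum(status == "down")) < 0.8],
    genes[status != "down"][runif(sum(status != "down")) < 0.05]
  ))
  for (t in 1:6) {
    go[[t + 2]] <- add_term(sprintf("GO:RND%02d", t), genes[runif(length(genes)) < 0.1])
  }
  go <- bind_rows(go)

  # miRNA-target network with planted hubs
  mirs <- unique(truth$locus_id[truth$class == "pri_miRNA_TV"])
  hub_degree <- min(40L, length(genes))
  hubs <- head(mirs, min(5L, length(mirs)))
  targets <- bind_rows(lapply(mirs, function(m) {
    deg <- if (m %in% hubs) hub_degree else min(3L, length(genes))
    tibble(mirna_id = m, gene_id = sample(genes, deg))
  }))

  tf2motif <- tibble(
    tf_id = paste0("TF_", config$motif_names),
    motif = config$motif_names
  )

  list(
    genome = genome, pwms = pwms, consensus = consensus,
    plants = bind_rows(plants), go = go, targets = targets,
    tf2motif = tf2motif,
    planted = list(go_up_term = "GO:UP01", go_down_term = "GO:DN01",
                   hub_mirnas = hubs, hub_degree = hub_degree)
  )
}

#' Generate a complete synthetic input bundle on disk
#'
#' Runs [generate_annotation()], [simulate_signal()], [generate_chromatin()]
#' and [generate_motifs_and_go()] and writes the full bundle: `genome.fa`,
#' `transcripts.bed` / `transcripts.tsv`, `signal/<sample>.<plus|minus>.bedGraph`,
#' `h3k4me3.bed`, `h3k4me1.bed`, `superenhancers.bed`, `motifs.pwm`,
#' `go.tsv`, `targets.tsv`, `tf2motif.tsv`, `truth.tsv` and `manifest.yaml`.
#' The bundle is a deterministic, byte-identical function of the config.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed). `NULL` keeps everything
#'   in memory and writes nothing.
#' @return Invisibly, a list with all in-memory pieces (`transcripts`,
#'   `truth`, `tracks`, `samples`, `chromatin`, `motifs_go`, `manifest`) and,
#'   when `dir` is given, `paths`.
#' @export
simulate_bundle <- function(config, dir = NULL) {
  ann <- generate_annotation(config)
  sig <- simulate_signal(ann, ann$truth, config)
  chrom <- generate_chromatin(ann, ann$truth, config)
  mg <- generate_motifs_and_go(ann, ann$truth, config)

  manifest <- list(
    seed = config$seed,
    samples = mutate(sig$samples,
      plus = file.path("signal", paste0(.data$sample, ".plus.bedGraph")),
      minus = file.path("signal", paste0(.data$sample, ".minus.bedGraph"))
    ),
    planted = mg$planted
  )

  out <- list(
    transcripts = ann$transcripts, truth = ann$truth,
    tracks = sig$tracks, samples = sig$samples,
    chromatin = chrom, motifs_go = mg, manifest = manifest
  )
  if (is.null(dir)) return(invisible(out))

  dir.create(file.path(dir, "signal"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(mg$genome, file.path(dir, "genome.fa"))
  bed12 <- ann$transcripts |>
    mutate(name = .data$transcript_id, score = 0,
           thick_start = .data$start, thick_end = .data$end,
           rgb = "0", n_blocks = 1,
           sizes = paste0(.data$end - .data$start, ","), starts = "0,")
  readr::write_tsv(
    select(bed12, "chrom", "start", "end", "name", "score", "strand",
           "thick_start", "thick_end", "rgb", "n_blocks", "sizes", "starts"),
    file.path(dir, "transcripts.bed"), col_names = FALSE, progress = FALSE
  )
  readr::write_tsv(ann$transcripts, file.path(dir, "transcripts.tsv"),
                   progress = FALSE)
  for (s in names(sig$tracks)) {
    write_signal_track(sig$tracks[[s]], file.path(dir, "signal", s))
  }
  write_bed(chrom$h3k4me3, file.path(dir, "h3k4me3.bed"), columns = 6)
  write_bed(chrom$h3k4me1, file.path(dir, "h3k4me1.bed"), columns = 6)
  write_bed(chrom$superenhancers, file.path(dir, "superenhancers.bed"),
            columns = 3)
  write_pwms(mg$pwms, file.path(dir, "motifs.pwm"))
  readr::write_tsv(mg$go, file.path(dir, "go.tsv"), progress = FALSE)
  readr::write_tsv(mg$targets, file.path(dir, "targets.tsv"), progress = FALSE)
  readr::write_tsv(mg$tf2motif, file.path(dir, "tf2motif.tsv"), progress = FALSE)
  readr::write_tsv(ann$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  write_manifest(manifest, file.path(dir, "manifest.yaml"))
  out$paths <- list(dir = dir)
  invisible(out)
}
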
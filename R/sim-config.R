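#' Configuration for the synthetic GRO-seq study generator
#'
#' Defines the simulated study: genome size, locus counts, sample groups and
#' replicate numbers, expression scale, planted effect sizes and the
#' structural fractions (bidirectional lncRNA pairs, enhancer-class lncRNAs,
#' super-enhancer overlap). Defaults emulate a two-condition nascent
#' transcription experiment (stem-cell-like vs hepatocyte-like) with four
#' replicates per group, negative-binomial biological noise at dispersion
#' 0.1, 8-fold planted differential transcription, and pri-miRNA loci with
#' 2-6 alternative TSSs sharing one 3' terminus.
#'
#' @param seed Integer RNG seed; the whole bundle is a deterministic function
#'   of the config, including the seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_coding,n_lncrna,n_primirna_loci Feature counts. Bidirectional
#'   partners are generated in addition to `n_lncrna`.
#' @param tss_per_locus_range Integer `c(min, max)` of alternative TSS counts
#'   per pri-miRNA locus; must stay within `[2, 6]`.
#' @param groups Named integer vector: group name -> replicate count (each
#'   at least 2). The first group is the reference for planted fold changes.
#' @param base_expression Baseline transcription level on the FPKM scale.
#' @param fold_change_planted Fold change planted into DE features (8 by
#'   default, i.e. |log2FC| = 3).
#' @param nb_dispersion Negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param frac_de Fraction of coding and lncRNA features planted as
#'   differentially transcribed (half up, half down in non-reference groups).
#' @param frac_switching Fraction of pri-miRNA loci whose dominant TSS flips
#'   between groups (4-fold dominance of the active TSS).
#' @param frac_bidirectional Fraction of lncRNAs given a divergent
#'   opposite-strand partner with TSS distance in 100-400 bp.
#' @param frac_enhancer Fraction of lncRNAs assigned the enhancer chromatin
#'   class (H3K4me1-marked TSS); the rest are promoter class (H3K4me3).
#' @param frac_se Fraction of enhancer-class lncRNAs placed inside a
#'   super-enhancer interval.
#' @param motif_names Character vector of TF motif names to plant at the TSSs
#'   of differentially transcribed lncRNAs; each motif also gets a planted TF
#'   gene (`TF_<name>`) whose expression follows the motif's direction.
#' @param library_size Sequencing depth per sample (equal across samples by
#'   default, decoupling normalization from DE testing); may be a vector of
#'   length `sum(groups)` for unequal depths.
#' @param peak_jitter Fractional jitter applied to chromatin peak boundaries
#'   (0 = peaks centred exactly on the TSS).
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_coding = 20, n_lncrna = 10, n_primirna_loci = 4)
#' cfg$groups
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 600000L,
                       n_coding = 60L,
                       n_lncrna = 40L,
                       n_primirna_loci = 12L,
                       tss_per_locus_range = c(2L, 4L),
                       groups = c(iPSC = 4L, PHH = 4L),
                       base_expression = 20,
                       fold_change_planted = 8,
                       nb_dispersion = 0.1,
                       frac_de = 0.25,
                       frac_switching = 0.3,
                       frac_bidirectional = 0.3,
                       frac_enhancer = 0.64,
                       frac_se = 0.3,
                       motif_names = c("SP1", "E2F2", "ETS1",
                                       "POU6F1", "RARG", "SIX1"),
                       library_size = 1e6,
                       peak_jitter = 0) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), n_coding = as.integer(n_coding),
    n_lncrna = as.integer(n_lncrna),
    n_primirna_loci = as.integer(n_primirna_loci),
    tss_per_locus_range = as.integer(tss_per_locus_range),
    groups = groups, base_expression = base_expression,
    fold_change_planted = fold_change_planted,
    nb_dispersion = nb_dispersion, frac_de = frac_de,
    frac_switching = frac_switching,
    frac_bidirectional = frac_bidirectional,
    frac_enhancer = frac_enhancer, frac_se = frac_se,
    motif_names = motif_names, library_size = library_size,
    peak_jitter = peak_jitter
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  r <- cfg$tss_per_locus_range
  if (length(r) != 2 || r[1] > r[2] || r[1] < 2 || r[2] > 6) {
    abort("tss_per_locus_range must be [min,max] within [2, 6]")
  }
  if (is.null(names(cfg$groups)) || any(names(cfg$groups) == "")) {
    abort("groups must be a named vector of replicate counts")
  }
  if (any(cfg$groups < 2)) abort("every group needs >= 2 replicates")
  fr <- c(cfg$frac_de, cfg$frac_switching, cfg$frac_bidirectional,
          cfg$frac_enhancer, cfg$frac_se)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (cfg$base_expression <= 0 || cfg$fold_change_planted <= 0) {
    abort("base_expression and fold_change_planted must be positive")
  }
  if (cfg$nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (cfg$n_coding < cfg$n_lncrna + length(cfg$motif_names)) {
    abort(sprintf(
      "n_coding (%d) must be >= n_lncrna + length(motif_names) (%d): each lncRNA needs a dedicated neighbour gene",
      cfg$n_coding, cfg$n_lncrna + length(cfg$motif_names)
    ))
  }
  n_samples <- sum(cfg$groups)
  if (!length(cfg$library_size) %in% c(1L, n_samples)) {
    abort("library_size must be scalar or one value per sample")
  }
  invisible(cfg)
}

# sample table implied by a config: sample id, group, library size
sim_samples <- function(config) {
  groups <- rep(names(config$groups), config$groups)
  samples <- tibble(
    sample = paste0(groups, "_r", unlist(lapply(config$groups, seq_len))),
    group = groups
  )
  samples$library_size <- rep(config$library_size, length.out = nrow(samples))
  samples
}
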
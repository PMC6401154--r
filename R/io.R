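#' Read a bedGraph file into a run-length coverage tibble
#'
#' bedGraph records are 0-based half-open `(chrom, start, end, value)` runs.
#' Records on the same chromosome must not overlap and values must be
#' non-negative; both are format errors here because coverage tracks are
#' run-length encodings of a non-negative per-base signal.
#'
#' @param path Path to a bedGraph file (plain text, no track lines).
#' @param strand Strand the file encodes: `"+"`, `"-"` or `"."`. GRO-seq
#'   tracks are conventionally deposited as one file per strand.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`, `strand`,
#'   sorted by chromosome and start, zero-value runs dropped and adjacent
#'   equal-value runs merged.
#' @export
#' @examples
#' f <- tempfile(fileext = ".bedGraph")
#' writeLines("chr1\t0\t10\t2", f)
#' read_bedgraph(f, "+")
read_bedgraph <- function(path, strand = "+") {
  stopifnot(strand %in% c("+", "-", "."))
  runs <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "value"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      value = readr::col_double()
    ),
    progress = FALSE
  )
  if (nrow(runs) == 0) {
    return(tibble(
      chrom = character(), start = double(), end = double(),
      value = double(), strand = character()
    ))
  }
  if (any(runs$start >= runs$end)) {
    bad <- which(runs$start >= runs$end)[1]
    abort(sprintf("bedGraph %s: start >= end at line %d", path, bad))
  }
  if (any(runs$value < 0)) {
    abort(sprintf("bedGraph %s: negative coverage value", path))
  }
  runs <- arrange(runs, .data$chrom, .data$start)
  overlapping <- runs |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start < dplyr::lag(.data$end, default = -Inf))) |>
    filter(.data$bad)
  if (nrow(overlapping) > 0) {
    abort(sprintf(
      "bedGraph %s: overlapping records on %s",
      path, paste(overlapping$chrom, collapse = ", ")
    ))
  }
  merge_runs(mutate(runs, strand = .env$strand))
}

# canonicalize a run tibble: sort, drop zero runs, merge touching equal runs
# (vectorized base R: run tables reach 1e5-1e6 rows on deep tracks)
merge_runs <- function(runs) {
  keep <- runs$value != 0
  chrom <- runs$chrom[keep]
  strand <- runs$strand[keep]
  start <- as.numeric(runs$start[keep])
  end <- as.numeric(runs$end[keep])
  value <- as.numeric(runs$value[keep])
  n <- length(start)
  if (n == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  value = double(), strand = character()))
  }
  o <- order(chrom, strand, start)
  chrom <- chrom[o]; strand <- strand[o]
  start <- start[o]; end <- end[o]; value <- value[o]
  same <- c(FALSE,
            chrom[-1] == chrom[-n] & strand[-1] == strand[-n] &
              start[-1] == end[-n] & value[-1] == value[-n])
  first <- which(!same)
  last <- c(first[-1] - 1L, n)
  tibble(chrom = chrom[first], start = start[first], end = end[last],
         value = value[first], strand = strand[first])
}

#' Write one strand of a coverage track as bedGraph
#'
#' @param runs Run tibble as returned by [read_bedgraph()] (a single strand).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(runs, path) {
  runs <- merge_runs(runs)
  readr::write_tsv(
    select(runs, "chrom", "start", "end", "value"),
    path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Build a stranded signal track from per-strand run tibbles
#'
#' A signal track is the in-memory form of a pair of strand-specific bedGraph
#' files: run-length coverage per (chromosome, strand) plus the library size,
#' defined as the total signal summed over both strands (the nascent-signal
#' analogue of total mapped reads).
#'
#' @param runs Run tibble with columns `chrom,start,end,value,strand`.
#' @param library_size Optional override; defaults to the summed coverage.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(runs, library_size = NULL) {
  runs <- merge_runs(runs)
  total <- sum(runs$value * (runs$end - runs$start))
  structure(
    list(runs = runs, library_size = library_size %||% total),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf(
    "<signal_track> %d runs on %d chromosome(s), library size %.0f\n",
    nrow(x$runs), length(unique(x$runs$chrom)), x$library_size
  ))
  invisible(x)
}

#' Read a plus/minus bedGraph pair as one stranded signal track
#'
#' @param plus_path,minus_path Paths to the two strand files.
#' @return A [signal_track()].
#' @export
read_signal_track <- function(plus_path, minus_path) {
  signal_track(bind_rows(
    read_bedgraph(plus_path, "+"),
    read_bedgraph(minus_path, "-")
  ))
}

#' Write a stranded signal track as a plus/minus bedGraph pair
#'
#' @param track A [signal_track()].
#' @param prefix Output path prefix; files are `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_signal_track <- function(track, prefix) {
  paths <- c(
    plus = paste0(prefix, ".plus.bedGraph"),
    minus = paste0(prefix, ".minus.bedGraph")
  )
  write_bedgraph(filter(track$runs, .data$strand == "+"), paths[["plus"]])
  write_bedgraph(filter(track$runs, .data$strand == "-"), paths[["minus"]])
  invisible(paths)
}

#' Read a BED file (BED3, BED6 or BED12)
#'
#' Coordinates are kept 0-based half-open throughout the package. The strand
#' defaults to `"."` when the file has fewer than six columns. BED12 block
#' definitions are validated against the record span.
#'
#' @param path Path to a tab-separated BED file.
#' @return Tibble with columns `chrom,start,end,name,score,strand` and, for
#'   BED12 input, `thick_start,thick_end,item_rgb,block_count,block_sizes,
#'   block_starts`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble(
      chrom = character(), start = double(), end = double(),
      name = character(), score = double(), strand = character()
    ))
  }
  nc <- ncol(raw)
  if (!nc %in% c(3, 4, 5, 6, 12)) {
    abort(sprintf("BED %s: unsupported column count %d", path, nc))
  }
  bed <- tibble(
    chrom = raw[[1]],
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]]),
    name = if (nc >= 4) raw[[4]] else sprintf("rec%d", seq_len(nrow(raw))),
    score = if (nc >= 5) suppressWarnings(as.numeric(raw[[5]])) else 0,
    strand = if (nc >= 6) raw[[6]] else "."
  )
  if (any(bed$start >= bed$end)) {
    bad <- which(bed$start >= bed$end)[1]
    abort(sprintf("BED %s: start >= end at line %d", path, bad))
  }
  if (nc == 12) {
    bed$thick_start <- as.numeric(raw[[7]])
    bed$thick_end <- as.numeric(raw[[8]])
    bed$item_rgb <- raw[[9]]
    bed$block_count <- as.integer(raw[[10]])
    bed$block_sizes <- raw[[11]]
    bed$block_starts <- raw[[12]]
    for (i in seq_len(nrow(bed))) {
      sizes <- as.numeric(strsplit(bed$block_sizes[i], ",")[[1]])
      starts <- as.numeric(strsplit(bed$block_starts[i], ",")[[1]])
      if (length(sizes) != bed$block_count[i] ||
          length(starts) != bed$block_count[i] ||
          any(bed$start[i] + starts + sizes > bed$end[i])) {
        abort(sprintf("BED %s: blocks exceed [start,end) at line %d", path, i))
      }
    }
  }
  bed
}

#' Write intervals as BED6 (or BED3)
#'
#' @param intervals Tibble with at least `chrom,start,end`; `name`, `score`
#'   and `strand` are filled with defaults when absent.
#' @param path Output path.
#' @param columns 3 or 6.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, columns = 6) {
  stopifnot(columns %in% c(3, 6))
  df <- tibble(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end
  )
  if (columns == 6) {
    df$name <- col_or(intervals, "name", sprintf("rec%d", seq_len(nrow(df))))
    df$score <- col_or(intervals, "score", 0)
    df$strand <- col_or(intervals, "strand", ".")
  }
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a genome FASTA, uppercasing soft-masked sequence
#'
#' @param path FASTA path.
#' @return A named character vector of chromosome sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path, width = 70
  )
  invisible(path)
}

#' Read a transcript annotation table
#'
#' Tab-separated with header; requires columns `transcript_id, locus_id,
#' class, chrom, start, end, strand` (0-based half-open).
#'
#' @param path TSV path.
#' @return Tibble of transcripts with a computed `tss` column.
#' @export
read_transcript_table <- function(path) {
  tx <- readr::read_tsv(path, col_types = readr::cols(), comment = "#",
                        progress = FALSE)
  req <- c("transcript_id", "locus_id", "class", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(req, names(tx))
  if (length(missing_cols) > 0) {
    abort(paste("transcript table missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  if (any(tx$start >= tx$end)) abort("transcript table: start >= end")
  mutate(tx, tss = ifelse(.data$strand == "-", .data$end - 1, .data$start))
}

#' Export transcripts as GTF (1-based closed coordinates)
#'
#' @param transcripts Transcript tibble (0-based half-open internally).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- sprintf(
    "%s\tnascentscape\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    transcripts$chrom, as.integer(transcripts$start + 1),
    as.integer(transcripts$end), transcripts$strand,
    transcripts$locus_id, transcripts$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a position-weight-matrix file
#'
#' One block per motif: a `>name` line, then four whitespace-separated rows of
#' per-position probabilities in A, C, G, T order. Columns must each sum to 1
#' (tolerance 1e-6) and the width must be at least 4.
#'
#' @param path PWM file path.
#' @return Named list of 4 x width probability matrices (rows A,C,G,T).
#' @export
read_pwms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort(sprintf("PWM %s: no '>' name lines", path))
  pwms <- list()
  for (i in seq_along(starts)) {
    name <- sub("^>\\s*", "", lines[starts[i]])
    block_end <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    rows <- lines[(starts[i] + 1):block_end]
    if (length(rows) != 4) {
      abort(sprintf("PWM %s: motif %s needs exactly 4 rows", path, name))
    }
    mat <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(r, "\\s+")[[1]])
    }))
    rownames(mat) <- c("A", "C", "G", "T")
    validate_pwm(mat, name)
    pwms[[name]] <- mat
  }
  pwms
}

validate_pwm <- function(mat, name = "pwm") {
  if (ncol(mat) < 4) abort(sprintf("PWM %s: width %d < 4", name, ncol(mat)))
  sums <- colSums(mat)
  if (any(abs(sums - 1) > 1e-6)) {
    abort(sprintf("PWM %s: columns must sum to 1", name))
  }
  invisible(mat)
}

#' Write a list of PWMs in the package's plain-text format
#' @param pwms Named list of 4 x width probability matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (name in names(pwms)) {
    writeLines(paste0(">", name), con)
    apply(pwms[[name]], 1, function(row) {
      writeLines(paste(format(row, trim = TRUE, digits = 10), collapse = "\t"), con)
    })
  }
  invisible(path)
}

#' Read a two-column mapping table (TSV with header)
#' @param path TSV path.
#' @param cols Expected column names, used to validate the header.
#' @return Tibble.
#' @export
read_mapping_table <- function(path, cols = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  if (!is.null(cols)) {
    missing_cols <- setdiff(cols, names(tab))
    if (length(missing_cols) > 0) {
      abort(paste0(path, " missing columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
  }
  tab
}

#' Read / write the sample manifest
#'
#' The manifest records, per sample: group, the two bedGraph paths and the
#' library size, plus any generator ground-truth bookkeeping.
#'
#' @param path YAML path.
#' @return For `read_manifest`, the manifest list with a `samples` tibble.
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  man$samples <- bind_rows(lapply(man$samples, as_tibble))
  man
}

#' @rdname read_manifest
#' @param manifest Manifest list; `samples` may be a tibble.
#' @return For `write_manifest`, `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  if (is.data.frame(manifest$samples)) {
    manifest$samples <- lapply(
      seq_len(nrow(manifest$samples)),
      function(i) as.list(manifest$samples[i, ])
    )
  }
  yaml::write_yaml(manifest, path)
  invisible(path)
}
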
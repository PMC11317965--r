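#' @include doublebox-package.R
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

check_dna <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGTN]", seq)[1]
  if (bad > 0) {
    stop(sprintf("illegal character '%s' in %s at position %d",
                 substr(seq, bad, bad), what, bad), call. = FALSE)
  }
  invisible(seq)
}

#' Construct a genome object
#'
#' A genome is a single named nucleotide sequence over \{A,C,G,T,N\} with a
#' circularity flag. Coordinates are 1-based inclusive throughout the
#' package; conversion to 0-based half-open happens only at the BED and
#' bedGraph boundaries.
#'
#' @param name Text identifier (first whitespace-delimited token of a FASTA
#'   header when read from file).
#' @param sequence Nucleotide string; lower case is accepted and stored
#'   upper case.
#' @param circular Logical; when `TRUE`, [extract_window()] may wrap around
#'   the origin. Scanning always treats the sequence as linear.
#' @return An object of class `"genome"` with fields `name`, `sequence`,
#'   `length` and `circular`.
#' @export
genome <- function(name, sequence, circular = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L,
            is.logical(circular), length(circular) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty genome sequence", call. = FALSE)
  check_dna(sequence, sprintf("genome '%s'", name))
  structure(list(name = name, sequence = sequence,
                 length = nchar(sequence), circular = circular),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp (%s)\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a single-record genome FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record
#'   (multi-record files are rejected: the pipeline works on a single
#'   replicon).
#' @param circular Circularity flag to attach to the genome.
#' @return A [genome()] object. The name is the first whitespace-delimited
#'   token of the header; the sequence is stored upper case.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (length(set) > 1L) {
    stop(sprintf("multiple records (%d) in %s; genome input must be a single record",
                 length(set), path), call. = FALSE)
  }
  seq <- as.character(set[[1L]])
  if (nchar(seq) == 0L) stop("empty record in ", path, call. = FALSE)
  name <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
  genome(name, seq, circular = circular)
}

#' Write a genome to FASTA
#'
#' @param g A [genome()] object.
#' @param path Output path.
#' @param line_width Bases per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, line_width = 70L) {
  stopifnot(inherits(g, "genome"))
  set <- Biostrings::DNAStringSet(g$sequence)
  names(set) <- g$name
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Standard complement, reversed; `N` maps to `N`. Required for
#' both-strand scanning and counting.
#'
#' @param seq String over \{A,C,G,T,N\} (case-insensitive; result is upper
#'   case).
#' @return The reverse complement string.
#' @examples
#' reverse_complement("TTATCCACA")  # "TGTGGATAA"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  seq <- toupper(seq)
  check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a fixed-width window centred on a coordinate
#'
#' Used for the windows the pipeline takes around region centres (101 bp
#' for motif discovery, 201 bp for coverage scoring). On a linear genome a
#' window extending past either end is an error; on a circular genome the
#' window wraps.
#'
#' @param g A [genome()] object.
#' @param centre 1-based centre coordinate.
#' @param width Odd positive window width (bp).
#' @param wrap Allow wrap-around when the genome is circular. Wrapping
#'   never happens on a linear genome.
#' @return A string of exactly `width` bases with the `centre` base at the
#'   middle position.
#' @export
extract_window <- function(g, centre, width, wrap = g$circular) {
  stopifnot(inherits(g, "genome"))
  if (width < 1L || width %% 2L == 0L) stop("width must be odd and positive", call. = FALSE)
  if (centre < 1L || centre > g$length) stop("centre outside genome", call. = FALSE)
  half <- (width - 1L) %/% 2L
  from <- centre - half
  to <- centre + half
  if (from >= 1L && to <= g$length) {
    return(substr(g$sequence, from, to))
  }
  if (!(g$circular && wrap)) {
    stop(sprintf("window [%d,%d] out of range on linear genome of length %d",
                 from, to, g$length), call. = FALSE)
  }
  pos <- ((seq.int(from, to) - 1L) %% g$length) + 1L
  paste(strsplit(g$sequence, "")[[1L]][pos], collapse = "")
}

#' Construct a per-base coverage track
#'
#' @param genome_name Name of the genome the track belongs to.
#' @param values One non-negative value per genome position (normalized
#'   depth, arbitrary units).
#' @param normalization_factor The factor the raw depths were multiplied
#'   by; see [normalize_track()].
#' @return An object of class `"coverage_track"`.
#' @export
coverage_track <- function(genome_name, values, normalization_factor = 1) {
  stopifnot(is.numeric(values))
  if (any(is.na(values))) stop("NA coverage values", call. = FALSE)
  if (any(values < 0)) stop("negative coverage values", call. = FALSE)
  if (normalization_factor <= 0) stop("normalization_factor must be positive", call. = FALSE)
  structure(list(genome_name = genome_name, values = as.numeric(values),
                 normalization_factor = normalization_factor),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d positions, mean %.3f (norm factor %.4g)\n",
              x$genome_name, length(x$values), mean(x$values),
              x$normalization_factor))
  invisible(x)
}

#' Rescale a coverage track to a fixed library size
#'
#' Rescales so the track mean equals `target_mean` (equivalently, the sum
#' equals `target_mean * length`), making replicate averaging and
#' signal/control ratios comparable across tracks of different depth.
#'
#' @param track A [coverage_track()].
#' @param target_mean Post-normalization mean depth (default 1).
#' @return A normalized `coverage_track`.
#' @export
normalize_track <- function(track, target_mean = 1) {
  stopifnot(inherits(track, "coverage_track"))
  s <- mean(track$values)
  if (s == 0) return(track)
  f <- target_mean / s
  coverage_track(track$genome_name, track$values * f,
                 normalization_factor = track$normalization_factor * f)
}

#' Read a bedGraph file into a per-base coverage track
#'
#' bedGraph intervals are 0-based half-open and must not overlap;
#' positions absent from the file get coverage 0. Internally everything is
#' 1-based inclusive.
#'
#' @param path bedGraph file path.
#' @param g The [genome()] the track is defined on (supplies the length).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, g) {
  stopifnot(inherits(g, "genome"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- numeric(g$length)
  if (length(gr) > 0L) {
    starts <- GenomicRanges::start(gr)   # already 1-based inclusive
    ends <- GenomicRanges::end(gr)
    score <- S4Vectors::mcols(gr)$score
    if (any(score < 0)) stop("negative coverage values in ", path, call. = FALSE)
    if (any(ends > g$length)) {
      stop(sprintf("bedGraph interval beyond genome length %d in %s",
                   g$length, path), call. = FALSE)
    }
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]; score <- score[ord]
    if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)])) {
      stop("overlapping intervals in ", path, call. = FALSE)
    }
    widths <- ends - starts + 1L
    vals[sequence(widths, from = starts)] <- rep(score, widths)
  }
  coverage_track(g$name, vals)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent positions with equal value are collapsed into one interval;
#' zero-coverage runs are omitted, matching the sparse bedGraph convention.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    seqnames = track$genome_name,
    ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
    score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Convert an interval table to GRanges and write BED6
#'
#' @param intervals Data frame with 1-based inclusive `start`, `end`, and
#'   optional `name`, `score`, `strand` columns.
#' @param path Output BED path (written 0-based half-open per the BED
#'   standard).
#' @param genome_name Sequence name for the BED records.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, genome_name = "genome") {
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in% names(intervals)))
  n <- nrow(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = genome_name,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end),
    strand = if ("strand" %in% names(intervals)) {
      ifelse(intervals$strand %in% c("+", "-"), intervals$strand, "*")
    } else rep("*", n))
  S4Vectors::mcols(gr)$name <- if ("name" %in% names(intervals)) {
    as.character(intervals$name)
  } else sprintf("interval_%d", seq_len(max(n, 0L)))
  S4Vectors::mcols(gr)$score <- if ("score" %in% names(intervals)) {
    intervals$score
  } else rep(0, n)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file into a 1-based inclusive interval table
#'
#' @param path BED file path.
#' @return Data frame with `start`, `end` (1-based inclusive), `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  mc <- S4Vectors::mcols(gr)
  data.frame(
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if ("name" %in% names(mc)) as.character(mc$name) else NA_character_,
    score = if ("score" %in% names(mc)) as.numeric(mc$score) else NA_real_,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Write a table as TSV with a commented header line
#'
#' All pipeline stage outputs use this layout: a single `#`-prefixed
#' header naming the columns, then tab-delimited rows.
#'
#' @param table A data frame (list columns are collapsed with commas).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  stopifnot(is.data.frame(table))
  tab <- table
  for (j in seq_along(tab)) {
    if (is.list(tab[[j]])) {
      tab[[j]] <- vapply(tab[[j]], function(x) paste(x, collapse = ","), "")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(tab), collapse = "\t")), con)
  write.table(tab, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return A data frame with the commented header restored as column names.
#' @export
read_tsv <- function(path) {
  header <- sub("^#\\s*", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t")[[1L]]
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  names(tab) <- cols
  tab
}
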
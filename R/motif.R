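#' @include genome.R
NULL

#' The DnaA box consensus sequence
#'
#' The 9 bp high-affinity DnaA binding site consensus, TTATCCACA.
#' @export
DNAA_BOX_CONSENSUS <- "TTATCCACA"

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param probs Numeric matrix, width x 4, columns named A,C,G,T; each row
#'   sums to 1.
#' @param background Length-4 base probabilities of the background model.
#' @param core_offset 0-based index of the 9-mer core start within the
#'   motif (the 9 most informative contiguous columns).
#' @param core_spacing For double-box PWMs, the number of columns between
#'   the two 9-mer cores; `NULL` for single-box PWMs.
#' @param id Motif identifier used in hit tables.
#' @return An object of class `"pwm"` with fields `width`, `probs`,
#'   `background`, `core_offset`, `core_spacing`, `id`.
#' @export
pwm <- function(probs, background = rep(0.25, 4), core_offset = 0L,
                core_spacing = NULL, id = "motif") {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("probs must have 4 columns (A,C,G,T)", call. = FALSE)
  colnames(probs) <- BASES
  background <- setNames(as.numeric(background), BASES)
  if (any(probs < 0) || any(background < 0)) {
    stop("negative probabilities", call. = FALSE)
  }
  if (max(abs(rowSums(probs) - 1)) > 1e-9) {
    stop("PWM rows must each sum to 1", call. = FALSE)
  }
  if (abs(sum(background) - 1) > 1e-9) {
    stop("background must sum to 1", call. = FALSE)
  }
  structure(list(width = nrow(probs), probs = probs, background = background,
                 core_offset = as.integer(core_offset),
                 core_spacing = if (is.null(core_spacing)) NULL else as.integer(core_spacing),
                 id = id),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: width %d, IC %.2f bits, consensus %s%s\n",
              x$id, x$width, information_content(x), consensus_string(x),
              if (!is.null(x$core_spacing))
                sprintf(" (double box, core spacing %d bp)", x$core_spacing)
              else ""))
  invisible(x)
}

#' Consensus string of a PWM
#'
#' The most probable base per column (ties broken alphabetically).
#'
#' @param x A [pwm()].
#' @return A string of length `x$width`.
#' @export
consensus_string <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(BASES[max.col(x$probs, ties.method = "first")], collapse = "")
}

#' Information content of a PWM (bits)
#'
#' Sum over columns of the Kullback-Leibler divergence from the background:
#' `sum_i sum_b p[i,b] log2(p[i,b] / bg[b])`.
#'
#' @param x A [pwm()].
#' @return Total information content in bits.
#' @export
information_content <- function(x) {
  stopifnot(inherits(x, "pwm"))
  p <- x$probs
  bg <- matrix(x$background, nrow = nrow(p), ncol = 4L, byrow = TRUE)
  terms <- p * log2(p / bg)
  terms[p == 0] <- 0
  sum(terms)
}

#' Reverse complement of a PWM
#'
#' @param x A [pwm()].
#' @return The PWM scoring the opposite strand.
#' @export
reverse_complement_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  p <- x$probs[rev(seq_len(x$width)), rev(seq_len(4L)), drop = FALSE]
  colnames(p) <- BASES
  core_off <- x$width - (x$core_offset + 9L)
  pwm(p, background = x$background,
      core_offset = max(core_off, 0L),
      core_spacing = x$core_spacing, id = paste0(x$id, "_rc"))
}

#' Count matches to the DnaA box consensus
#'
#' Positionwise identity between a candidate 9-mer and the consensus; the
#' statistic behind "x/9 matches" descriptions of individual boxes.
#'
#' @param site Candidate site, same length as `consensus`.
#' @param consensus Reference sequence (default the DnaA box consensus
#'   TTATCCACA).
#' @return Integer number of matching positions.
#' @examples
#' count_consensus_matches("TTACGCACA")  # 7
#' @export
count_consensus_matches <- function(site, consensus = DNAA_BOX_CONSENSUS) {
  stopifnot(is.character(site), length(site) == 1L)
  site <- toupper(site)
  consensus <- toupper(consensus)
  if (nchar(site) != nchar(consensus)) {
    stop(sprintf("length mismatch: site has %d bases, consensus %d",
                 nchar(site), nchar(consensus)), call. = FALSE)
  }
  sum(strsplit(site, "")[[1L]] == strsplit(consensus, "")[[1L]])
}

#' Parse a mixed-case double-box annotation string
#'
#' Bound-region tables annotate each locus with a string in which the two
#' 9 bp boxes are upper case and the spacer and flanks are lower case,
#' e.g. `"tTTACGCACAgagTTATCCACAa"`. This extracts the two boxes and their
#' core spacing.
#'
#' @param string Annotation string with exactly two upper-case 9-base runs.
#' @return List with `upstream`, `downstream` (9-mers), `spacing` (bp
#'   between the cores) and `spacer` (the lower-case spacer string).
#' @export
parse_double_box <- function(string) {
  stopifnot(is.character(string), length(string) == 1L)
  m <- gregexpr("[ACGTN]+", string)[[1L]]
  if (m[1L] == -1L || length(m) != 2L) {
    stop("expected exactly two upper-case box runs in '", string, "'", call. = FALSE)
  }
  len <- attr(m, "match.length")
  if (any(len != 9L)) {
    stop("upper-case runs must be 9 bases long in '", string, "'", call. = FALSE)
  }
  up_end <- m[1L] + 8L
  spacing <- m[2L] - up_end - 1L
  list(upstream = substr(string, m[1L], up_end),
       downstream = substr(string, m[2L], m[2L] + 8L),
       spacing = as.integer(spacing),
       spacer = substr(string, up_end + 1L, m[2L] - 1L))
}

#' Build a PWM from an alignment of equal-length sites
#'
#' Column probabilities are `(count(b) + pseudocount * background[b]) /
#' (n_sites + pseudocount)`, the MEME-style convention of distributing one
#' pseudocount by the background composition.
#'
#' @param sites Character vector of aligned, equal-length sequences over
#'   \{A,C,G,T\}.
#' @param pseudocount Total pseudocount distributed by background
#'   (default 0.1).
#' @param background Length-4 background probabilities.
#' @param weights Optional per-site weights (EM responsibilities); default
#'   1 per site.
#' @param id Motif identifier.
#' @return A [pwm()]; `core_offset` marks the 9 highest-information
#'   contiguous columns (or column 0 for motifs narrower than 9).
#' @export
build_pwm <- function(sites, pseudocount = 0.1, background = rep(0.25, 4),
                      weights = NULL, id = "motif") {
  if (length(sites) < 2L && is.null(weights)) {
    stop("need at least 2 sites to build a PWM", call. = FALSE)
  }
  if (length(sites) == 0L) stop("empty alignment", call. = FALSE)
  sites <- toupper(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("ragged alignment: sites differ in length", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(sites))
  stopifnot(length(weights) == length(sites))
  background <- setNames(as.numeric(background), BASES)
  mat <- matrix(unlist(strsplit(sites, "")), nrow = length(sites), byrow = TRUE)
  counts <- vapply(BASES, function(b) {
    colSums((mat == b) * weights)
  }, numeric(w))
  counts <- matrix(counts, nrow = w, ncol = 4L, dimnames = list(NULL, BASES))
  n <- sum(weights)
  probs <- (counts + pseudocount * matrix(background, w, 4L, byrow = TRUE)) /
    (n + pseudocount)
  probs <- probs / rowSums(probs)  # guard rounding
  p <- pwm(probs, background = background, id = id)
  p$core_offset <- find_core_offset(p)
  p
}

find_core_offset <- function(p, core_width = 9L) {
  if (p$width <= core_width) return(0L)
  bg <- matrix(p$background, nrow = p$width, ncol = 4L, byrow = TRUE)
  terms <- p$probs * log2(p$probs / bg)
  terms[p$probs == 0] <- 0
  ic_col <- rowSums(terms)
  win <- vapply(seq_len(p$width - core_width + 1L), function(i) {
    sum(ic_col[i:(i + core_width - 1L)])
  }, numeric(1))
  which.max(win) - 1L
}

#' Compose a double-box PWM from a single-box PWM
#'
#' A single-box PWM of width `W = 2f + 9` (f flanking columns each side of
#' the 9-mer core) is concatenated with itself. Plain tandem concatenation
#' puts the two cores `2f` columns apart; inserting one
#' background-distributed column between the copies gives `2f + 1`. For
#' the canonical width-11 motif (one flank each side) these are the 2 bp
#' and 3 bp core spacings of the double DnaA box.
#'
#' @param single A single-box [pwm()] of odd width >= 9 with symmetric
#'   flanks.
#' @param spacing Desired spacing between the 9-mer cores; must equal `2f`
#'   (tandem) or `2f + 1` (tandem plus background column).
#' @return A double-box [pwm()] with `core_spacing` recorded.
#' @export
make_double_pwm <- function(single, spacing) {
  stopifnot(inherits(single, "pwm"))
  if ((single$width - 9L) %% 2L != 0L) {
    stop("single PWM must have symmetric flanks around a 9-column core", call. = FALSE)
  }
  f <- (single$width - 9L) %/% 2L
  spacing <- as.integer(spacing)
  if (spacing == 2L * f) {
    probs <- rbind(single$probs, single$probs)
  } else if (spacing == 2L * f + 1L) {
    probs <- rbind(single$probs, matrix(single$background, 1L, 4L), single$probs)
  } else {
    stop(sprintf("spacing %d unsupported for flank size %d (use %d or %d)",
                 spacing, f, 2L * f, 2L * f + 1L), call. = FALSE)
  }
  pwm(probs, background = single$background, core_offset = f,
      core_spacing = spacing,
      id = sprintf("%s_double_s%d", single$id, spacing))
}

#' Discover an enriched motif in a set of sequence windows
#'
#' A seeded expectation-maximization finder standing in for a full motif
#' discovery program: every window position on both strands is a candidate
#' site in a two-component (motif vs background) mixture with no limit on
#' occurrences per window. Seeds are the most over-represented
#' `width`-mers (both strands counted); each seed is refined by EM until
#' the information content changes by less than `tol` or `max_iter`
#' iterations, and the converged motif with the highest information
#' content wins. Ties at any stage are broken toward the
#' lexicographically smallest seed, so the result is deterministic.
#'
#' @param windows Character vector (>= 4) of sequences, typically the
#'   101 bp windows centred on bound regions.
#' @param width Motif width (default 11 = 1 + 9-mer core + 1).
#' @param background Length-4 background probabilities; default estimated
#'   from the windows (both strands).
#' @param n_seeds Number of seed words to refine.
#' @param pseudocount Pseudocount for the PWM updates.
#' @param tol Convergence threshold on the change in information content.
#' @param max_iter Maximum EM iterations per seed.
#' @return List with `pwm` (the winning motif), `sites` (data frame of
#'   aligned occurrences with responsibility > 0.5: window, offset,
#'   strand, sequence, responsibility) and `ic` (its information content).
#' @export
discover_motif <- function(windows, width = 11L, background = NULL,
                           n_seeds = 5L, pseudocount = 0.1,
                           tol = 1e-6, max_iter = 200L) {
  if (length(windows) < 4L) stop("need at least 4 windows", call. = FALSE)
  windows <- toupper(windows)
  if (any(nchar(windows) < width)) {
    stop("motif width exceeds window length", call. = FALSE)
  }
  kmers <- unlist(lapply(windows, function(w) {
    n <- nchar(w) - width + 1L
    if (n < 1L) return(character())
    substring(w, seq_len(n), seq_len(n) + width - 1L)
  }))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) == 0L) stop("no informative motif: windows contain no scorable k-mers", call. = FALSE)
  if (length(unique(unlist(strsplit(unique(kmers), "")))) < 2L) {
    stop("no informative motif: single-base input", call. = FALSE)
  }
  both <- c(kmers,
            as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers))))
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(both, "")), levels = BASES))
    background <- as.numeric(tab) / sum(tab)
    background[background == 0] <- 1e-6
    background <- background / sum(background)
  }
  background <- setNames(as.numeric(background), BASES)

  # Seed words are the most over-represented core-width words (9, the box
  # width, when the motif is at least that wide), counted on both strands;
  # the seed PWM embeds the core centrally with background flanks. Counting
  # at core width concentrates the signal that full-width counting spreads
  # over flank variants.
  seed_w <- if (width >= 9L) 9L else width
  core_words <- unlist(lapply(windows, function(w) {
    n <- nchar(w) - seed_w + 1L
    substring(w, seq_len(n), seq_len(n) + seed_w - 1L)
  }))
  core_words <- core_words[!grepl("N", core_words, fixed = TRUE)]
  core_words <- c(core_words,
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAStringSet(core_words))))
  counts <- table(core_words)
  ord <- order(-as.numeric(counts), names(counts))  # count desc, lexicographic
  seeds <- names(counts)[ord][seq_len(min(n_seeds, length(counts)))]

  enc <- lapply(both, encode_bases)
  fits <- lapply(seeds, function(seed) {
    em_fit_motif(seed, enc, both, width, background, pseudocount, tol, max_iter)
  })
  ics <- vapply(fits, function(f) f$ic, numeric(1))
  best <- which(ics == max(ics))[1L]  # seeds already in lexicographic tie order
  fit <- fits[[best]]

  keep <- fit$z > 0.5
  n_fwd <- length(kmers)
  sites <- data.frame(
    sequence = both[keep],
    strand = ifelse(which(keep) <= n_fwd, "+", "-"),
    responsibility = fit$z[keep],
    stringsAsFactors = FALSE)
  list(pwm = fit$pwm, sites = sites, ic = fit$ic, seed = seeds[best])
}

encode_bases <- function(s) {
  match(strsplit(s, "")[[1L]], BASES)
}

em_fit_motif <- function(seed, enc, kmers, width, background, pseudocount,
                         tol, max_iter) {
  # init PWM from the (possibly narrower) seed word embedded centrally:
  # 0.7 on the seed base, the rest split evenly; flank columns background
  seed_enc <- encode_bases(seed)
  probs <- matrix(background, width, 4L, byrow = TRUE,
                  dimnames = list(NULL, BASES))
  off <- (width - length(seed_enc)) %/% 2L
  at <- off + seq_along(seed_enc)
  probs[at, ] <- 0.1
  probs[cbind(at, seed_enc)] <- 0.7
  probs <- probs / rowSums(probs)
  p <- pwm(probs, background = background, id = "em")
  gamma <- 0.05
  enc_mat <- do.call(rbind, enc)
  n <- nrow(enc_mat)
  log_bg <- rowSums(matrix(log(background)[enc_mat], nrow = n))
  bg_row <- matrix(background, width, 4L, byrow = TRUE)
  ic_old <- -Inf
  z <- numeric(n)
  for (iter in seq_len(max_iter)) {
    lp <- log(p$probs)
    log_motif <- rowSums(matrix(lp[cbind(rep(seq_len(width), each = n),
                                         as.vector(enc_mat))],
                                nrow = n))
    a <- log(gamma) + log_motif
    b <- log1p(-gamma) + log_bg
    z <- 1 / (1 + exp(b - a))
    gamma <- min(max(mean(z), 1e-6), 0.5)
    counts <- vapply(1:4, function(bb) colSums((enc_mat == bb) * z), numeric(width))
    counts <- matrix(counts, nrow = width)
    probs2 <- (counts + pseudocount * bg_row) / (sum(z) + pseudocount)
    probs2 <- probs2 / rowSums(probs2)
    p <- pwm(probs2, background = background, id = "em")
    ic <- information_content(p)
    if (abs(ic - ic_old) < tol) break
    ic_old <- ic
  }
  p$core_offset <- find_core_offset(p)
  list(pwm = p, z = z, ic = information_content(p), gamma = gamma)
}

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms A [pwm()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1L]]$background
  writeLines(c("MEME version 5", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", BASES, bg), collapse = " "), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$width), con)
    writeLines(apply(p$probs, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from MEME minimal motif format
#'
#' @param path Input path.
#' @return A list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    bg <- as.numeric(toks[seq(2L, 8L, by = 2L)])
  }
  motif_at <- grep("^MOTIF ", lines)
  lapply(motif_at, function(i) {
    id <- strsplit(lines[i], "\\s+")[[1L]][2L]
    hdr <- grep("^letter-probability matrix", lines[i:length(lines)])[1L] + i - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    probs <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    }))
    probs <- probs / rowSums(probs)
    p <- pwm(probs, background = bg / sum(bg), id = id)
    p$core_offset <- find_core_offset(p)
    p
  })
}
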
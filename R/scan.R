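#' @include motif.R
NULL

#' Log-odds score of a k-mer against a PWM
#'
#' `sum_i log2(probs[i, base_i] / background[base_i])`, the standard
#' motif-scanner scoring rule.
#'
#' @param p A [pwm()].
#' @param kmer String of length `p$width` over \{A,C,G,T\} (windows
#'   containing N are never scored; passing one is an error).
#' @param background Optional override of the PWM's background.
#' @return Score in bits (can be `-Inf` for zero-probability columns).
#' @export
log_odds <- function(p, kmer, background = p$background) {
  stopifnot(inherits(p, "pwm"))
  kmer <- toupper(kmer)
  if (nchar(kmer) != p$width) {
    stop(sprintf("k-mer length %d does not match PWM width %d",
                 nchar(kmer), p$width), call. = FALSE)
  }
  if (grepl("N", kmer, fixed = TRUE)) stop("k-mer contains N", call. = FALSE)
  e <- encode_bases(kmer)
  if (any(is.na(e))) stop("illegal character in k-mer", call. = FALSE)
  sum(log2(p$probs[cbind(seq_len(p$width), e)] / background[e]))
}

# Integer per-column score matrix at the given granularity (bits/bin).
int_score_matrix <- function(p, background, granularity) {
  lo <- log2(p$probs / matrix(background, p$width, 4L, byrow = TRUE))
  m <- round(lo / granularity)
  if (any(!is.finite(m))) {
    stop("PWM has zero probabilities; apply a pseudocount before scanning",
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' Exact score distribution of a PWM under the background model
#'
#' The null distribution of the log-odds score of a random `width`-mer
#' drawn from the 0-order background, computed exactly by positionwise
#' convolution of the discretized per-column score contributions
#' (the dynamic program behind FIMO-style p-values). The tail table gives
#' `p(s) = P(score >= s)`.
#'
#' @param p A [pwm()] with strictly positive probabilities.
#' @param granularity Score discretization in bits per bin (default
#'   0.001).
#' @param background Background distribution the random k-mer is drawn
#'   from (default the PWM's own background).
#' @return An object of class `"score_distribution"`: `granularity`,
#'   `min_int`/`max_int` (integer score range), `probs` (bin
#'   probabilities) and `tail` (upper-tail probabilities, non-increasing).
#' @export
score_distribution <- function(p, granularity = 0.001, background = p$background) {
  stopifnot(inherits(p, "pwm"), granularity > 0)
  background <- setNames(as.numeric(background), BASES)
  m <- int_score_matrix(p, background, granularity)
  col_min <- apply(m, 1L, min)
  col_max <- apply(m, 1L, max)
  lo <- sum(col_min)
  hi <- sum(col_max)
  probs <- numeric(hi - lo + 1L)
  probs[1L] <- 1
  cur_lo <- 0L
  cur_len <- 1L
  for (i in seq_len(p$width)) {
    new_lo <- cur_lo + col_min[i]
    new_len <- cur_len + (col_max[i] - col_min[i])
    acc <- numeric(new_len)
    old <- probs[seq_len(cur_len)]
    for (b in 1:4) {
      off <- m[i, b] - col_min[i]
      idx <- seq_len(cur_len) + off
      acc[idx] <- acc[idx] + old * background[b]
    }
    probs[seq_len(new_len)] <- acc
    cur_lo <- new_lo
    cur_len <- new_len
  }
  probs <- probs[seq_len(cur_len)]
  tail_p <- rev(cumsum(rev(probs)))
  tail_p <- pmin(tail_p, 1)
  structure(list(granularity = granularity, min_int = lo, max_int = hi,
                 probs = probs, tail = tail_p),
            class = "score_distribution")
}

#' Upper-tail p-value of a discretized score
#'
#' @param dist A [score_distribution()].
#' @param int_score Integer score(s) in `dist`'s discretization (score in
#'   bits / granularity, rounded per column before summation).
#' @return `P(score >= int_score)`; 1 below the attainable minimum, 0
#'   above the attainable maximum.
#' @export
score_pvalue <- function(dist, int_score) {
  stopifnot(inherits(dist, "score_distribution"))
  idx <- int_score - dist$min_int + 1L
  out <- numeric(length(int_score))
  out[idx <= 0L] <- 1
  inside <- idx >= 1L & idx <= length(dist$tail)
  out[inside] <- dist$tail[idx[inside]]
  out[idx > length(dist$tail)] <- 0
  out
}

encode_genome <- function(g) {
  raw <- utf8ToInt(g$sequence)
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut[raw]
}

scan_one_strand <- function(enc, m, width) {
  nwin <- length(enc) - width + 1L
  if (nwin < 1L) return(integer(0))
  total <- numeric(nwin)
  for (i in seq_len(width)) {
    total <- total + m[i, ][enc[i:(i + nwin - 1L)]]
  }
  total  # NA where any window base is N
}

#' Scan a genome for PWM matches on both strands
#'
#' Slides the PWM over every position of the forward and reverse strands,
#' scores by discretized log-odds, converts scores to exact p-values via
#' [score_distribution()], and reports matches with `p_value <= p_max`
#' (inclusive). Windows containing N are skipped. The genome is treated
#' as linear regardless of its circularity flag, matching standard
#' scanner behaviour.
#'
#' @param g A [genome()].
#' @param p A [pwm()].
#' @param p_max p-value threshold (default 1e-4).
#' @param background `"genome"` (default) estimates a 0-order background
#'   from the scanned sequence with both strands averaged; `"pwm"` uses
#'   the PWM's stored background; or a numeric length-4 vector.
#' @param granularity Score discretization (bits/bin).
#' @return Data frame of hits sorted by `start` then strand (`+` first):
#'   `motif_id`, `start`, `stop` (1-based inclusive, forward-strand
#'   coordinates of the leftmost/rightmost matched base), `strand`,
#'   `score` (bits), `p_value`, `matched_sequence` (reported on the hit
#'   strand).
#' @export
scan_genome <- function(g, p, p_max = 1e-4, background = "genome",
                        granularity = 0.001) {
  stopifnot(inherits(g, "genome"), inherits(p, "pwm"))
  if (p$width > g$length) {
    return(empty_hits())
  }
  enc <- encode_genome(g)
  bg <- resolve_background(background, enc, p)
  m <- int_score_matrix(p, bg, granularity)
  dist <- score_distribution(p, granularity = granularity, background = bg)
  # reverse-strand hits: score the forward sequence with the
  # reverse-complemented score matrix; start stays the leftmost base
  m_rc <- m[rev(seq_len(p$width)), rev(seq_len(4L)), drop = FALSE]
  res <- list()
  for (str in c("+", "-")) {
    mm <- if (str == "+") m else m_rc
    total <- scan_one_strand(enc, mm, p$width)
    ok <- which(!is.na(total))
    if (length(ok) == 0L) next
    pv <- score_pvalue(dist, as.integer(round(total[ok])))
    hit <- ok[pv <= p_max]
    if (length(hit) == 0L) next
    seqs <- substring(g$sequence, hit, hit + p$width - 1L)
    if (str == "-") {
      seqs <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
    }
    res[[str]] <- data.frame(
      motif_id = p$id, start = hit, stop = hit + p$width - 1L,
      strand = str,
      score = total[hit] * granularity,
      p_value = pv[match(hit, ok)],
      matched_sequence = seqs,
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(empty_hits())
  out <- do.call(rbind, res)
  out <- out[order(out$start, factor(out$strand, levels = c("+", "-"))), ]
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(motif_id = character(), start = integer(), stop = integer(),
             strand = character(), score = numeric(), p_value = numeric(),
             matched_sequence = character(), stringsAsFactors = FALSE)
}

resolve_background <- function(background, enc, p) {
  if (is.numeric(background)) {
    stopifnot(length(background) == 4L)
    bg <- background / sum(background)
  } else if (identical(background, "pwm")) {
    bg <- p$background
  } else if (identical(background, "genome")) {
    cnt <- tabulate(enc, nbins = 4L)
    # average of both strands: A with T, C with G
    at <- (cnt[1L] + cnt[4L]) / 2
    cg <- (cnt[2L] + cnt[3L]) / 2
    bg <- c(at, cg, cg, at)
    bg[bg == 0] <- 0.5
    bg <- bg / sum(bg)
  } else {
    stop("background must be 'genome', 'pwm' or a length-4 numeric", call. = FALSE)
  }
  setNames(bg, BASES)
}

#' Count exact occurrences of a word on both strands
#'
#' Overlapping forward-strand occurrences of `word` plus forward-strand
#' occurrences of its reverse complement (i.e. reverse-strand instances).
#'
#' @param g A [genome()].
#' @param word Non-empty word over \{A,C,G,T\}.
#' @return Integer count.
#' @examples
#' count_exact(genome("g", "TGTGGATAA"), "TTATCCACA")  # 1, on the minus strand
#' @export
count_exact <- function(g, word) {
  stopifnot(inherits(g, "genome"), nchar(word) > 0L)
  word <- toupper(word)
  check_dna(word, "word")
  subj <- Biostrings::DNAString(g$sequence)
  fwd <- Biostrings::countPattern(word, subj)
  rev <- Biostrings::countPattern(reverse_complement(word), subj)
  fwd + rev
}
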
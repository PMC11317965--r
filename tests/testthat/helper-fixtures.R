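# Shared fixture builders and independent oracles for the test suite.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# A random strictly-positive PWM of the given width.
random_pwm <- function(width, alpha = 1) {
  probs <- matrix(rgamma(width * 4L, alpha) + 1e-6, width, 4L)
  probs <- probs / rowSums(probs)
  pwm(probs)
}

# A near-deterministic PWM concentrated on `word` (prob `p` on the word's
# base at each column).
word_pwm <- function(word, p = 0.97, background = rep(0.25, 4)) {
  e <- match(strsplit(word, "")[[1L]], c("A", "C", "G", "T"))
  probs <- matrix((1 - p) / 3, length(e), 4L)
  probs[cbind(seq_along(e), e)] <- p
  pwm(probs, background = background)
}

# Independent oracle for score-distribution tails: enumerate every k-mer,
# discretize per-column scores exactly as the scanner does, and weight by
# the background. Only feasible for small widths.
brute_force_tail <- function(p, int_score, background = p$background,
                             granularity = 0.001) {
  width <- p$width
  m <- round(log2(p$probs / matrix(background, width, 4L, byrow = TRUE)) /
               granularity)
  grid <- as.matrix(expand.grid(rep(list(1:4), width)))
  ints <- rowSums(matrix(m[cbind(rep(seq_len(width), each = nrow(grid)),
                                 as.vector(grid))], nrow = nrow(grid)))
  w <- apply(matrix(background[grid], nrow = nrow(grid)), 1L, prod)
  vapply(int_score, function(s) sum(w[ints >= s]), numeric(1))
}

# Brute-force scan oracle: score every window on both strands directly
# through log_odds() and the enumeration tail above.
brute_force_scan <- function(g, p, p_max, background = p$background,
                             granularity = 0.001) {
  width <- p$width
  n <- g$length - width + 1L
  if (n < 1L) return(data.frame(start = integer(), strand = character()))
  out <- list()
  for (i in seq_len(n)) {
    km <- substr(g$sequence, i, i + width - 1L)
    if (grepl("N", km, fixed = TRUE)) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") km else reverse_complement(km)
      e <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
      ints <- sum(round(log2(p$probs[cbind(seq_len(width), e)] /
                               background[e]) / granularity))
      pv <- brute_force_tail(p, ints, background, granularity)
      if (pv <= p_max) {
        out[[length(out) + 1L]] <- data.frame(start = i, strand = strand,
                                              p_value = pv)
      }
    }
  }
  if (length(out) == 0L) return(data.frame(start = integer(), strand = character()))
  do.call(rbind, out)
}

# Constant-valued replicate coverage tracks, for closed-form ratio checks.
constant_tracks <- function(value, length, n = 2L, genome_name = "g") {
  lapply(seq_len(n), function(i) coverage_track(genome_name, rep(value, length)))
}

# Hits table builder for ranking tests.
make_hits <- function(start, score, strand = "+", motif_id = "m",
                      width = 9L, p_value = NULL) {
  n <- length(start)
  data.frame(motif_id = rep_len(motif_id, n), start = start,
             stop = start + width - 1L, strand = rep_len(strand, n),
             score = score,
             p_value = if (is.null(p_value)) 2^(-score) else p_value,
             matched_sequence = strrep("A", width),
             stringsAsFactors = FALSE)
}
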
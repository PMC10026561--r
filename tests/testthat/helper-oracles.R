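# Independent brute-force oracles: explicit loops, no shared code with the
# package internals they check.

# rank with average ties via counting: rank_i = count_less + (count_tie + 1)/2
# where count_tie includes i itself.
oracle_percentiles <- function(scores) {
  n <- length(scores)
  out <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0
    tie <- 0
    for (j in seq_len(n)) {
      if (scores[j] < scores[i]) less <- less + 1
      else if (scores[j] == scores[i]) tie <- tie + 1
    }
    rank_i <- less + (tie + 1) / 2
    out[i] <- (rank_i - 0.5) / n * 100
  }
  out
}

oracle_split_label <- function(label) {
  toks <- strsplit(label, "-", fixed = TRUE)[[1]]
  toks[toks != "ζ"]
}

oracle_motif_mean <- function(labels, percentiles, motif) {
  vals <- c()
  for (i in seq_along(labels)) {
    if (motif %in% oracle_split_label(labels[i])) {
      vals <- c(vals, percentiles[i])
    }
  }
  list(mean = if (length(vals)) mean(vals) else NA_real_, n = length(vals))
}

oracle_pair_mean <- function(labels, percentiles, a, b) {
  vals <- c()
  for (i in seq_along(labels)) {
    m <- oracle_split_label(labels[i])
    hit <- if (a == b) sum(m == a) >= 2 else (a %in% m) && (b %in% m)
    if (hit) vals <- c(vals, percentiles[i])
  }
  list(mean = if (length(vals)) mean(vals) else NA_real_, n = length(vals))
}

oracle_position_mean <- function(labels, percentiles, motif, slot_index) {
  vals <- c()
  for (i in seq_along(labels)) {
    m <- oracle_split_label(labels[i])
    if (length(m) >= slot_index && m[slot_index] == motif) {
      vals <- c(vals, percentiles[i])
    }
  }
  list(mean = if (length(vals)) mean(vals) else NA_real_, n = length(vals))
}

# All ordered sequences of 1..S motifs by explicit nested loops.
oracle_enumerate <- function(ids, S) {
  out <- character(0)
  for (a in ids) out <- c(out, a)
  if (S >= 2) for (a in ids) for (b in ids) out <- c(out, paste(a, b, sep = "-"))
  if (S >= 3) for (a in ids) for (b in ids) for (c in ids) {
    out <- c(out, paste(a, b, c, sep = "-"))
  }
  out
}
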
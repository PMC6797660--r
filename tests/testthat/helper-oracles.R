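# Independent oracles and small utilities shared across test files.

set_test_seed <- function(seed) set.seed(seed)

random_nucleotides <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force epitope scan: plain nested loops, no shared code with the
# implementation.
brute_scan <- function(protein, epitopes, max_mismatch) {
  seq <- strsplit(protein, "")[[1]]
  out <- NULL
  if (length(seq) < 9) return(data.frame())
  for (s in 0:(length(seq) - 9)) {
    for (e in seq_len(nrow(epitopes))) {
      ep <- strsplit(epitopes$sequence[e], "")[[1]]
      mm <- 0
      for (k in 1:9) if (seq[s + k] != ep[k]) mm <- mm + 1
      if (mm <= max_mismatch) {
        out <- rbind(out, data.frame(epitope_name = epitopes$name[e],
                                     start = s, mismatches = mm))
      }
    }
  }
  out
}

# Independent dynamic program for the codon-aware free-end-gap alignment
# score: a direct (slow) R transcription of the scoring model, written
# against the model definition, not the C++ code path.
oracle_align_score <- function(q, r, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2,
                               frameshift = -30) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e18
  # states: M=1, D1=2, D2=3, D0=4, I1=5, I2=6, I0=7
  f <- array(NEG, dim = c(n + 1, m + 1, 7))
  f[1, , 1] <- 0; f[, 1, 1] <- 0
  close_pen <- c(0, frameshift, frameshift, 0, frameshift, frameshift, 0)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (qc[i - 1] == rc[j - 1]) match else mismatch
      best <- NEG
      for (s in 1:7) {
        v <- f[i - 1, j - 1, s]
        if (v > NEG / 2) best <- max(best, v + sub + close_pen[s])
      }
      f[i, j, 1] <- best
      f[i, j, 2] <- max(f[i, j - 1, 1] + gap_open + gap_extend,
                        f[i, j - 1, 4] + gap_extend)
      f[i, j, 3] <- f[i, j - 1, 2] + gap_extend
      f[i, j, 4] <- f[i, j - 1, 3] + gap_extend
      f[i, j, 5] <- max(f[i - 1, j, 1] + gap_open + gap_extend,
                        f[i - 1, j, 7] + gap_extend)
      f[i, j, 6] <- f[i - 1, j, 5] + gap_extend
      f[i, j, 7] <- f[i - 1, j, 6] + gap_extend
    }
  }
  best <- max(f[n + 1, , 1], f[, m + 1, 1])
  if (best < NEG / 2) 0 else best
}

# Mutate n random positions of a nucleotide string (to another base).
mutate_bases <- function(seq, n) {
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), n)
  ch[idx] <- vapply(ch[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

# Small cohort cache so several test files can reuse one simulation.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(seed, n_genes, ...) {
  key <- paste(seed, n_genes, ..., sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(sim_config(seed = seed,
                                                       n_genes = n_genes, ...))
  }
  .cohort_cache[[key]]
}
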
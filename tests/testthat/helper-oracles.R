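# Shared fixtures and independent oracles, built in code at test time.

rna_alphabet <- c("A", "U", "G", "C")

random_rna <- function(n = 19L) {
  paste(sample(rna_alphabet, n, replace = TRUE), collapse = "")
}

# Independent k-mer frequency oracle: Biostrings' oligonucleotide counter
# on the DNA transcription of the sequence, remapped from its ACGT order
# to this package's A < U < G < C order.
oracle_kmer_frequencies <- function(sequences, k) {
  dna <- Biostrings::DNAStringSet(chartr("U", "T", sequences))
  counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
  colnames(counts) <- paste0(chartr("T", "U", colnames(counts)), "%")
  words <- paste0(sirnaforest:::kmer_words(k), "%")
  counts[, words, drop = FALSE] / (nchar(sequences)[1L] - k + 1L)
}

# Brute-force maximum nested pairing: enumerates, without memoization or
# dynamic programming, every way to leave position i unpaired or pair it
# with a compatible partner, and returns the maximum pair count.
oracle_max_pairing <- function(sequence, min_loop = 3L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  best <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    out <- best(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (pairs_ok(chars[i], chars[k])) {
        out <- max(out, 1L + best(i + 1L, k - 1L) + best(k + 1L, j))
      }
    }
    out
  }
  as.numeric(best(1L, length(chars)))
}

# Small labeled toy set: two Gaussian blobs, linearly separable for sep
# large relative to sd.
make_blobs <- function(n_per_class = 20L, sep = 3, sd = 0.5, p = 2L,
                       seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p, 0, sd), ncol = p),
             matrix(rnorm(n_per_class * p, sep, sd), ncol = p))
  colnames(X) <- paste0("f", seq_len(p))
  y <- rep(c("negative", "positive"), each = n_per_class)
  list(X = X, y = factor(y, levels = c("negative", "positive")))
}

# Strongly separated synthetic scenario (motif effect >> noise): the
# baseline sits clear of the 0.5 cutoff, so a single planted UCC
# occurrence flips the label almost deterministically.
separated_config <- function(n, seed) {
  generator_config(n = n, base_level = 0.58,
                   motif_effects = c(UCC = 0.2), noise_sd = 0.03,
                   seed = seed)
}
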
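RNA_ALPHABET <- c("A", "U", "G", "C")
POSITIONAL_CODES <- c(A = 0.1, U = 0.2, G = 0.3, C = 0.4)

# All k-mers over the RNA alphabet in lexicographic order under A < U < G < C
# (first character most significant).
kmer_words <- function(k, alphabet = RNA_ALPHABET) {
  if (k == 1L) return(alphabet)
  unlist(lapply(alphabet, function(a) paste0(a, kmer_words(k - 1L, alphabet))))
}

#' The canonical 120-feature schema
#'
#' The fixed feature order used throughout the package: 19 positional
#' nucleotide codes `NT1..NT19`; 4 mononucleotide frequencies `A%..C%`;
#' 16 dinucleotide and 64 trinucleotide frequencies (lexicographic under
#' `A < U < G < C`); 16 G/C-content features (`GC_overall` plus the 15
#' five-nt sliding windows `GC_w1..GC_w15`); and the secondary-structure
#' minimum free energy `MFE`.
#'
#' @return List with `names` (120 feature names) and `groups` (named list
#'   of index ranges).
#' @examples
#' s <- feature_schema()
#' lengths(s$groups)
#' @export
feature_schema <- function() {
  nm <- c(paste0("NT", 1:19),
          paste0(RNA_ALPHABET, "%"),
          paste0(kmer_words(2L), "%"),
          paste0(kmer_words(3L), "%"),
          "GC_overall", paste0("GC_w", 1:15),
          "MFE")
  stopifnot(length(nm) == 120L, !anyDuplicated(nm))
  list(names = nm,
       groups = list(positional = 1:19,
                     mono = 20:23,
                     dimer = 24:39,
                     trimer = 40:103,
                     gc = 104:119,
                     structure = 120L))
}

#' Positional nucleotide codes
#'
#' Encodes the nucleotide identity at each of the 19 positions (1-based
#' from the 5' end of the antisense strand) as a real code:
#' A = 0.1, U = 0.2, G = 0.3, C = 0.4.
#'
#' @param sequence A 19-nt sequence (normalized internally).
#' @return Named numeric vector `NT1..NT19`.
#' @examples
#' positional_codes("GUCAAAAAAAAAAAAAAAA")[1:3]
#' @export
positional_codes <- function(sequence) {
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) != 19L) {
    stop("positional codes are defined for 19-nt sequences only")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  stats::setNames(POSITIONAL_CODES[chars], paste0("NT", 1:19))
}

#' Decode positional codes back to a sequence
#'
#' Inverse of [positional_codes()]; the code map is a bijection of the
#' alphabet, so decoding recovers the sequence exactly.
#'
#' @param codes Numeric vector of codes in `{0.1, 0.2, 0.3, 0.4}`.
#' @return The decoded sequence.
#' @export
decode_positional <- function(codes) {
  idx <- match(round(codes * 10), round(POSITIONAL_CODES * 10))
  if (anyNA(idx)) stop("codes must be in {0.1, 0.2, 0.3, 0.4}")
  paste(names(POSITIONAL_CODES)[idx], collapse = "")
}

#' Overlapping k-mer frequencies
#'
#' Counts each of the `4^k` words among the `L - k + 1` overlapping
#' windows of the sequence and divides by the window count, so each group
#' is a probability vector summing to 1.
#'
#' @param sequence Sequence of length `L >= k` (normalized internally).
#' @param k Word length, 1 to 3.
#' @return Named numeric vector of length `4^k`, lexicographic under
#'   `A < U < G < C`, names suffixed with `%`.
#' @examples
#' kmer_frequencies("AUAUAUAUAUAUAUAUAUA", 2)[c("AU%", "UA%")]
#' @export
kmer_frequencies <- function(sequence, k) {
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  sequence <- normalize_sequence(sequence)
  L <- nchar(sequence)
  if (L < k) stop("sequence shorter than k")
  nwin <- L - k + 1L
  windows <- substring(sequence, 1:nwin, k:L)
  words <- kmer_words(k)
  counts <- table(factor(windows, levels = words))
  stats::setNames(as.numeric(counts) / nwin, paste0(words, "%"))
}

#' Global and local G/C content
#'
#' The overall G/C fraction of the 19-nt sequence plus the G/C fraction in
#' each of the 15 sliding windows of five nucleotides (windows start at
#' positions 1..15 from the 5' end of the antisense strand; window 1 is
#' the "first 5 bases" terminal feature).
#'
#' @param sequence A 19-nt sequence (normalized internally).
#' @param window Window width (default 5).
#' @return Named numeric vector `GC_overall`, `GC_w1..GC_w15`.
#' @export
gc_features <- function(sequence, window = 5L) {
  sequence <- normalize_sequence(sequence)
  L <- nchar(sequence)
  if (L != 19L) stop("G/C window features are defined for 19-nt sequences")
  gc <- strsplit(sequence, "", fixed = TRUE)[[1L]] %in% c("G", "C")
  nwin <- L - window + 1L
  local <- vapply(seq_len(nwin),
                  function(i) mean(gc[i:(i + window - 1L)]), numeric(1L))
  stats::setNames(c(mean(gc), local),
                  c("GC_overall", paste0("GC_w", seq_len(nwin))))
}

#' Secondary-structure free energy of one sequence
#'
#' Delegates to a folding backend (see [nussinov_backend()] and
#' [rnafold_backend()]) and checks the contract: the returned minimum free
#' energy is a single finite number at most 0 kcal/mol.
#'
#' @param sequence A sequence (normalized internally).
#' @param backend A `folding_backend`.
#' @return Minimum free energy in kcal/mol (\eqn{\le 0}).
#' @export
fold_free_energy <- function(sequence, backend = nussinov_backend()) {
  stopifnot(inherits(backend, "folding_backend"))
  sequence <- normalize_sequence(sequence)
  mfe <- backend$fold(sequence)
  if (!is.numeric(mfe) || length(mfe) != 1L || !is.finite(mfe)) {
    stop("backend '", backend$name, "' returned a non-numeric energy")
  }
  if (mfe > 1e-9) {
    stop("backend '", backend$name, "' returned a positive free energy")
  }
  min(mfe, 0)
}

#' Encode one siRNA as the 120-feature vector
#'
#' Concatenates, in [feature_schema()] order: positional codes,
#' mono-/di-/trinucleotide frequencies, G/C-content features, and the
#' folding free energy. Deterministic for a fixed sequence and backend.
#'
#' @param sequence A 19-nt sequence (or a single-row `sirna_dataset`).
#' @param backend A `folding_backend` (default: built-in Nussinov model).
#' @return Named numeric vector of length 120.
#' @examples
#' v <- extract_features("AUGCAUGCAUGCAUGCAUG")
#' length(v)
#' @export
extract_features <- function(sequence, backend = nussinov_backend()) {
  if (inherits(sequence, "sirna_dataset")) {
    stopifnot(nrow(sequence) == 1L)
    sequence <- sequence$sequence
  }
  sequence <- normalize_sequence(sequence)
  v <- c(positional_codes(sequence),
         kmer_frequencies(sequence, 1L),
         kmer_frequencies(sequence, 2L),
         kmer_frequencies(sequence, 3L),
         gc_features(sequence),
         MFE = fold_free_energy(sequence, backend))
  schema <- feature_schema()
  stopifnot(identical(names(v), schema$names))
  v
}

#' Encode a dataset as an n x 120 feature table
#'
#' Rows follow record order; row names are record ids. Labels and levels
#' travel with the table as attributes so downstream selection, training
#' and evaluation need only this one object.
#'
#' @param dataset A `sirna_dataset`.
#' @param backend A `folding_backend`.
#' @return A `feature_table`: numeric matrix with attributes `labels`
#'   (factor) and `levels` (numeric or `NULL`).
#' @export
extract_table <- function(dataset, backend = nussinov_backend()) {
  stopifnot(inherits(dataset, "sirna_dataset"))
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    tryCatch(extract_features(dataset$sequence[i], backend),
             error = function(e) {
               stop("feature extraction failed for record '",
                    dataset$id[i], "': ", conditionMessage(e))
             })
  })
  X <- do.call(rbind, rows)
  rownames(X) <- dataset$id
  attr(X, "labels") <- dataset$label
  attr(X, "levels") <- if (all(is.na(dataset$level))) NULL else dataset$level
  class(X) <- c("feature_table", class(X))
  X
}

#' Write a feature table as TSV
#'
#' @param table A `feature_table` (or plain matrix with column names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
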
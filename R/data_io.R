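#' Canonicalize an siRNA sequence to RNA alphabet
#'
#' Uppercases the input and maps DNA-style `T` to `U`, so that published
#' siRNA tables written in DNA letters can be used directly. Any character
#' outside `A, C, G, U, T` (either case) is rejected with the 1-based
#' position of the first offender.
#'
#' @param raw A non-empty character scalar.
#' @return The normalized sequence over `{A, U, G, C}`.
#' @examples
#' normalize_sequence("ugcAUGCaugcaugcaugc")
#' normalize_sequence("TTTTTTTTTTTTTTTTTTT")
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("sequence must be a non-empty character scalar")
  }
  up <- toupper(raw)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "U", "T"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid character '%s' at position %d",
                 substr(raw, bad[1L], bad[1L]), bad[1L]))
  }
  chartr("T", "U", up)
}

#' Label an siRNA from its remaining relative mRNA level
#'
#' A treatment leaving at most half of the wild-type mRNA (level \eqn{\le}
#' 0.5) defines a potent ("positive") siRNA; anything above 0.5 is
#' non-potent ("negative"). The boundary 0.5 itself is positive.
#'
#' @param level Numeric vector of remaining relative mRNA levels in
#'   `[0, 1]` (0 = complete silencing, 1 = no effect).
#' @return Factor with levels `negative`, `positive`.
#' @examples
#' label_from_level(c(0.2, 0.5, 0.51))
#' @export
label_from_level <- function(level) {
  if (!is.numeric(level) || anyNA(level)) {
    stop("level must be numeric without missing values")
  }
  if (any(level < 0 | level > 1)) {
    stop("level must lie in [0, 1]")
  }
  factor(ifelse(level <= 0.5, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Assemble a validated siRNA dataset
#'
#' Builds the package's central data container: a data frame with columns
#' `id`, `sequence`, `level`, `label`. Sequences are normalized
#' ([normalize_sequence()]) and by default must be exactly 19 nt (the
#' guide strand without its 3' two-nucleotide overhang). Labels are
#' derived from levels where absent, and checked for consistency with the
#' 0.5 cutoff where both are given.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of sequences (RNA or DNA letters).
#' @param level Optional numeric vector of remaining mRNA levels in `[0,1]`.
#' @param label Optional labels (`"positive"`/`"negative"`, logical or 0/1).
#' @param strict_length Require exactly 19 nt (default `TRUE`). Positional
#'   and windowed features are only defined for 19-nt input; relax this
#'   only for generalized k-mer work.
#' @return A `sirna_dataset` (also a `data.frame`).
#' @examples
#' d <- sirna_dataset(c("a", "b"),
#'                    c("AUGCAUGCAUGCAUGCAUG", "GGGCCCAAAUUUGGGCCCA"),
#'                    level = c(0.2, 0.8))
#' dataset_counts(d)
#' @export
sirna_dataset <- function(id, sequence, level = NULL, label = NULL,
                          strict_length = TRUE) {
  id <- as.character(id)
  n <- length(id)
  if (length(sequence) != n) stop("id and sequence lengths differ")
  if (anyDuplicated(id)) {
    stop("duplicate id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sequence <- vapply(sequence, normalize_sequence, character(1L),
                     USE.NAMES = FALSE)
  if (strict_length) {
    badlen <- which(nchar(sequence) != 19L)
    if (length(badlen) > 0L) {
      stop("expected 19 nt for record(s): ",
           paste(id[badlen], collapse = ", "))
    }
  }
  if (!is.null(level)) {
    if (length(level) != n) stop("level length differs from id")
    if (anyNA(level) || any(level < 0 | level > 1)) {
      stop("level must lie in [0, 1] with no missing values")
    }
  }
  if (!is.null(label)) {
    if (length(label) != n) stop("label length differs from id")
    label <- as_label_factor(label)
    if (!is.null(level) && !all(label == label_from_level(level))) {
      stop("label inconsistent with the 0.5 level cutoff for record(s): ",
           paste(id[label != label_from_level(level)], collapse = ", "))
    }
  } else if (!is.null(level)) {
    label <- label_from_level(level)
  }
  out <- data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
  out$level <- if (is.null(level)) rep(NA_real_, n) else as.numeric(level)
  out$label <- if (is.null(label)) {
    factor(rep(NA_character_, n), levels = c("negative", "positive"))
  } else {
    label
  }
  class(out) <- c("sirna_dataset", "data.frame")
  out
}

#' Class counts of an siRNA dataset
#'
#' @param dataset A `sirna_dataset`.
#' @return Named integer vector `n_positive`, `n_negative`.
#' @export
dataset_counts <- function(dataset) {
  stopifnot(inherits(dataset, "sirna_dataset"))
  c(n_positive = sum(dataset$label == "positive", na.rm = TRUE),
    n_negative = sum(dataset$label == "negative", na.rm = TRUE))
}

#' @export
print.sirna_dataset <- function(x, ...) {
  cnt <- dataset_counts(x)
  cat(sprintf("siRNA dataset: %d records (%d positive, %d negative)\n",
              nrow(x), cnt[["n_positive"]], cnt[["n_negative"]]))
  NextMethod()
}

#' Read an siRNA dataset from TSV or FASTA
#'
#' Two on-disk layouts are accepted:
#' \describe{
#'   \item{TSV}{Tab-separated with a header; columns `id`, `sequence`,
#'     and optionally `level` and `label`.}
#'   \item{FASTA + level table}{A plain FASTA of 19-nt entries plus a
#'     two-column TSV (`id`, `level`) supplied as `levels_path`; ids are
#'     the first whitespace-delimited token of each FASTA header.}
#' }
#' Records are normalized and validated; labels are derived from levels
#' when not given explicitly. Record order is preserved.
#'
#' @param path Path to the TSV or FASTA file.
#' @param levels_path Optional path to the level table (FASTA input only).
#' @param strict_length Passed to [sirna_dataset()].
#' @return A `sirna_dataset`.
#' @export
read_dataset <- function(path, levels_path = NULL, strict_length = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  is_fasta <- grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE) ||
    startsWith(first, ">")
  if (is_fasta) {
    seqs <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    level <- NULL
    if (!is.null(levels_path)) {
      lv <- utils::read.delim(levels_path, stringsAsFactors = FALSE)
      if (!all(c("id", "level") %in% names(lv))) {
        stop("level table needs columns 'id' and 'level'")
      }
      miss <- setdiff(ids, lv$id)
      if (length(miss) > 0L) {
        stop("no level for record(s): ", paste(miss, collapse = ", "))
      }
      level <- lv$level[match(ids, lv$id)]
    }
    return(sirna_dataset(ids, as.character(seqs), level = level,
                         strict_length = strict_length))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!all(c("id", "sequence") %in% names(tab))) {
    stop("TSV needs header columns 'id' and 'sequence'")
  }
  level <- if ("level" %in% names(tab) && !all(is.na(tab$level))) {
    tab$level
  }
  label <- if ("label" %in% names(tab) && !all(is.na(tab$label))) {
    tab$label
  }
  sirna_dataset(tab$id, tab$sequence, level = level, label = label,
                strict_length = strict_length)
}

#' Write an siRNA dataset as TSV
#'
#' Emits the canonical tab-separated layout (`id`, `sequence`, `level`,
#' `label`) that [read_dataset()] parses back to an identical dataset.
#'
#' @param dataset A `sirna_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sirna_dataset"))
  out <- as.data.frame(dataset)
  out$label <- as.character(out$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
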
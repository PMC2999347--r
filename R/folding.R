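#' Folding backends
#'
#' A folding backend maps a sequence to the minimum free energy (MFE, in
#' kcal/mol, at most 0) of its predicted secondary structure. Backends are
#' deterministic for a fixed sequence and return exactly 0 for a sequence
#' admitting no base pairs under their model.
#'
#' `nussinov_backend()` is the built-in model: maximum nested base pairing
#' over AU, GC and GU (wobble) pairs with a minimum hairpin loop of three
#' unpaired bases, scored at `pair_energy` per pair. It is a structural
#' stand-in — monotone in the amount of pairable structure — not a
#' thermodynamic nearest-neighbor model.
#'
#' `rnafold_backend()` adapts an external ViennaRNA-compatible `RNAfold`
#' executable: the plain sequence is piped in and the MFE is parsed from
#' the trailing parenthesized energy of its output.
#'
#' @param pair_energy Energy per base pair, kcal/mol (negative).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @param path Name or path of the `RNAfold` executable.
#' @return A `folding_backend`: list with `name` and `fold(sequence)`.
#' @examples
#' b <- nussinov_backend()
#' b$fold("AAAAAAAAAAAAAAAAAAA")  # no pairs -> 0
#' @export
nussinov_backend <- function(pair_energy = -1.0, min_loop = 3L) {
  stopifnot(pair_energy < 0, min_loop >= 0)
  structure(
    list(name = sprintf("nussinov(pair=%.2f,loop=%d)", pair_energy, min_loop),
         fold = function(sequence) {
           cpp_nussinov_energy(sequence, pair_energy, as.integer(min_loop))
         }),
    class = "folding_backend")
}

#' @rdname nussinov_backend
#' @export
rnafold_backend <- function(path = "RNAfold") {
  exe <- Sys.which(path)
  if (!nzchar(exe)) {
    stop("RNAfold executable '", path, "' not found on PATH; ",
         "use the built-in nussinov_backend() instead")
  }
  structure(
    list(name = paste0("rnafold(", exe, ")"),
         fold = function(sequence) {
           out <- suppressWarnings(
             system2(exe, args = "--noPS", input = sequence, stdout = TRUE))
           line <- grep("\\(\\s*-?[0-9.]+\\)\\s*$", out, value = TRUE)
           if (length(line) == 0L) {
             stop("could not parse RNAfold output for: ", sequence)
           }
           as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1",
                          line[length(line)]))
         }),
    class = "folding_backend")
}

#' @export
print.folding_backend <- function(x, ...) {
  cat("folding backend:", x$name, "\n")
  invisible(x)
}
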
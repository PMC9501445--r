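# Nearest-neighbor molar extinction coefficient of single-stranded DNA at
# 260 nm and 25 degC, from the Cantor-Warshaw-Shapiro single-strand set.

# dinucleotide epsilon260 (M-1 cm-1)
.NN_DIMER <- c(
  AA = 27400, AC = 21200, AG = 25000, AT = 22800,
  CA = 21200, CC = 14600, CG = 18000, CT = 15200,
  GA = 25200, GC = 17600, GG = 21600, GT = 20000,
  TA = 23400, TC = 16200, TG = 19000, TT = 16800)

# monomer epsilon260 (M-1 cm-1)
.NN_MONO <- c(A = 15400, C = 7400, G = 11500, T = 8700)

#' Nearest-neighbor extinction coefficient of a DNA strand
#'
#' Single-strand molar extinction coefficient at 260 nm and 25 degC,
#' `eps = sum(adjacent dinucleotides) - sum(internal monomers)`, using the
#' Cantor-Warshaw-Shapiro values.  For the 22GT sequence
#' `GGGTTAGGGTTAGGGTTAGGGT` this evaluates to 223,500 M-1 cm-1.
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T` (case-insensitive),
#'   length >= 2.
#' @return Extinction coefficient in M-1 cm-1.
#' @export
nn_extinction <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) < 2) stop("sequence must contain at least 2 bases", call. = FALSE)
  bad <- which(!chars %in% names(.NN_MONO))
  if (length(bad)) {
    stop(sprintf("invalid base '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  dimers <- paste0(chars[-length(chars)], chars[-1])
  internal <- chars[-c(1, length(chars))]
  sum(.NN_DIMER[dimers]) - sum(.NN_MONO[internal])
}
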
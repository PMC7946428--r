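#' @import methods
#' @importFrom stats coef lm rnorm runif rbinom setNames complete.cases
#' @importFrom utils read.delim write.table modifyList
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

assertDNA <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("alphabet error: ", what, " must be a single character string")
  if (nchar(x) < 1L)
    stop("alphabet error: ", what, " is empty")
  if (grepl("[^ACGTNacgtn]", x))
    stop("alphabet error: ", what, " contains characters outside {A,C,G,T,N}")
  toupper(x)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick reverse complement over the {A,C,G,T,N} alphabet, operating
#' on plain character strings (vectorised).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @examples
#' revComp("AGG")   # "CCT"
#' @export
revComp <- function(x) {
  x <- vapply(x, assertDNA, character(1), USE.NAMES = FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a coding DNA string
#'
#' Translates from the first base to the first stop codon (standard code).
#' Trailing partial codons are dropped.
#'
#' @param x single DNA string starting at a codon boundary.
#' @param toStop logical; if TRUE (default) translation halts at the first
#'   stop codon and the stop is not included in the output.
#' @return single amino-acid string.
#' @export
translateCDS <- function(x, toStop = TRUE) {
  x <- assertDNA(x, "CDS")
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1L, n))))
  if (toStop) {
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0L) aa <- substr(aa, 1L, stop_at - 1L)
  }
  aa
}

# Run `expr` under a private RNG stream; global .Random.seed is untouched.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

randomDNA <- function(n, exclude_stops_in_frame = FALSE) {
  if (n <= 0L) return("")
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  s
}

# Random in-frame coding stretch (no internal stop codons), length n %% 3 == 0.
randomCodons <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  paste(codons, collapse = "")
}

gcFraction <- function(x) {
  x <- assertDNA(x)
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  gc / n
}

maxHomopolymer <- function(x) {
  x <- assertDNA(x)
  r <- rle(strsplit(x, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

# Wallace-rule melting estimate: 2(A+T) + 4(G+C), degrees C.
wallaceTm <- function(x) {
  x <- toupper(x)
  at <- nchar(gsub("[^AT]", "", x))
  gc <- nchar(gsub("[^GC]", "", x))
  2L * at + 4L * gc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
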
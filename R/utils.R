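#' @importFrom methods new validObject is setValidity slot
#' @importFrom stats hclust as.dist runif setNames
#' @importFrom utils head tail write.table read.table combn
NULL

## The 20 standard amino acids, alphabetical one-letter order used throughout.
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

## Reverse genetic-code lookup: amino acid -> synonymous codons.
.codonTable <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

.stopCodons <- c("TAA", "TAG", "TGA")

## Derive a reproducible child seed (< 2^31) from a master seed and a tag.
## Keeps independent random streams for the different simulator components.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

## Translate a DNA character string (frame 0; codons containing N or other
## ambiguity letters become X). Vectorized codon lookup -- called in the
## inner loops of the scanners.
translateDNA <- function(dna) {
  n <- nchar(dna) %/% 3L * 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  aa <- unname(Biostrings::GENETIC_CODE[substring(dna, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revComp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

## Sample n background bases, then repair any occurrence of the given
## (fixed-width, literal-or-class) regex patterns by resampling the offending
## window.  Used so that simulated intergenic/intronic filler does not carry
## accidental gene signals.
randomDNA <- function(n, avoid = character(0), alphabet = c("A","C","G","T")) {
  if (n <= 0L) return("")
  x <- paste(sample(alphabet, n, replace = TRUE), collapse = "")
  if (length(avoid)) {
    for (iter in 1:200) {
      hit <- FALSE
      for (pat in avoid) {
        m <- regexpr(pat, x, perl = TRUE)
        while (m[1] != -1L) {
          hit <- TRUE
          len <- attr(m, "match.length")
          repl <- paste(sample(setdiff(alphabet, substr(x, m[1], m[1])),
                               1L), collapse = "")
          ## change the first base of the match; cheap and always breaks it
          substr(x, m[1], m[1]) <- repl
          m <- regexpr(pat, x, perl = TRUE)
        }
      }
      if (!hit) break
    }
  }
  x
}

## Reflect a 1-based inclusive interval through a sequence of length L
## (coordinates on the reverse complement <-> forward strand).
reflectInterval <- function(start, end, L) {
  c(L - end + 1L, L - start + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Merge an override list over a base config. Unlike modifyList this keeps
## unnamed list elements (family definitions etc.): named sub-lists are
## merged recursively, everything else is replaced wholesale.
mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    bo <- base[[nm]]; ov <- override[[nm]]
    if (is.list(bo) && is.list(ov) &&
        length(names(bo)) == length(bo) && length(names(ov)) == length(ov) &&
        all(nzchar(names(ov))))
      base[[nm]] <- mergeConfig(bo, ov)
    else base[[nm]] <- ov
  }
  base
}
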
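#' @useDynLib siseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn
NULL

# IUPAC nucleotide code -> set of denoted bases
iupac_sets <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
}

iupac_alphabet <- function() names(iupac_sets())

#' Normalize a nucleotide string
#'
#' Uppercases, converts U to T, and validates against the IUPAC alphabet.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @export
normalize_seq <- function(x) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl(paste0("[^", paste(iupac_alphabet(), collapse = ""), "]"), x)
  if (any(bad)) {
    abort(sprintf("non-IUPAC characters in sequence(s): %s",
                  paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  x
}

#' Reverse complement (IUPAC-aware)
#'
#' @param x character vector of IUPAC nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  fwd <- "ACGTRYSWKMBDHVN"
  rev <- "TGCAYRSWMKVHDBN"
  vapply(x, function(s) {
    s <- chartr(fwd, rev, s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# TRUE where the IUPAC codes a and b denote at least one common base
iupac_compatible_matrix <- function() {
  sets <- iupac_sets()
  ab <- names(sets)
  m <- matrix(FALSE, length(ab), length(ab), dimnames = list(ab, ab))
  for (i in ab) for (j in ab) m[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0
  m
}

# EDNAFULL-like scoring over the IUPAC alphabet: any compatible pair scores
# as a match (+5), incompatible pairs -4
iupac_substitution_matrix <- function(match = 5, mismatch = -4) {
  comp <- iupac_compatible_matrix()
  ifelse(comp, match, mismatch)
}

# Per-column compatibility of two equal-length (possibly gapped) strings;
# gaps are incompatible
iupac_column_matches <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  comp <- iupac_compatible_matrix()
  ok <- ca %in% rownames(comp) & cb %in% rownames(comp)
  n <- sum(ok)
  if (n == 0) return(0L)
  sum(comp[cbind(ca[ok], cb[ok])])
}
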
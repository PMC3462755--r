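#' Default SI-Seq sequencing primers
#'
#' The four sequencing primers that define the serial read structure: the
#' forward V5 and V6a primers and the reverse V6b and V7 primers. Each
#' 36-nt segment is sequenced 3' of one of these primers, giving the
#' concatenated V5::V6a::V7::V6b layout (144 nt at the default segment
#' length of 36).
#'
#' @param role filter by primer role; currently all defaults are sequencing
#'   primers (the V5 and V7 primers double as barcoded amplification
#'   primers).
#' @return a tibble with columns `name`, `sequence`, `direction`, `role`.
#' @export
siseq_primers <- function(role = c("sequencing", "amplification")) {
  role <- match.arg(role)
  out <- tibble::tibble(
    name = c("V5", "V6a", "V6b", "V7"),
    sequence = c(
      "GGGKAKCRAACVGGATTAGATACCCBGGTAGTCCWNRCHSTAAACGWTG",
      "AAGCRGHGGADYRTGYGGYTYAATTCGANGMWAMGCGMRRAACCTTACC",
      "CTCACRRCACGAGCTGACGACRRCCATGCASCACCT",
      "GGSCRTRMKGAYTTGACGTCRYCCCCDCCTTCCTCC"
    ),
    direction = c("forward", "forward", "reverse", "reverse"),
    role = "sequencing"
  )
  if (role == "amplification") out <- out[out$name %in% c("V5", "V7"), ]
  validate_primers(out)
  out
}

validate_primers <- function(primers) {
  stopifnot(all(c("name", "sequence", "direction") %in% names(primers)))
  if (any(!nzchar(primers$sequence))) abort("empty primer sequence")
  normalize_seq(primers$sequence)
  if (!all(primers$direction %in% c("forward", "reverse"))) {
    abort("primer direction must be 'forward' or 'reverse'")
  }
  invisible(primers)
}

#' Read a primer table from a tab-separated file
#'
#' Expects columns name, sequence, direction (forward/reverse).
#'
#' @param path file path.
#' @return a primer tibble.
#' @export
read_primers <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$sequence <- normalize_seq(df$sequence)
  validate_primers(df)
  tibble::as_tibble(df)
}
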
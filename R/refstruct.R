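#' Align degenerate primers to reference sequences
#'
#' Local (Smith-Waterman) alignment of each primer against each reference,
#' with an EDNAFULL-like scoring in which an IUPAC ambiguity code matches any
#' base it denotes (+5) and incompatible pairs score -4; gap opening and
#' extension penalties are 15 and 1. Reverse primers are aligned as their
#' reverse complement; both strands of the reference are searched so that
#' records deposited in flipped orientation are handled. Coordinates are
#' 0-based, half-open, on the reference forward strand.
#'
#' @param records tibble with columns `id` and `sequence`.
#' @param primers primer tibble (see [siseq_primers()]).
#' @param match,mismatch,gap_opening,gap_extension scoring parameters.
#' @param identity_floor minimum degenerate-aware identity (matches divided
#'   by primer length) for a primer to count as found.
#' @return tibble with one row per record x primer: `ref_id`, `primer_name`,
#'   `score`, `ref_start`, `ref_end`, `strand`, `identity_fraction`,
#'   `found`, `reads_right` (whether sequencing proceeds rightward on the
#'   forward strand from this site).
#' @export
align_primers <- function(records, primers = siseq_primers(),
                          match = 5, mismatch = -4,
                          gap_opening = 15, gap_extension = 1,
                          identity_floor = 0.6) {
  validate_primers(primers)
  stopifnot(all(c("id", "sequence") %in% names(records)))
  seqs <- normalize_seq(records$sequence)
  submat <- iupac_substitution_matrix(match, mismatch)
  subj <- Biostrings::DNAStringSet(seqs)
  out <- vector("list", nrow(primers))
  for (p in seq_len(nrow(primers))) {
    pseq <- normalize_seq(primers$sequence[p])
    pat1 <- if (primers$direction[p] == "forward") pseq else revcomp(pseq)
    fwd <- align_one_strand(pat1, subj, submat, gap_opening, gap_extension)
    rev <- align_one_strand(revcomp(pat1), subj, submat, gap_opening, gap_extension)
    use_fwd <- fwd$score >= rev$score
    res <- tibble::tibble(
      ref_id = records$id,
      primer_name = primers$name[p],
      score = ifelse(use_fwd, fwd$score, rev$score),
      ref_start = ifelse(use_fwd, fwd$start, rev$start),
      ref_end = ifelse(use_fwd, fwd$end, rev$end),
      strand = ifelse(use_fwd, "+", "-"),
      identity_fraction = ifelse(use_fwd, fwd$matches, rev$matches) / nchar(pseq),
      direction = primers$direction[p]
    )
    out[[p]] <- res
  }
  out <- dplyr::bind_rows(out)
  out$found <- out$identity_fraction >= identity_floor
  out$reads_right <- (out$direction == "forward") == (out$strand == "+")
  out
}

# best local alignment of pattern against each subject; returns 0-based
# half-open subject coordinates and degenerate-aware match counts
align_one_strand <- function(pattern, subjects, submat, gap_opening, gap_extension) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(rep(pattern, length(subjects))),
    subject = subjects,
    type = "local",
    substitutionMatrix = submat,
    gapOpening = gap_opening,
    gapExtension = gap_extension
  )
  ap <- as.character(Biostrings::alignedPattern(pa))
  as <- as.character(Biostrings::alignedSubject(pa))
  matches <- mapply(iupac_column_matches, ap, as, USE.NAMES = FALSE)
  rng <- methods::slot(methods::slot(pa, "subject"), "range")
  list(
    score = Biostrings::score(pa),
    start = BiocGenerics::start(rng) - 1L,
    end = BiocGenerics::end(rng),
    matches = matches
  )
}

#' Extract a sequencing fragment relative to an aligned primer
#'
#' `mode = "downstream"` returns the `segment_length` bases 3' of the
#' primer's 3' terminus, in sequencing direction (fragments read from
#' reverse-strand sites are reverse complemented so they read as the
#' sequencer produces them). `mode = "from_primer_start"` returns the window
#' beginning at the primer's 5' end. Windows extending past the sequence end
#' are truncated and flagged.
#'
#' @param sequence reference sequence (forward strand).
#' @param ref_start,ref_end 0-based half-open primer site coordinates.
#' @param reads_right logical; does sequencing proceed rightward on the
#'   forward strand (see [align_primers()]).
#' @param segment_length fragment length in nt.
#' @param mode `"downstream"` or `"from_primer_start"`.
#' @return list with `fragment`, `truncated`, and 0-based half-open source
#'   coordinates `src_start`, `src_end` on the forward strand.
#' @export
extract_fragment <- function(sequence, ref_start, ref_end, reads_right,
                             segment_length = 36,
                             mode = c("downstream", "from_primer_start")) {
  mode <- match.arg(mode)
  L <- nchar(sequence)
  if (mode == "downstream") {
    if (reads_right) {
      s <- ref_end; e <- min(ref_end + segment_length, L)
    } else {
      e <- ref_start; s <- max(ref_start - segment_length, 0L)
    }
  } else {
    if (reads_right) {
      s <- ref_start; e <- min(ref_start + segment_length, L)
    } else {
      e <- ref_end; s <- max(ref_end - segment_length, 0L)
    }
  }
  if (e <= s) {
    return(list(fragment = "", truncated = TRUE, src_start = s, src_end = s))
  }
  frag <- substr(sequence, s + 1, e)
  if (!reads_right) frag <- revcomp(frag)
  list(fragment = frag, truncated = (e - s) < segment_length,
       src_start = as.integer(s), src_end = as.integer(e))
}

siseq_segment_order <- c("V5", "V6a", "V7", "V6b")

#' Build a structure-matched reference database
#'
#' Aligns the sequencing primers to every reference record, extracts the
#' corresponding fragments, and concatenates them in the layout's read
#' order. For the serial layout the order is V5::V6a::V7::V6b (144 nt at
#' the default 36-nt segments). Records failing any required primer are
#' dropped and counted in the structuring report.
#'
#' @param records tibble with columns `id`, `lineage`, `sequence`.
#' @param primers primer tibble; the serial layout needs V5, V6a, V6b, V7.
#' @param layout `"siseq"` (four concatenated segments), `"platform454"`
#'   (single fragment from the V5 primer's 5' end), `"paired_end"` (V5 and
#'   V7 windows from the primers' 5' ends, joined), or `"full_length"`
#'   (records passed through unstructured).
#' @param segment_length nt per segment (per mate for `paired_end`; total
#'   read length for `platform454`).
#' @param identity_floor minimum primer identity to accept an alignment.
#' @return object of class `siseq_structured_ref`: the structured records
#'   are available via [tidy()] (columns `id`, `lineage`, `sequence`, and
#'   per-segment source coordinates); the structuring report via
#'   `attr(x, "report")` or [glance()].
#' @export
build_structured_db <- function(records, primers = siseq_primers(),
                                layout = c("siseq", "platform454",
                                           "paired_end", "full_length"),
                                segment_length = 36, identity_floor = 0.6) {
  layout <- match.arg(layout)
  stopifnot(all(c("id", "lineage", "sequence") %in% names(records)))
  if (nrow(records) == 0) {
    warn("empty reference input; returning empty structured reference")
    return(new_structured_ref(records[0, c("id", "lineage")], layout,
                              segment_length, report = tibble::tibble(
                                stage = character(), n = integer())))
  }
  records$sequence <- normalize_seq(records$sequence)
  short <- nchar(records$sequence) < 500 & layout != "full_length"
  dropped_short <- sum(short)
  records <- records[!short, , drop = FALSE]

  if (layout == "full_length") {
    recs <- tibble::tibble(id = records$id, lineage = records$lineage,
                           sequence = records$sequence)
    rep <- tibble::tibble(stage = c("input", "structured"),
                          n = c(nrow(records), nrow(records)))
    return(new_structured_ref(recs, layout, segment_length, rep))
  }

  segs <- switch(layout,
    siseq = tibble::tibble(primer = siseq_segment_order, mode = "downstream"),
    platform454 = tibble::tibble(primer = "V5", mode = "from_primer_start"),
    paired_end = tibble::tibble(primer = c("V5", "V7"), mode = "from_primer_start")
  )
  need <- segs$primer
  if (!all(need %in% primers$name)) {
    abort(sprintf("layout '%s' needs primers: %s", layout,
                  paste(need, collapse = ", ")))
  }
  aln <- align_primers(records, primers[primers$name %in% need, , drop = FALSE],
                       identity_floor = identity_floor)

  frag_tbl <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    a <- aln[aln$primer_name == segs$primer[k], , drop = FALSE]
    a <- a[base::match(records$id, a$ref_id), , drop = FALSE]
    fr <- purrr::pmap(
      list(records$sequence, a$ref_start, a$ref_end, a$reads_right),
      function(seq, s, e, rr) {
        extract_fragment(seq, s, e, rr, segment_length, segs$mode[k])
      }
    )
    frag_tbl[[k]] <- tibble::tibble(
      id = records$id,
      segment = segs$primer[k],
      found = a$found,
      fragment = purrr::map_chr(fr, "fragment"),
      truncated = purrr::map_lgl(fr, "truncated"),
      src_start = purrr::map_int(fr, "src_start"),
      src_end = purrr::map_int(fr, "src_end"),
      strand = ifelse(a$reads_right, "+", "-")
    )
  }
  frags <- dplyr::bind_rows(frag_tbl)
  bad <- frags |>
    dplyr::filter(!.data$found | .data$fragment == "") |>
    dplyr::distinct(.data$id, .data$segment)
  drop_ids <- unique(bad$id)
  keep <- records[!records$id %in% drop_ids, , drop = FALSE]

  wide <- frags |>
    dplyr::filter(.data$id %in% keep$id) |>
    tidyr::pivot_wider(id_cols = "id",
                       names_from = "segment",
                       values_from = c("fragment", "truncated",
                                       "src_start", "src_end", "strand"))
  wide <- wide[base::match(keep$id, wide$id), , drop = FALSE]
  concat <- do.call(paste0, lapply(segs$primer,
                                   function(s) wide[[paste0("fragment_", s)]]))
  recs <- tibble::tibble(id = keep$id, lineage = keep$lineage,
                         sequence = concat)
  recs <- dplyr::bind_cols(recs, wide[setdiff(names(wide), "id")])
  rep <- dplyr::bind_rows(
    tibble::tibble(stage = "input", n = nrow(records) + dropped_short),
    tibble::tibble(stage = "dropped_short", n = dropped_short),
    bad |> dplyr::count(.data$segment) |>
      dplyr::transmute(stage = paste0("dropped_", .data$segment), n = .data$n),
    tibble::tibble(stage = "structured", n = nrow(recs))
  )
  new_structured_ref(recs, layout, segment_length, rep)
}

new_structured_ref <- function(records, layout, segment_length, report) {
  structure(list(records = records, layout = layout,
                 segment_length = segment_length, report = report),
            class = "siseq_structured_ref")
}

#' @export
print.siseq_structured_ref <- function(x, ...) {
  cat(sprintf("<siseq_structured_ref> layout=%s segment_length=%d records=%d\n",
              x$layout, x$segment_length, nrow(x$records)))
  print(x$report)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.siseq_structured_ref <- function(x, ...) x$records

#' @export
glance.siseq_structured_ref <- function(x, ...) {
  tibble::tibble(layout = x$layout, segment_length = x$segment_length,
                 n_records = nrow(x$records),
                 n_dropped = sum(x$report$n[startsWith(x$report$stage, "dropped")]))
}

#' Fraction of references with a perfect degenerate-aware primer site
#'
#' A match is an ungapped placement (on either strand) where every primer
#' position is compatible with the reference base.
#'
#' @param records tibble with a `sequence` column.
#' @param primer a single-row primer tibble, or a primer sequence string.
#' @return fraction in \[0, 1\].
#' @export
probe_match_fraction <- function(records, primer) {
  if (is.data.frame(primer)) primer <- primer$sequence[1]
  primer <- normalize_seq(primer)
  if (nrow(records) == 0) abort("empty record set: fraction undefined")
  seqs <- Biostrings::DNAStringSet(normalize_seq(records$sequence))
  pat <- Biostrings::DNAString(primer)
  hit_f <- Biostrings::vcountPattern(pat, seqs, fixed = "subject") > 0
  hit_r <- Biostrings::vcountPattern(
    Biostrings::reverseComplement(pat), seqs, fixed = "subject") > 0
  mean(hit_f | hit_r)
}
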
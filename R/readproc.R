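#' Barcode map
#'
#' Each sample carries an ordered pair of 8-mer barcodes (one at each end
#' of the template). Assignment compares the two observed 8-mers,
#' concatenated, to the reference 16-mers; the 13-of-16 match rule can only
#' assign uniquely if any two reference 16-mers differ at 7 or more sites,
#' which is validated at load time.
#'
#' @param sample_id sample labels.
#' @param barcode1,barcode2 8-mer barcodes (V5 end and V7 end).
#' @return tibble of class `siseq_barcode_map` with derived column
#'   `barcode16`.
#' @export
barcode_map <- function(sample_id, barcode1, barcode2) {
  barcode1 <- normalize_seq(barcode1)
  barcode2 <- normalize_seq(barcode2)
  if (any(nchar(barcode1) != 8) || any(nchar(barcode2) != 8)) {
    abort("barcodes must be 8-mers")
  }
  bc16 <- paste0(barcode1, barcode2)
  if (anyDuplicated(bc16)) abort("concatenated 16-mers must be unique")
  if (length(bc16) > 1) {
    d <- round((1 - identity_matrix_cpp(bc16, bc16)) * 16)
    diag(d) <- NA
    if (any(d < 7, na.rm = TRUE)) {
      abort("any two reference 16-mers must differ at >= 7 sites")
    }
  }
  out <- tibble::tibble(sample_id = sample_id, barcode1 = barcode1,
                        barcode2 = barcode2, barcode16 = bc16)
  class(out) <- c("siseq_barcode_map", class(out))
  out
}

#' Read a barcode map from tab-separated text
#'
#' Expects columns sample_id (or sample), barcode1, barcode2.
#'
#' @param path file path.
#' @return a [barcode_map()] tibble.
#' @export
read_barcode_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  id <- if ("sample_id" %in% names(df)) df$sample_id else df$sample
  barcode_map(id, df$barcode1, df$barcode2)
}

#' Demultiplex read pairs by dual 8-mer barcodes
#'
#' The observed leading 8-mers of the two mates are concatenated (mate 1
#' then mate 2) and compared to each reference 16-mer by Hamming distance;
#' because templates occur in both orientations, the swapped concatenation
#' is also tested and the better of the two used. The best-matching
#' reference wins if it matches at `min_matches` (default 13) of 16 sites;
#' a tie between two references at or above the cutoff leaves the read
#' unassigned with reason "ambiguous". N counts as a mismatch.
#'
#' @param pairs read-pair tibble (see [simulate_reads()]).
#' @param barcodes a [barcode_map()].
#' @param min_matches minimum matching sites out of 16.
#' @return `pairs` with added columns `sample_assigned` (NA when
#'   unassigned), `barcode_matches`, `demux_reason` ("assigned",
#'   "unassigned", or "ambiguous").
#' @export
demultiplex <- function(pairs, barcodes, min_matches = 13) {
  obs <- paste0(substr(pairs$mate1_seq, 1, 8), substr(pairs$mate2_seq, 1, 8))
  swp <- paste0(substr(pairs$mate2_seq, 1, 8), substr(pairs$mate1_seq, 1, 8))
  M <- pmax(identity_matrix_cpp(obs, barcodes$barcode16),
            identity_matrix_cpp(swp, barcodes$barcode16))
  M <- round(M * 16)
  best <- max.col(M, ties.method = "first")
  bestval <- M[cbind(seq_len(nrow(M)), best)]
  tie <- rowSums(M == bestval) > 1
  reason <- dplyr::case_when(
    bestval < min_matches ~ "unassigned",
    tie ~ "ambiguous",
    TRUE ~ "assigned"
  )
  pairs$sample_assigned <- ifelse(reason == "assigned",
                                  barcodes$sample_id[best], NA_character_)
  pairs$barcode_matches <- as.integer(bestval)
  pairs$demux_reason <- reason
  pairs
}

#' Quality-filter policy
#'
#' Reads with more than `max_low_quality_bases` bases below
#' `phred_threshold` (over the 16S bases of both mates jointly by default;
#' barcode bases are excluded) are discarded.
#'
#' @param phred_threshold Phred cutoff (default 20).
#' @param max_low_quality_bases maximum tolerated low-quality bases
#'   (default 6; the rule is strict: discard iff count > max).
#' @param scope `"template"` (both mates jointly) or `"mate"` (either mate
#'   alone exceeding the maximum discards the pair).
#' @return list of class `siseq_quality_policy`.
#' @export
quality_policy <- function(phred_threshold = 20, max_low_quality_bases = 6,
                           scope = c("template", "mate")) {
  scope <- match.arg(scope)
  if (phred_threshold < 2 || phred_threshold > 41) {
    abort("phred_threshold must lie in [2, 41]")
  }
  if (max_low_quality_bases < 0) abort("max_low_quality_bases must be >= 0")
  structure(list(phred_threshold = phred_threshold,
                 max_low_quality_bases = max_low_quality_bases,
                 scope = scope),
            class = "siseq_quality_policy")
}

# per-read count of bases with Phred < threshold, skipping the first
# `skip` (barcode) cycles; quals must share one length
phred_low_counts <- function(quals, threshold, skip = 8) {
  if (length(quals) == 0) return(integer(0))
  L <- nchar(quals[1])
  if (any(nchar(quals) != L)) abort("quality strings of unequal length")
  m <- matrix(utf8ToInt(paste(quals, collapse = "")), nrow = L)
  as.integer(colSums(m[(skip + 1):L, , drop = FALSE] < threshold + 33))
}

#' Apply the Phred quality filter to read pairs
#'
#' @param pairs read-pair tibble.
#' @param policy a [quality_policy()].
#' @return `pairs` with added columns `n_low_quality` and `qc_keep`.
#' @export
quality_filter <- function(pairs, policy = quality_policy()) {
  if (!all(c("mate1_qual", "mate2_qual") %in% names(pairs)) ||
      any(is.na(pairs$mate1_qual)) || any(is.na(pairs$mate2_qual))) {
    abort("per-base qualities are required for quality filtering")
  }
  c1 <- phred_low_counts(pairs$mate1_qual, policy$phred_threshold)
  c2 <- phred_low_counts(pairs$mate2_qual, policy$phred_threshold)
  if (policy$scope == "template") {
    pairs$n_low_quality <- c1 + c2
    pairs$qc_keep <- pairs$n_low_quality <= policy$max_low_quality_bases
  } else {
    pairs$n_low_quality <- pmax(c1, c2)
    pairs$qc_keep <- c1 <= policy$max_low_quality_bases &
      c2 <= policy$max_low_quality_bases
  }
  pairs
}

#' Resolve read orientation against the structured reference
#'
#' The barcode-trimmed mates are concatenated in both orders
#' (Read1::Read2 and Read2::Read1) and each concatenation is compared to
#' the structured reference; the order with the higher best-hit identity is
#' retained if that identity meets the cutoff. The output sequence is
#' always reported in V5::V6a::V7::V6b order. An exact tie keeps the
#' Read1::Read2 interpretation and is flagged.
#'
#' @param pairs read-pair tibble.
#' @param sref structured reference (serial layout).
#' @param identity_cutoff minimum identity to call an orientation
#'   (default 0.8).
#' @return `pairs` with added columns `sequence` (oriented concatenation),
#'   `orientation_call` ("V5-first"/"V7-first"), `identity`, `oriented`
#'   (logical), `orientation_tie`.
#' @export
resolve_orientation <- function(pairs, sref, identity_cutoff = 0.8) {
  refs <- tidy(sref)$sequence
  r1 <- substr(pairs$mate1_seq, 9, nchar(pairs$mate1_seq))
  r2 <- substr(pairs$mate2_seq, 9, nchar(pairs$mate2_seq))
  ca <- paste0(r1, r2)
  cb <- paste0(r2, r1)
  ia <- apply(identity_matrix_cpp(ca, refs), 1, max)
  ib <- apply(identity_matrix_cpp(cb, refs), 1, max)
  a_wins <- ia >= ib
  pairs$sequence <- ifelse(a_wins, ca, cb)
  pairs$orientation_call <- ifelse(a_wins, "V5-first", "V7-first")
  pairs$identity <- pmax(ia, ib)
  pairs$oriented <- pairs$identity >= identity_cutoff
  pairs$orientation_tie <- ia == ib
  pairs
}

#' Run the full read-processing front end
#'
#' Stage order: demultiplex, quality filter, orientation resolution. Every
#' input read pair lands in exactly one outcome: `assigned_oriented`,
#' `unassigned` (including barcode-ambiguous), `quality_discarded`, or
#' `unoriented`.
#'
#' @param pairs read-pair tibble.
#' @param barcodes a [barcode_map()].
#' @param policy a [quality_policy()].
#' @param sref structured reference.
#' @param min_matches,identity_cutoff stage parameters.
#' @return list of class `siseq_frontend` with elements `reads` (tibble:
#'   `read_id`, `sample_id`, `sequence`, `orientation_call`, `identity`),
#'   `report` (per-stage, per-sample in/out counts), and `outcomes`
#'   (per-outcome counts). [tidy()] returns `reads`; [glance()] the
#'   outcome counts.
#' @export
run_frontend <- function(pairs, barcodes, policy = quality_policy(), sref,
                         min_matches = 13, identity_cutoff = 0.8) {
  n0 <- nrow(pairs)
  dm <- demultiplex(pairs, barcodes, min_matches)
  assigned <- dm |> dplyr::filter(!is.na(.data$sample_assigned))
  qc <- quality_filter(assigned, policy)
  kept <- qc |> dplyr::filter(.data$qc_keep)
  ori <- resolve_orientation(kept, sref, identity_cutoff)
  good <- ori |> dplyr::filter(.data$oriented)

  outcomes <- tibble::tibble(
    outcome = c("assigned_oriented", "unassigned", "quality_discarded",
                "unoriented"),
    n = c(nrow(good), n0 - nrow(assigned), nrow(assigned) - nrow(kept),
          nrow(kept) - nrow(good))
  )
  per_sample <- dplyr::full_join(
    assigned |> dplyr::count(sample_id = .data$sample_assigned,
                             name = "demux_out"),
    dplyr::full_join(
      kept |> dplyr::count(sample_id = .data$sample_assigned, name = "qc_out"),
      good |> dplyr::count(sample_id = .data$sample_assigned,
                           name = "orient_out"),
      by = "sample_id"),
    by = "sample_id") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ tidyr::replace_na(.x, 0L)))
  report <- per_sample |>
    tidyr::pivot_longer(-"sample_id", names_to = "stage", values_to = "n_out") |>
    dplyr::mutate(stage = sub("_out$", "", .data$stage))

  reads <- good |>
    dplyr::transmute(read_id = .data$read_id,
                     sample_id = .data$sample_assigned,
                     sequence = .data$sequence,
                     orientation_call = .data$orientation_call,
                     identity = .data$identity)
  structure(list(reads = reads, report = report, outcomes = outcomes,
                 n_input = n0),
            class = "siseq_frontend")
}

#' @export
print.siseq_frontend <- function(x, ...) {
  cat(sprintf("<siseq_frontend> %d read pairs in\n", x$n_input))
  print(x$outcomes)
  invisible(x)
}

#' @export
tidy.siseq_frontend <- function(x, ...) x$reads

#' @export
glance.siseq_frontend <- function(x, ...) {
  tidyr::pivot_wider(x$outcomes, names_from = "outcome", values_from = "n") |>
    dplyr::mutate(n_input = x$n_input)
}
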
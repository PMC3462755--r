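#' Read reference sequences with lineages from FASTA
#'
#' Headers carry an id followed by a semicolon-delimited lineage, either
#' as "id k__Bacteria;p__...;g__..." or as a plain semicolon list.
#'
#' @param path FASTA file.
#' @return tibble with columns `id`, `lineage`, `sequence`.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  lineage <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  tibble::tibble(id = id, lineage = lineage,
                 sequence = normalize_seq(as.character(ss)))
}

#' Write a structured reference database
#'
#' Writes the concatenated sequences as FASTA (headers `id lineage`), a
#' tab-separated sidecar of per-segment source coordinates, and the
#' structuring report.
#'
#' @param sref structured reference.
#' @param fasta_path,coords_path,report_path output paths (NULL to skip).
#' @return `sref`, invisibly.
#' @export
write_structured_db <- function(sref, fasta_path, coords_path = NULL,
                                report_path = NULL) {
  recs <- tidy(sref)
  ss <- Biostrings::DNAStringSet(recs$sequence)
  names(ss) <- paste(recs$id, recs$lineage)
  Biostrings::writeXStringSet(ss, fasta_path)
  if (!is.null(coords_path)) {
    coords <- recs[c("id", grep("^(src_|strand_|truncated_)",
                                names(recs), value = TRUE))]
    utils::write.table(coords, coords_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(report_path)) {
    utils::write.table(sref$report, report_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(sref)
}

#' Write simulated read pairs as paired FASTQ plus a truth table
#'
#' @param pairs read-pair tibble from [simulate_reads()].
#' @param prefix output prefix; writes `<prefix>_R1.fastq`,
#'   `<prefix>_R2.fastq` and `<prefix>_truth.tsv`.
#' @return the file paths, invisibly.
#' @export
write_read_pairs <- function(pairs, prefix) {
  f1 <- paste0(prefix, "_R1.fastq")
  f2 <- paste0(prefix, "_R2.fastq")
  ft <- paste0(prefix, "_truth.tsv")
  s1 <- Biostrings::DNAStringSet(pairs$mate1_seq)
  names(s1) <- paste0(pairs$read_id, "/1")
  s2 <- Biostrings::DNAStringSet(pairs$mate2_seq)
  names(s2) <- paste0(pairs$read_id, "/2")
  Biostrings::writeXStringSet(s1, f1, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$mate1_qual))
  Biostrings::writeXStringSet(s2, f2, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$mate2_qual))
  utils::write.table(pairs[c("read_id", "sample_id", "taxon", "orientation")],
                     ft, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, ft))
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param path1,path2 mate FASTQ files (Sanger qualities); read ids may be
#'   suffixed /1 and /2.
#' @return read-pair tibble.
#' @export
read_read_pairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2)) abort("mate files of unequal length")
  id1 <- sub("/[12]$", "", sub("\\s.*$", "", names(r1)))
  id2 <- sub("/[12]$", "", sub("\\s.*$", "", names(r2)))
  if (!all(id1 == id2)) abort("mate files are not in matching order")
  tibble::tibble(
    read_id = id1,
    mate1_seq = unname(as.character(r1)),
    mate1_qual = unname(as.character(S4Vectors::mcols(r1)$qualities)),
    mate2_seq = unname(as.character(r2)),
    mate2_qual = unname(as.character(S4Vectors::mcols(r2)$qualities))
  )
}

#' Write per-sample FASTA files of oriented reads
#'
#' @param frontend a [run_frontend()] result.
#' @param dir output directory (created if absent).
#' @return the file paths, invisibly.
#' @export
write_sample_fasta <- function(frontend, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  reads <- tidy(frontend)
  paths <- purrr::map_chr(split(reads, reads$sample_id), function(df) {
    p <- file.path(dir, paste0(df$sample_id[1], ".fasta"))
    ss <- Biostrings::DNAStringSet(df$sequence)
    names(ss) <- df$read_id
    Biostrings::writeXStringSet(ss, p)
    p
  })
  invisible(paths)
}

#' Write a classic OTU table
#'
#' Rows are OTUs, columns samples, last column taxonomy.
#'
#' @param table a `siseq_otu_table`.
#' @param path output path.
#' @return `table`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  df <- as.data.frame(table)
  df$rep_centroid <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}
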
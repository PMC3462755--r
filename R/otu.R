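#' Pairwise identity of two sequences
#'
#' Matching columns divided by alignment columns of a global alignment.
#' Equal-length sequences are compared ungapped (the structured-read
#' setting, where the error model is substitution-only); unequal lengths
#' fall back to a Needleman-Wunsch alignment.
#'
#' @param a,b nucleotide strings.
#' @return identity in \[0, 1\].
#' @export
seq_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    return(identity_matrix_cpp(a, b)[1, 1])
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  sum(ap == as & ap != "-") / length(ap)
}

#' Mean within-genus pairwise identity of structured sequences
#'
#' The empirical anchor for the OTU clustering cutoff: the mean over all
#' unordered pairs of structured sequences from one genus.
#'
#' @param sref structured reference.
#' @param genus genus label.
#' @return mean pairwise identity (scalar).
#' @export
mean_within_genus_identity <- function(sref, genus) {
  recs <- tidy(sref)
  g <- split_lineage(recs$lineage)$genus
  seqs <- recs$sequence[g == genus]
  if (length(seqs) < 2) abort("need >= 2 structured members of the genus")
  if (length(unique(nchar(seqs))) == 1) {
    m <- identity_matrix_cpp(seqs, seqs)
    return(mean(m[upper.tri(m)]))
  }
  pairs <- utils::combn(length(seqs), 2)
  mean(apply(pairs, 2, function(ij) seq_identity(seqs[ij[1]], seqs[ij[2]])))
}

#' Greedy centroid OTU clustering
#'
#' Reads are dereplicated into unique sequences, sorted by decreasing
#' abundance (ties broken lexicographically), and processed first-fit: a
#' sequence joins the first centroid it matches at or above the identity
#' cutoff, else founds a new centroid. Every read is assigned to exactly
#' one cluster.
#'
#' @param reads tibble with columns `read_id`, `sequence` (e.g. the tidy
#'   output of [run_frontend()]), or a character vector of sequences.
#' @param identity_cutoff clustering identity (default 0.87).
#' @return object of class `siseq_otu_clusters`: `clusters` (tibble `otu`,
#'   `centroid`, `size`), `membership` (tibble `read_id`, `otu`), and the
#'   cutoff. [tidy()] returns the cluster table.
#' @export
cluster_otus <- function(reads, identity_cutoff = 0.87) {
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = sprintf("r%06d", seq_along(reads)),
                            sequence = reads)
  }
  if (nrow(reads) == 0) {
    return(structure(list(
      clusters = tibble::tibble(otu = character(), centroid = character(),
                                size = integer()),
      membership = tibble::tibble(read_id = character(), otu = character()),
      identity_cutoff = identity_cutoff), class = "siseq_otu_clusters"))
  }
  derep <- reads |>
    dplyr::count(.data$sequence, name = "abundance") |>
    dplyr::arrange(dplyr::desc(.data$abundance), .data$sequence)
  cl <- greedy_cluster_cpp(derep$sequence, identity_cutoff)
  derep$cluster <- cl
  centroids <- derep |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(centroid = dplyr::first(.data$sequence),
                     size = sum(.data$abundance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$centroid) |>
    dplyr::mutate(otu = sprintf("OTU_%04d", dplyr::row_number()))
  derep <- dplyr::left_join(derep, centroids[c("cluster", "otu")],
                            by = "cluster")
  membership <- reads |>
    dplyr::left_join(derep[c("sequence", "otu")], by = "sequence") |>
    dplyr::select("read_id", "otu")
  structure(list(
    clusters = centroids |> dplyr::select("otu", "centroid", "size"),
    membership = membership,
    identity_cutoff = identity_cutoff), class = "siseq_otu_clusters")
}

#' @export
print.siseq_otu_clusters <- function(x, ...) {
  cat(sprintf("<siseq_otu_clusters> %d clusters from %d reads at identity %.2f\n",
              nrow(x$clusters), nrow(x$membership), x$identity_cutoff))
  invisible(x)
}

#' @export
tidy.siseq_otu_clusters <- function(x, ...) x$clusters

#' @export
glance.siseq_otu_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters), n_reads = nrow(x$membership),
                 identity_cutoff = x$identity_cutoff)
}

#' Calibrate the OTU clustering identity cutoff on a single-species control
#'
#' For each candidate cutoff the control reads are clustered, cluster
#' centroids are classified, and the number of clusters (and fraction of
#' reads) assigned to taxa conflicting with the known control lineage is
#' recorded. The chosen cutoff minimizes the false-positive read fraction;
#' ties are broken toward the candidate nearest the mean within-genus
#' identity of the control genus, then toward the larger cutoff.
#'
#' @param reads control read tibble (columns `read_id`, `sequence`).
#' @param classifier structure-matched classifier for centroid taxonomy.
#' @param truth_lineage control taxon lineage string.
#' @param anchor_identity mean within-genus identity of the control genus
#'   (see [mean_within_genus_identity()]).
#' @param candidates candidate cutoffs (default the
#'   97/95/93/90/87/85/83/80% sweep).
#' @param threshold,comparison centroid acceptance rule (per-read
#'   convention, support > 0.8).
#' @param n_boot,seed bootstrap parameters.
#' @return object of class `siseq_cutoff_calibration` with the per-cutoff
#'   sweep (`tidy()`) and the `chosen` cutoff.
#' @export
calibrate_cutoff <- function(reads, classifier, truth_lineage,
                             anchor_identity,
                             candidates = c(0.97, 0.95, 0.93, 0.90, 0.87,
                                            0.85, 0.83, 0.80),
                             threshold = 0.8, comparison = ">",
                             n_boot = 100, seed) {
  truth <- as.matrix(split_lineage(truth_lineage))[1, ]
  sweep <- purrr::map_dfr(seq_along(candidates), function(k) {
    cut <- candidates[k]
    cl <- cluster_otus(reads, identity_cutoff = cut)
    cent <- cl$clusters
    asg <- assign_taxonomy(
      classify_reads(classifier,
                     tibble::tibble(read_id = cent$otu,
                                    sequence = cent$centroid),
                     n_boot = n_boot, seed = seed + k),
      threshold = threshold, comparison = comparison)
    conflict <- rep(FALSE, nrow(asg))
    for (j in seq_along(classifier_ranks)) {
      lab <- asg[[paste0("label_", classifier_ranks[j])]]
      conflict <- conflict | (!is.na(lab) & lab != truth[j])
    }
    tibble::tibble(cutoff = cut,
                   n_clusters = nrow(cent),
                   n_fp_clusters = sum(conflict),
                   fp_fraction = sum(cent$size[conflict]) / sum(cent$size))
  })
  best <- sweep |>
    dplyr::arrange(.data$fp_fraction,
                   abs(.data$cutoff - anchor_identity),
                   dplyr::desc(.data$cutoff))
  structure(list(sweep = sweep, chosen = best$cutoff[1],
                 anchor_identity = anchor_identity),
            class = "siseq_cutoff_calibration")
}

#' @export
print.siseq_cutoff_calibration <- function(x, ...) {
  cat(sprintf("<siseq_cutoff_calibration> chosen cutoff %.2f (anchor %.3f)\n",
              x$chosen, x$anchor_identity))
  print(x$sweep)
  invisible(x)
}

#' @export
tidy.siseq_cutoff_calibration <- function(x, ...) x$sweep

#' @export
glance.siseq_cutoff_calibration <- function(x, ...) {
  tibble::tibble(chosen = x$chosen, anchor_identity = x$anchor_identity)
}

#' Run-specific low-abundance OTU threshold
#'
#' The single-species control's misclassification rate is used directly as
#' the minimum within-sample relative abundance for an OTU to be retained.
#'
#' @param rate control misclassification rate in \[0, 1).
#' @return the abundance threshold (scalar).
#' @export
abundance_threshold <- function(rate) {
  if (is.na(rate) || rate < 0 || rate >= 1) abort("rate must lie in [0, 1)")
  rate
}

#' Build an OTU table from per-sample clusterings
#'
#' OTUs are matched across samples by clustering the per-sample centroids
#' at the same identity cutoff. Centroids are classified and a merged OTU's
#' taxonomy is the deepest common ancestor of its members' accepted
#' lineages (conflicts are logged in the provenance).
#'
#' @param sample_clusters named list of [cluster_otus()] results, one per
#'   sample.
#' @param classifier classifier for centroid taxonomy (NULL to skip).
#' @param threshold,comparison centroid acceptance rule.
#' @param n_boot,seed bootstrap parameters (required when `classifier` is
#'   given).
#' @return object of class `siseq_otu_table`: tibble with one row per OTU,
#'   one count column per sample, and a `taxonomy` column; provenance in
#'   `attr(, "provenance")`.
#' @export
build_otu_table <- function(sample_clusters, classifier = NULL,
                            threshold = 0.8, comparison = ">",
                            n_boot = 100, seed = NULL) {
  stopifnot(length(sample_clusters) > 0, !is.null(names(sample_clusters)))
  cutoff <- sample_clusters[[1]]$identity_cutoff
  cent <- purrr::imap_dfr(sample_clusters, function(cl, s) {
    dplyr::mutate(dplyr::rename(cl$clusters, sample_otu = "otu"),
                  sample_id = s)
  })
  ord <- cent |>
    dplyr::group_by(.data$centroid) |>
    dplyr::summarise(total = sum(.data$size), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$centroid)
  merged <- greedy_cluster_cpp(ord$centroid, cutoff)
  ord$merged <- merged
  cent <- dplyr::left_join(cent, ord[c("centroid", "merged")], by = "centroid")
  otu_ids <- cent |>
    dplyr::group_by(.data$merged) |>
    dplyr::summarise(total = sum(.data$size),
                     rep_centroid = .data$centroid[which.max(.data$size)],
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$rep_centroid) |>
    dplyr::mutate(otu = sprintf("OTU_%04d", dplyr::row_number()))
  cent <- dplyr::left_join(cent, otu_ids[c("merged", "otu")], by = "merged")

  counts <- cent |>
    dplyr::group_by(.data$otu, .data$sample_id) |>
    dplyr::summarise(n = sum(.data$size), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L)

  taxonomy <- NULL
  conflicts <- character(0)
  if (!is.null(classifier)) {
    uq <- dplyr::distinct(cent, .data$otu, .data$centroid)
    asg <- assign_taxonomy(
      classify_reads(classifier,
                     tibble::tibble(read_id = paste0(uq$otu, "_", seq_len(nrow(uq))),
                                    sequence = uq$centroid),
                     n_boot = n_boot, seed = seed),
      threshold = threshold, comparison = comparison)
    asg$otu <- uq$otu
    lab_cols <- paste0("label_", classifier_ranks)
    taxonomy <- asg |>
      dplyr::group_by(.data$otu) |>
      dplyr::group_modify(function(df, key) {
        labs <- as.matrix(df[lab_cols])
        dca <- character(0)
        for (k in seq_len(ncol(labs))) {
          u <- unique(labs[, k])
          if (length(u) == 1 && !is.na(u)) dca <- c(dca, u) else break
        }
        conflict <- ncol(labs) > length(dca) &&
          length(unique(labs[, length(dca) + 1])) > 1
        tibble::tibble(taxonomy = paste(dca, collapse = ";"),
                       taxonomy_conflict = conflict)
      }) |>
      dplyr::ungroup()
    conflicts <- taxonomy$otu[taxonomy$taxonomy_conflict]
  }
  out <- dplyr::left_join(otu_ids[c("otu", "rep_centroid")], counts, by = "otu")
  if (!is.null(taxonomy)) {
    out <- dplyr::left_join(out, taxonomy[c("otu", "taxonomy")], by = "otu")
  }
  structure(out, class = c("siseq_otu_table", class(out)),
            provenance = list(identity_cutoff = cutoff,
                              abundance_threshold = NULL,
                              taxonomy_conflicts = conflicts))
}

#' Sample-by-OTU count matrix of an OTU table
#'
#' @param table a `siseq_otu_table`.
#' @return integer matrix, rows samples, columns OTUs.
#' @export
otu_matrix <- function(table) {
  cols <- setdiff(names(table), c("otu", "rep_centroid", "taxonomy"))
  m <- t(as.matrix(table[cols]))
  colnames(m) <- table$otu
  m
}

#' Remove low-abundance OTUs
#'
#' OTUs whose within-sample relative abundance is below the threshold have
#' their counts removed in that sample; OTUs left with no counts anywhere
#' are dropped. The applied threshold is recorded in the provenance.
#'
#' @param table a `siseq_otu_table`.
#' @param threshold minimum within-sample relative abundance (see
#'   [abundance_threshold()]).
#' @return the filtered table.
#' @export
apply_abundance_threshold <- function(table, threshold) {
  prov <- attr(table, "provenance")
  cols <- setdiff(names(table), c("otu", "rep_centroid", "taxonomy"))
  for (s in cols) {
    tot <- sum(table[[s]])
    if (tot > 0) {
      low <- table[[s]] / tot < threshold
      table[[s]][low] <- 0L
    }
  }
  keep <- rowSums(as.matrix(table[cols])) > 0
  out <- table[keep, , drop = FALSE]
  prov$abundance_threshold <- threshold
  attr(out, "provenance") <- prov
  out
}
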
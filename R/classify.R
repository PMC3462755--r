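classifier_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

split_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  parts <- lapply(parts, function(p) {
    p <- trimws(sub("^[a-z]__", "", p))
    p[!nzchar(p)] <- "unclassified"
    length(p) <- max(length(p), 6)
    p[is.na(p)] <- "unclassified"
    p[1:6]
  })
  m <- do.call(rbind, parts)
  colnames(m) <- classifier_ranks
  tibble::as_tibble(m)
}

#' Train the naive Bayes taxonomic classifier
#'
#' RDP-style word-based classifier: for each genus g and word w, the
#' conditional probability of w given g is the smoothed estimator
#' (n_g(w) + 0.5 * prior(w)) / (N_g + 1), with
#' prior(w) = (n(w) + 0.5) / (N + 1), where n counts training sequences
#' containing w (presence/absence, not multiplicity). The classifier must
#' be trained on sequences in the same structural format as the queries.
#'
#' @param sref structured reference (or tibble with `lineage`, `sequence`).
#' @param word_size word length in nt (default 8).
#' @return object of class `siseq_classifier`.
#' @export
train_classifier <- function(sref, word_size = 8) {
  recs <- if (inherits(sref, "siseq_structured_ref")) tidy(sref) else sref
  stopifnot(all(c("lineage", "sequence") %in% names(recs)))
  if (word_size < 1 || word_size > 10) abort("word_size must lie in 1..10")
  if (word_size > min(nchar(recs$sequence))) {
    abort("word_size exceeds the shortest training sequence")
  }
  tax <- split_lineage(recs$lineage)
  genus_key <- apply(as.matrix(tax), 1, paste, collapse = ";")
  genera <- unique(genus_key)
  g_idx <- base::match(genus_key, genera)
  V <- 4L^word_size
  enc <- encode_words_cpp(recs$sequence, word_size)
  counts <- matrix(0, nrow = V, ncol = length(genera))
  for (i in seq_along(recs$sequence)) {
    w <- enc$words[(enc$offsets[i] + 1):enc$offsets[i + 1]] + 1L
    counts[w, g_idx[i]] <- counts[w, g_idx[i]] + 1
  }
  n_g <- tabulate(g_idx, nbins = length(genera))
  N <- length(recs$sequence)
  prior <- (rowSums(counts) + 0.5) / (N + 1)
  logp <- log((counts + 0.5 * prior) / rep(n_g + 1, each = V))
  taxonomy <- split_lineage(genera)
  taxonomy$n_train <- n_g
  structure(list(word_size = word_size, logp = logp, taxonomy = taxonomy),
            class = "siseq_classifier")
}

#' @export
print.siseq_classifier <- function(x, ...) {
  cat(sprintf("<siseq_classifier> word_size=%d genera=%d training_seqs=%d\n",
              x$word_size, nrow(x$taxonomy), sum(x$taxonomy$n_train)))
  invisible(x)
}

#' @export
tidy.siseq_classifier <- function(x, ...) x$taxonomy

#' @export
glance.siseq_classifier <- function(x, ...) {
  tibble::tibble(word_size = x$word_size, n_genera = nrow(x$taxonomy),
                 n_training = sum(x$taxonomy$n_train))
}

#' Classify sequences with bootstrap confidence
#'
#' Each query is scored per genus as the sum of log conditional word
#' probabilities over its distinct words; bootstrap support is the fraction
#' of `n_boot` resamples (each drawing floor(W / word_size) words with
#' replacement from the query's W distinct words) whose top genus matches.
#' Per-rank support is the rollup: the fraction of resamples whose top
#' genus lies within the taxon on the best genus's lineage path, so
#' supports are monotone non-increasing from domain to genus.
#'
#' @param classifier a [train_classifier()] model.
#' @param reads tibble with columns `read_id` (optional) and `sequence`,
#'   or a character vector of sequences.
#' @param n_boot bootstrap trials (default 100).
#' @param seed RNG seed (required; results are reproducible given the seed).
#' @return object of class `siseq_classification`; [tidy()] gives one row
#'   per read and rank (`read_id`, `rank`, `label`, `support`), and
#'   `$results` holds the wide per-read table.
#' @export
classify_reads <- function(classifier, reads, n_boot = 100, seed) {
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = sprintf("q%06d", seq_along(reads)),
                            sequence = reads)
  }
  if (!"read_id" %in% names(reads)) {
    reads$read_id <- sprintf("q%06d", seq_len(nrow(reads)))
  }
  ws <- classifier$word_size
  if (any(nchar(reads$sequence) < ws)) {
    abort("query shorter than the classifier word size")
  }
  enc <- encode_words_cpp(reads$sequence, ws)
  kr <- with_seed(seed, classify_kernel(enc$words, enc$offsets,
                                        classifier$logp, n_boot, ws))
  tax <- classifier$taxonomy
  n <- nrow(reads)
  top <- kr$top
  boot <- kr$boot
  support <- matrix(NA_real_, n, length(classifier_ranks),
                    dimnames = list(NULL, classifier_ranks))
  labels <- matrix(NA_character_, n, length(classifier_ranks),
                   dimnames = list(NULL, classifier_ranks))
  ok <- !is.na(top)
  for (r in classifier_ranks) {
    groups <- unique(tax[[r]])
    ind <- outer(tax[[r]], groups, "==") * 1
    rank_counts <- boot %*% ind
    gi <- base::match(tax[[r]][top[ok]], groups)
    support[ok, r] <- rank_counts[cbind(which(ok), gi)] / n_boot
    labels[ok, r] <- tax[[r]][top[ok]]
  }
  results <- tibble::tibble(read_id = reads$read_id,
                            top_genus = ifelse(ok, tax$genus[top], NA))
  for (r in classifier_ranks) {
    results[[paste0("label_", r)]] <- labels[, r]
    results[[paste0("support_", r)]] <- support[, r]
  }
  structure(list(results = results, n_boot = n_boot),
            class = "siseq_classification")
}

#' @export
print.siseq_classification <- function(x, ...) {
  cat(sprintf("<siseq_classification> %d reads, %d bootstrap trials\n",
              nrow(x$results), x$n_boot))
  invisible(x)
}

#' @export
tidy.siseq_classification <- function(x, ...) {
  sup <- x$results |>
    dplyr::select("read_id", dplyr::starts_with("support_")) |>
    tidyr::pivot_longer(-"read_id", names_to = "rank", values_to = "support",
                        names_prefix = "support_")
  lab <- x$results |>
    dplyr::select("read_id", dplyr::starts_with("label_")) |>
    tidyr::pivot_longer(-"read_id", names_to = "rank", values_to = "label",
                        names_prefix = "label_")
  dplyr::left_join(lab, sup, by = c("read_id", "rank")) |>
    dplyr::mutate(rank = factor(.data$rank, levels = classifier_ranks))
}

#' Accept classifications down to a bootstrap-support threshold
#'
#' The accepted rank is the deepest rank whose support meets the threshold
#' under the chosen comparison: `">="` (used for simulation experiments at
#' 0.7) or `">"` (used for per-read assignment at 0.8). Shallower ranks are
#' retained, deeper ones discarded.
#'
#' @param classification a [classify_reads()] result.
#' @param threshold bootstrap support threshold.
#' @param comparison `">="` or `">"`.
#' @return tibble with `read_id`, `accepted_rank` (NA if no rank accepted),
#'   `accepted_depth` (0..6), and accepted labels `label_domain` ..
#'   `label_genus` (NA beyond the accepted rank).
#' @export
assign_taxonomy <- function(classification, threshold = 0.8,
                            comparison = c(">", ">=")) {
  comparison <- match.arg(comparison)
  res <- classification$results
  sup <- as.matrix(res[paste0("support_", classifier_ranks)])
  meets <- if (comparison == ">") sup > threshold else sup >= threshold
  meets[is.na(meets)] <- FALSE
  for (r in 2:ncol(meets)) meets[, r] <- meets[, r] & meets[, r - 1]
  depth <- rowSums(meets)
  out <- tibble::tibble(
    read_id = res$read_id,
    accepted_rank = ifelse(depth > 0, classifier_ranks[pmax(depth, 1)], NA),
    accepted_depth = as.integer(depth)
  )
  for (k in seq_along(classifier_ranks)) {
    r <- classifier_ranks[k]
    out[[paste0("label_", r)]] <- ifelse(depth >= k,
                                         res[[paste0("label_", r)]], NA)
  }
  out
}

#' Fraction of reads accepted at the genus rank
#'
#' The genus-assignability experiment: classify a read set with a
#' structure-matched classifier and report the fraction of reads whose
#' accepted rank is genus.
#'
#' @param classifier structure-matched classifier.
#' @param reads sequences (tibble or character vector).
#' @param threshold,comparison acceptance rule (defaults to the simulation
#'   convention, support >= 0.7).
#' @param n_boot,seed bootstrap parameters.
#' @return one-row tibble: `n_reads`, `n_genus`, `fraction_genus`.
#' @export
genus_assignability <- function(classifier, reads, threshold = 0.7,
                                comparison = ">=", n_boot = 100, seed) {
  if (is.character(reads) && length(reads) == 0 ||
      is.data.frame(reads) && nrow(reads) == 0) {
    abort("empty read set")
  }
  cl <- classify_reads(classifier, reads, n_boot = n_boot, seed = seed)
  asg <- assign_taxonomy(cl, threshold = threshold, comparison = comparison)
  tibble::tibble(n_reads = nrow(asg),
                 n_genus = sum(asg$accepted_rank == "genus", na.rm = TRUE),
                 fraction_genus = .data$n_genus / .data$n_reads)
}

#' Misclassification rate on a single-species control
#'
#' Among reads accepted at one or more ranks, the fraction whose accepted
#' lineage conflicts with the known source lineage at any accepted rank.
#' This run-specific error rate feeds the low-abundance OTU threshold.
#'
#' @param assignments an [assign_taxonomy()] table.
#' @param truth_lineage the control taxon's lineage string
#'   (semicolon-delimited, domain..genus).
#' @return one-row tibble: `n_classified`, `n_conflicting`, `rate`.
#' @export
misclassification_rate <- function(assignments, truth_lineage) {
  truth <- as.matrix(split_lineage(truth_lineage))[1, ]
  acc <- assignments[assignments$accepted_depth > 0, , drop = FALSE]
  if (nrow(acc) == 0) {
    return(tibble::tibble(n_classified = 0L, n_conflicting = 0L,
                          rate = NA_real_))
  }
  conflict <- rep(FALSE, nrow(acc))
  for (k in seq_along(classifier_ranks)) {
    lab <- acc[[paste0("label_", classifier_ranks[k])]]
    conflict <- conflict | (!is.na(lab) & lab != truth[k])
  }
  tibble::tibble(n_classified = nrow(acc),
                 n_conflicting = sum(conflict),
                 rate = sum(conflict) / nrow(acc))
}
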
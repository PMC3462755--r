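#' Rarefy a count vector to a fixed depth
#'
#' Subsampling without replacement (hypergeometric), via
#' [vegan::rrarefy()].
#'
#' @param counts non-negative integer vector (one sample).
#' @param depth target depth; must not exceed the sample total.
#' @param seed RNG seed.
#' @return integer vector of the same length summing to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed) {
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (depth > sum(counts)) abort("depth exceeds the sample total")
  # vegan warns on any vector whose smallest nonzero entry exceeds 1;
  # counts are validated above, so the heuristic does not apply
  with_seed(seed, as.integer(suppressWarnings(vegan::rrarefy(counts, depth))))
}

#' Bias-corrected Chao1 richness estimate
#'
#' S_obs + n1 (n1 - 1) / (2 (n2 + 1)), with n1 the singleton and n2 the
#' doubleton count; the (n2 + 1) form is defined when no doubletons exist.
#'
#' @param counts non-negative integer vector.
#' @return the Chao1 estimate (0 for an all-zero vector).
#' @export
chao1 <- function(counts) {
  s_obs <- sum(counts > 0)
  if (s_obs == 0) return(0)
  n1 <- sum(counts == 1)
  n2 <- sum(counts == 2)
  s_obs + n1 * (n1 - 1) / (2 * (n2 + 1))
}

#' Bray-Curtis dissimilarity
#'
#' 1 - 2 sum_i min(a_i, b_i) / (sum a + sum b).
#'
#' @param a,b equal-length non-negative count vectors, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) abort("count vectors of unequal length")
  if (sum(a) + sum(b) == 0) abort("both vectors all-zero: undefined")
  1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
}

#' Rarefaction curve of a richness metric
#'
#' Repeated subsampling without replacement at each depth (default 100
#' rarefactions per sampling step).
#'
#' @param counts count vector for one sample.
#' @param depths sampling depths (default 10 steps up to the sample total).
#' @param metric `"observed"` or `"chao1"`.
#' @param n_rep rarefactions per depth.
#' @param seed RNG seed.
#' @return tibble with columns `depth`, `mean`, `sd`.
#' @export
rarefaction_curve <- function(counts, depths = NULL, metric = c("observed", "chao1"),
                              n_rep = 100, seed) {
  metric <- match.arg(metric)
  total <- sum(counts)
  if (is.null(depths)) {
    depths <- unique(round(seq(max(1, total / 10), total, length.out = 10)))
  }
  if (any(depths > total)) abort("depth exceeds the sample total")
  f <- if (metric == "observed") function(x) sum(x > 0) else chao1
  with_seed(seed, {
    purrr::map_dfr(depths, function(d) {
      vals <- replicate(
        n_rep, f(as.integer(suppressWarnings(vegan::rrarefy(counts, d)))))
      tibble::tibble(depth = d, mean = mean(vals), sd = stats::sd(vals))
    })
  })
}

#' Species accumulation curve
#'
#' Mean cumulative OTU count as samples are drawn in random order
#' (default 100 orderings), optionally after removing OTUs whose share of
#' the grand total is below `abundance_filter` (the 0.1% filter).
#'
#' @param table a `siseq_otu_table` (or samples-by-OTUs count matrix).
#' @param n_orderings random sample orderings.
#' @param abundance_filter minimum share of the grand total (e.g. 0.001),
#'   or NULL for no filter.
#' @param seed RNG seed.
#' @return tibble with columns `k` (samples drawn), `mean`, `sd`,
#'   `filtered`.
#' @export
species_accumulation <- function(table, n_orderings = 100,
                                 abundance_filter = NULL, seed) {
  m <- if (inherits(table, "siseq_otu_table")) otu_matrix(table) else table
  filtered <- !is.null(abundance_filter)
  if (filtered) {
    share <- colSums(m) / sum(m)
    m <- m[, share >= abundance_filter, drop = FALSE]
  }
  if (nrow(m) == 1) {
    return(tibble::tibble(k = 1L, mean = sum(colSums(m) > 0), sd = 0,
                          filtered = filtered))
  }
  sa <- with_seed(seed, vegan::specaccum(m, method = "random",
                                         permutations = n_orderings))
  tibble::tibble(k = sa$sites, mean = sa$richness,
                 sd = ifelse(is.na(sa$sd), 0, sa$sd), filtered = filtered)
}
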
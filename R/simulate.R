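# run expr with a private RNG stream, restoring caller RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) abort("a seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# fixture gene layout (0-based half-open coordinates on a 1400 nt gene):
# primer sites are conserved; the four sequenced segments and two extra
# blocks are hypervariable
fixture_layout <- function(segment_length = 36) {
  L <- segment_length
  list(
    gene_length = 1400L,
    # forward primers end where their segment begins; reverse primers'
    # reverse complements begin where their (reverse-complemented) segment
    # ends
    v5_primer = c(742L, 791L),          # 49 nt forward
    v5_seg = c(791L, 791L + L),
    v6a_primer = c(867L, 916L),         # 49 nt forward
    v6a_seg = c(916L, 916L + L),
    v6b_seg = c(988L - L, 988L),        # read leftward, reverse complemented
    v6b_primer = c(988L, 1024L),        # 36 nt reverse (rc on forward strand)
    v7_seg = c(1060L - L, 1060L),       # read leftward, reverse complemented
    v7_primer = c(1060L, 1096L),        # 36 nt reverse (rc on forward strand)
    extra_variable = list(c(180L, 300L), c(450L, 560L))
  )
}

# concrete instantiation of a degenerate primer (one base per position)
instantiate_primer <- function(seq) {
  sets <- iupac_sets()
  ch <- strsplit(normalize_seq(seq), "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(c) {
    s <- sets[[c]]
    s[sample.int(length(s), 1)]
  }, character(1)), collapse = "")
}

mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    ch[p] <- sample(setdiff(bases, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic 16S-like reference database
#'
#' Builds ~1400 nt sequences containing exact (instantiated) sites for the
#' four default sequencing primers, conserved blocks, and hypervariable
#' blocks whose pairwise divergences realize the requested within- and
#' between-genus levels. Divergence is imposed only within hypervariable
#' windows (which include the four sequenced 36-nt segments), so structured
#' within-genus identity is approximately `1 - within_genus_divergence`.
#'
#' @param n_genera,species_per_genus database shape.
#' @param between_genus_divergence,within_genus_divergence target pairwise
#'   divergences within the hypervariable windows (fractions in (0, 1),
#'   within < between).
#' @param seed RNG seed (required; output is deterministic given the seed).
#' @return tibble with columns `id`, `lineage` (semicolon-delimited
#'   domain..genus), `sequence`.
#' @export
generate_fixture_db <- function(n_genera = 8, species_per_genus = 5,
                                between_genus_divergence = 0.25,
                                within_genus_divergence = 0.11,
                                seed) {
  if (!(between_genus_divergence > 0 && between_genus_divergence < 1 &&
        within_genus_divergence > 0 && within_genus_divergence < 1)) {
    abort("divergences must lie in (0, 1)")
  }
  if (within_genus_divergence >= between_genus_divergence) {
    abort("within-genus divergence must be below between-genus divergence")
  }
  with_seed(seed, {
    lay <- fixture_layout()
    glen <- lay$gene_length
    root <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")
    prim <- siseq_primers()
    inst <- vapply(prim$sequence, instantiate_primer, character(1))
    names(inst) <- prim$name
    put <- function(seq, at, frag) {
      substr(seq, at[1] + 1, at[2]) <- frag
      seq
    }
    root <- put(root, lay$v5_primer, inst[["V5"]])
    root <- put(root, lay$v6a_primer, inst[["V6a"]])
    root <- put(root, lay$v6b_primer, revcomp(inst[["V6b"]]))
    root <- put(root, lay$v7_primer, revcomp(inst[["V7"]]))

    windows <- c(lay$extra_variable,
                 list(lay$v5_seg, c(lay$v6a_seg[1], lay$v6b_primer[1]),
                      lay$v7_seg))
    var_pos <- unlist(lapply(windows, function(w) seq(w[1] + 1, w[2])))
    n_between <- round(between_genus_divergence / 2 * length(var_pos))
    n_within <- round(within_genus_divergence / 2 * length(var_pos))

    out <- vector("list", n_genera * species_per_genus)
    i <- 0
    for (g in seq_len(n_genera)) {
      anc <- mutate_positions(root, sample(var_pos, n_between))
      lineage <- paste(
        "Bacteria",
        sprintf("Phylum_%d", (g - 1) %/% 4 + 1),
        sprintf("Class_%d", (g - 1) %/% 2 + 1),
        sprintf("Order_%d", g),
        sprintf("Family_%d", g),
        sprintf("Genus_%d", g),
        sep = ";")
      for (s in seq_len(species_per_genus)) {
        i <- i + 1
        out[[i]] <- tibble::tibble(
          id = sprintf("G%02d_S%02d", g, s),
          lineage = lineage,
          sequence = mutate_positions(anc, sample(var_pos, n_within))
        )
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Define a mock community
#'
#' Expected template proportions are corrected for rRNA operon copy number:
#' the expected fraction of taxon i is
#' (mass_i * operons_i / genome_i) / sum_j (mass_j * operons_j / genome_j).
#'
#' @param taxon reference record ids.
#' @param mass_pg genomic DNA mass per taxon (pg).
#' @param rrna_operons rRNA operon count per genome.
#' @param genome_bp genome size (bp).
#' @return tibble of class `siseq_mock_community`.
#' @export
mock_community <- function(taxon, mass_pg, rrna_operons, genome_bp) {
  if (length(taxon) == 0) abort("empty community")
  if (any(mass_pg <= 0) || any(rrna_operons < 1) || any(genome_bp <= 0)) {
    abort("masses and genome sizes must be positive; operons >= 1")
  }
  out <- tibble::tibble(taxon = taxon, mass_pg = mass_pg,
                        rrna_operons = rrna_operons, genome_bp = genome_bp)
  class(out) <- c("siseq_mock_community", class(out))
  out
}

#' Expected template proportions of a mock community
#'
#' @param community a [mock_community()] tibble.
#' @return tibble with columns `taxon`, `expected`.
#' @export
expected_proportions <- function(community) {
  if (nrow(community) == 0) abort("empty community")
  w <- community$mass_pg * community$rrna_operons / community$genome_bp
  tibble::tibble(taxon = community$taxon, expected = w / sum(w))
}

#' Default five-taxon validation community
#'
#' Five taxa from five different genera of a fixture database, with genomic
#' DNA masses in 10-fold steps spanning five orders of magnitude (lowest
#' 1.2 pg) and identical operon counts and genome sizes, so the expected
#' template proportions are exact 10-fold steps.
#'
#' @param records fixture reference tibble (or structured reference).
#' @return a [mock_community()] tibble.
#' @export
default_mock_community <- function(records) {
  if (inherits(records, "siseq_structured_ref")) records <- tidy(records)
  gen <- sub("^.*;", "", records$lineage)
  pick <- records |>
    dplyr::mutate(genus = gen) |>
    dplyr::distinct(.data$genus, .keep_all = TRUE) |>
    dplyr::slice_head(n = 5)
  if (nrow(pick) < 5) abort("need at least 5 genera in the fixture database")
  mock_community(taxon = pick$id,
                 mass_pg = 1.2e4 / 10^(0:4),
                 rrna_operons = rep(4, 5),
                 genome_bp = rep(4e6, 5))
}

#' Substitution-only sequencing error model
#'
#' Per-cycle mean Phred is `q_high` for cycles 1..`plateau` of each 36-cycle
#' sequencing step, declining linearly to `q_low` by the final cycle, with
#' Gaussian jitter `q_sd` clamped to \[2, 41\]. If `substitution_rate` is
#' NULL (the default), the per-base substitution probability is derived
#' from the emitted Phred score (10^(-Q/10)); otherwise the flat rate is
#' used at every base.
#'
#' @param substitution_rate flat per-base substitution probability, or NULL.
#' @param q_high,q_low,plateau,q_sd quality profile parameters.
#' @return list of class `siseq_error_model`.
#' @export
error_model <- function(substitution_rate = NULL, q_high = 38, q_low = 30,
                        plateau = 18, q_sd = 3) {
  if (!is.null(substitution_rate) &&
      (substitution_rate < 0 || substitution_rate > 1)) {
    abort("substitution_rate must lie in [0, 1]")
  }
  structure(list(substitution_rate = substitution_rate, q_high = q_high,
                 q_low = q_low, plateau = plateau, q_sd = q_sd),
            class = "siseq_error_model")
}

# mean Phred per cycle of one sequencing step of `n_cycles`
quality_profile <- function(em, n_cycles) {
  cyc <- seq_len(n_cycles)
  ifelse(cyc <= em$plateau, em$q_high,
         em$q_high + (em$q_low - em$q_high) *
           (cyc - em$plateau) / max(n_cycles - em$plateau, 1))
}

draw_qualities <- function(em, profile, n) {
  q <- matrix(stats::rnorm(n * length(profile), mean = rep(profile, each = n),
                           sd = em$q_sd), nrow = n)
  q <- round(q)
  q[q < 2] <- 2L
  q[q > 41] <- 41L
  q
}

qual_to_string <- function(q) {
  # q: integer matrix n x L -> Sanger-encoded strings
  ch <- matrix(intToUtf8(t(q) + 33L, multiple = TRUE),
               nrow = nrow(q), byrow = TRUE)
  do.call(paste0, as.data.frame(ch, stringsAsFactors = FALSE))
}

apply_substitutions <- function(seqs, q, em) {
  p <- if (is.null(em$substitution_rate)) 10^(-q / 10) else em$substitution_rate
  hit <- which(matrix(stats::runif(length(q)), nrow = nrow(q)) < p,
               arr.ind = TRUE)
  if (nrow(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    for (k in seq_len(nrow(hit))) {
      i <- hit[k, 1]; j <- hit[k, 2]
      old <- substr(seqs[i], j, j)
      substr(seqs[i], j, j) <- sample(setdiff(bases, old), 1)
    }
  }
  seqs
}

#' Simulate serial structured read pairs
#'
#' Templates are drawn from the structured reference in proportion to the
#' community's operon-corrected expected proportions (or from a single
#' taxon); each template binds the flowcell in either orientation with
#' probability 0.5. Mate 1 carries the 8-nt barcode of the end it reads
#' from, followed by two `segment_length`-nt segments: barcode1::V5::V6a
#' and barcode2::V7::V6b when the template is V5-first, swapped otherwise.
#' Substitution errors and Phred qualities follow the error model.
#'
#' @param sref structured reference (`layout = "siseq"`).
#' @param community a [mock_community()] tibble, or NULL.
#' @param taxa single taxon id (used when `community` is NULL).
#' @param n_reads number of read pairs.
#' @param em an [error_model()].
#' @param sample_id,barcode1,barcode2 sample label and its 8-mer barcode
#'   pair (barcode1 on the V5 end, barcode2 on the V7 end).
#' @param seed RNG seed (required).
#' @return tibble with one row per read pair: `read_id`, `sample_id`,
#'   `taxon`, `orientation` (truth), `mate1_seq`, `mate1_qual`,
#'   `mate2_seq`, `mate2_qual`. The truth columns (`taxon`, `orientation`,
#'   `sample_id`) form the truth table.
#' @export
simulate_reads <- function(sref, community = NULL, taxa = NULL,
                           n_reads, em = error_model(),
                           sample_id = "S1",
                           barcode1 = "ACGTACGT", barcode2 = "TGCATGCA",
                           seed) {
  if (n_reads <= 0) abort("n_reads must be positive")
  recs <- tidy(sref)
  L <- sref$segment_length
  if (is.null(community)) {
    if (is.null(taxa)) abort("supply a community or a taxon id")
    props <- tibble::tibble(taxon = taxa, expected = 1)
  } else {
    props <- expected_proportions(community)
  }
  miss <- setdiff(props$taxon, recs$id)
  if (length(miss) > 0) {
    abort(sprintf("taxa absent from structured reference: %s",
                  paste(miss, collapse = ", ")))
  }
  idx <- base::match(props$taxon, recs$id)
  half1 <- substr(recs$sequence[idx], 1, 2 * L)            # V5::V6a
  half2 <- substr(recs$sequence[idx], 2 * L + 1, 4 * L)    # V7::V6b
  if (nchar(barcode1) != 8 || nchar(barcode2) != 8) {
    abort("barcodes must be 8-mers")
  }
  with_seed(seed, {
    t_i <- sample.int(nrow(props), n_reads, replace = TRUE,
                      prob = props$expected)
    v5_first <- stats::runif(n_reads) < 0.5
    m1 <- paste0(ifelse(v5_first, barcode1, barcode2),
                 ifelse(v5_first, half1[t_i], half2[t_i]))
    m2 <- paste0(ifelse(v5_first, barcode2, barcode1),
                 ifelse(v5_first, half2[t_i], half1[t_i]))
    prof <- c(rep(em$q_high, 8), quality_profile(em, L), quality_profile(em, L))
    q1 <- draw_qualities(em, prof, n_reads)
    q2 <- draw_qualities(em, prof, n_reads)
    m1 <- apply_substitutions(m1, q1, em)
    m2 <- apply_substitutions(m2, q2, em)
    tibble::tibble(
      read_id = sprintf("%s_%07d", sample_id, seq_len(n_reads)),
      sample_id = sample_id,
      taxon = props$taxon[t_i],
      orientation = ifelse(v5_first, "V5-first", "V7-first"),
      mate1_seq = m1, mate1_qual = qual_to_string(q1),
      mate2_seq = m2, mate2_qual = qual_to_string(q2)
    )
  })
}

#' Simulate error-free reads for alternative platform layouts
#'
#' Produces layout-faithful, error-free fragments for genus-assignability
#' experiments: 454-style reads start at the 5' end of the aligned V5
#' primer; paired-end reads join the V5 and V7 windows (each `read_length`
#' nt, 5'-anchored at the primers).
#'
#' @param records full-length reference tibble.
#' @param primers primer tibble.
#' @param layout `"platform454"` or `"paired_end"`.
#' @param read_length read length in nt (per mate for paired-end).
#' @return tibble with columns `read_id`, `taxon`, `lineage`, `sequence`.
#' @export
simulate_platform_reads <- function(records, primers = siseq_primers(),
                                    layout = c("platform454", "paired_end"),
                                    read_length = 400) {
  layout <- match.arg(layout)
  sref <- build_structured_db(records, primers, layout = layout,
                              segment_length = read_length)
  recs <- tidy(sref)
  tibble::tibble(read_id = paste0(layout, "_", recs$id), taxon = recs$id,
                 lineage = recs$lineage, sequence = recs$sequence)
}
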
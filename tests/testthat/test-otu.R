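test_that("pairwise identity matches closed-form arithmetic", {
  s <- tidy(fx_sref())$sequence[1]
  expect_equal(seq_identity(s, s), 1.0)
  s18 <- mutate_k(s, 18, seed = 110)
  expect_equal(seq_identity(s, s18), (144 - 18) / 144)
  # identical-sequence genus
  recs <- tibble::tibble(id = c("x1", "x2"),
                         lineage = "B;P;C;O;F;GX",
                         sequence = c(s, s))
  sref <- structure(list(records = recs, layout = "siseq",
                         segment_length = 36, report = NULL),
                    class = "siseq_structured_ref")
  expect_equal(mean_within_genus_identity(sref, "GX"), 1.0)
  expect_error(mean_within_genus_identity(fx_sref(), "NoSuchGenus"), ">= 2")
})

test_that("fixture genera built at 11% divergence show ~89% within-genus identity", {
  expect_equal(mean_within_genus_identity(fx_sref(), "Genus_1"), 0.89,
               tolerance = 0.03)
})

test_that("greedy clustering obeys the identity cutoff on constructed pairs", {
  s <- tidy(fx_sref())$sequence[1]
  far <- mutate_k(s, 29, seed = 111)   # identity 115/144 = 0.799
  near <- mutate_k(s, 7, seed = 112)   # identity 137/144 = 0.951
  cl2 <- cluster_otus(c(rep(s, 5), rep(far, 3)), identity_cutoff = 0.87)
  expect_equal(nrow(tidy(cl2)), 2)
  cl1 <- cluster_otus(c(rep(s, 5), rep(near, 3)), identity_cutoff = 0.87)
  expect_equal(nrow(tidy(cl1)), 1)
  expect_equal(tidy(cl1)$size, 8)
  # n identical reads -> one cluster of size n
  cid <- cluster_otus(rep(s, 17))
  expect_equal(tidy(cid)$size, 17)
  expect_equal(nrow(cluster_otus(character(0))$clusters), 0)
})

test_that("clustering partitions the reads and matches a brute-force oracle", {
  sref <- fx_sref()
  pairs <- simulate_reads(sref, community = default_mock_community(sref),
                          n_reads = 200,
                          em = error_model(substitution_rate = 0.02),
                          seed = 113)
  ori <- resolve_orientation(pairs, sref)
  reads <- ori[c("read_id", "sequence")]
  prev <- Inf
  for (cut in c(0.97, 0.93, 0.87, 0.80)) {
    cl <- cluster_otus(reads, identity_cutoff = cut)
    # partition: every read in exactly one cluster
    expect_equal(sort(cl$membership$read_id), sort(reads$read_id))
    expect_equal(sum(tidy(cl)$size), nrow(reads))
    # oracle: same dereplication order, independent identity + first-fit
    derep <- reads |>
      dplyr::count(sequence, name = "abundance") |>
      dplyr::arrange(dplyr::desc(abundance), sequence)
    orc <- oracle_cluster(derep$sequence, cut)
    expect_equal(length(unique(orc)), nrow(tidy(cl)))
    # identical partitions of the unique sequences
    m <- dplyr::left_join(cl$membership, reads, by = "read_id")
    got <- m$otu[base::match(derep$sequence, m$sequence)]
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(orc, levels = unique(orc))))
    # cutoff monotonicity: clusters non-increasing as the cutoff decreases
    expect_lte(nrow(tidy(cl)), prev)
    prev <- nrow(tidy(cl))
  }
})

test_that("every candidate cutoff recapitulates an error-free single-species control", {
  sref <- fx_sref()
  clf <- fx_clf()
  pairs <- simulate_reads(sref, taxa = "G01_S01", n_reads = 500,
                          em = error_model(substitution_rate = 0), seed = 114)
  ori <- resolve_orientation(pairs, sref)
  anchor <- mean_within_genus_identity(sref, "Genus_1")
  cal <- calibrate_cutoff(ori[c("read_id", "sequence")], clf,
                          fx_lineage("G01_S01"), anchor, seed = 115)
  sw <- tidy(cal)
  expect_true(all(sw$n_clusters == 1))
  expect_true(all(sw$fp_fraction == 0))
  # tie-break lands on the candidate nearest the within-genus identity
  expect_equal(cal$chosen, sw$cutoff[which.min(abs(sw$cutoff - anchor))])
  expect_equal(cal$chosen, 0.87)
})

test_that("a 1% substitution control still calibrates to the 0.87 cutoff", {
  sref <- fx_sref()
  pairs <- simulate_reads(sref, taxa = "G01_S01", n_reads = 1000,
                          em = error_model(substitution_rate = 0.01),
                          seed = 116)
  ori <- resolve_orientation(pairs, sref)
  anchor <- mean_within_genus_identity(sref, "Genus_1")
  cal <- calibrate_cutoff(ori[c("read_id", "sequence")], fx_clf(),
                          fx_lineage("G01_S01"), anchor, seed = 117)
  expect_equal(cal$chosen, 0.87)
})

test_that("planted foreign-genus contamination surfaces as false-positive fraction", {
  sref <- fx_sref()
  own <- simulate_reads(sref, taxa = "G01_S01", n_reads = 950,
                        em = error_model(substitution_rate = 0), seed = 118)
  foreign <- simulate_reads(sref, taxa = "G05_S01", n_reads = 50,
                            em = error_model(substitution_rate = 0), seed = 119)
  reads <- resolve_orientation(dplyr::bind_rows(own, foreign),
                               sref)[c("read_id", "sequence")]
  anchor <- mean_within_genus_identity(sref, "Genus_1")
  cal <- calibrate_cutoff(reads, fx_clf(), fx_lineage("G01_S01"), anchor,
                          seed = 120)
  expect_true(all(abs(tidy(cal)$fp_fraction - 0.05) < 0.01))
})

test_that("the abundance threshold removes only sub-threshold OTUs", {
  expect_equal(abundance_threshold(3e-4), 3e-4)
  expect_error(abundance_threshold(1.2), "rate")
  tbl <- tibble::tibble(otu = c("OTU_0001", "OTU_0002", "OTU_0003"),
                        rep_centroid = c("A", "B", "C"),
                        S1 = c(9998L, 1L, 1L), S2 = c(100L, 50L, 0L))
  class(tbl) <- c("siseq_otu_table", class(tbl))
  attr(tbl, "provenance") <- list(identity_cutoff = 0.87)
  out <- apply_abundance_threshold(tbl, 3e-4)
  # OTU_0002: 1/10000 = 1e-4 < 3e-4 in S1, but 50/150 in S2 -> kept in S2 only
  expect_equal(out$S1[out$otu == "OTU_0002"], 0L)
  expect_equal(out$S2[out$otu == "OTU_0002"], 50L)
  # OTU_0003 falls below threshold everywhere -> dropped
  expect_false("OTU_0003" %in% out$otu)
  expect_equal(attr(out, "provenance")$abundance_threshold, 3e-4)
  # zero threshold leaves the table unchanged
  same <- apply_abundance_threshold(tbl, 0)
  expect_equal(same$S1, tbl$S1)
})

test_that("OTU tables sum to retained reads and match OTUs across samples", {
  sref <- fx_sref()
  clf <- fx_clf()
  cm <- default_mock_community(sref)
  mk_sample <- function(s, seed) {
    pairs <- simulate_reads(sref, community = cm, n_reads = 2000,
                            seed = seed, sample_id = s)
    cluster_otus(resolve_orientation(pairs, sref)[c("read_id", "sequence")])
  }
  clusters <- list(A = mk_sample("A", 121), B = mk_sample("B", 122))
  tab <- build_otu_table(clusters, clf, seed = 123)
  expect_equal(sum(tab$A), 2000)
  expect_equal(sum(tab$B), 2000)
  # dominant taxon present in both samples as a shared OTU
  dom <- tab[which.max(tab$A), ]
  expect_gt(dom$B, 0)
  expect_match(dom$taxonomy, "Genus_1")
  # deep sampling: one dominant OTU per detectable input taxon
  expect_gte(nrow(tab), 3)
  expect_true(all(colSums(otu_matrix(tab)) >= 0))
})
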
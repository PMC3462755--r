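test_that("smoothed word probabilities match hand arithmetic on a tiny model", {
  recs <- tibble::tibble(
    id = c("a1", "a2", "b1"),
    lineage = c("Bacteria;P1;C1;O1;F1;GA", "Bacteria;P1;C1;O1;F1;GA",
                "Bacteria;P1;C1;O2;F2;GB"),
    sequence = c("ACGTA", "ACGGA", "TTTTT"))
  clf <- train_classifier(recs, word_size = 3)
  # independent enumeration of distinct 3-mers per sequence
  words <- function(s) unique(substring(s, 1:(nchar(s) - 2), 3:nchar(s)))
  code <- function(w) {
    b <- c(A = 0, C = 1, G = 2, T = 3)[strsplit(w, "")[[1]]]
    sum(b * 4^(2:0)) + 1
  }
  all_seqs <- recs$sequence
  genus_of <- c(1, 1, 2)
  N <- 3
  for (w in c("ACG", "CGT", "TTT", "AAA")) {
    n_w <- sum(vapply(all_seqs, function(s) w %in% words(s), logical(1)))
    prior <- (n_w + 0.5) / (N + 1)
    for (g in 1:2) {
      n_gw <- sum(vapply(all_seqs[genus_of == g],
                         function(s) w %in% words(s), logical(1)))
      N_g <- sum(genus_of == g)
      expect_equal(clf$logp[code(w), g],
                   log((n_gw + 0.5 * prior) / (N_g + 1)))
    }
  }
  expect_error(train_classifier(recs, word_size = 8), "shortest")
})

test_that("training is deterministic and a single-genus model accepts everything", {
  expect_identical(train_classifier(fx_sref()), train_classifier(fx_sref()))
  db1 <- fx_db()[1:5, ] # one genus
  clf1 <- train_classifier(build_structured_db(db1))
  cl <- classify_reads(clf1, random_seq(10, seed = 90), seed = 91)
  expect_true(all(cl$results$top_genus == "Genus_1"))
  expect_true(all(cl$results$support_genus == 1))
})

test_that("training sequences classify to their own genus with full support", {
  clf <- fx_clf()
  recs <- tidy(fx_sref())
  pick <- recs[c(1, 11, 21, 31), ]
  cl <- classify_reads(clf, pick$sequence, seed = 92)
  truth <- sub("^.*;", "", pick$lineage)
  expect_equal(cl$results$top_genus, truth)
  expect_true(all(cl$results$support_genus == 1))
})

test_that("bootstrap supports are reproducible for a fixed seed", {
  clf <- fx_clf()
  q <- random_seq(5, seed = 93)
  a <- classify_reads(clf, q, seed = 94)
  b <- classify_reads(clf, q, seed = 94)
  expect_identical(a$results, b$results)
})

test_that("random queries against two balanced genera get no confident genus call", {
  two <- fx_db()[fx_db()$lineage %in% unique(fx_db()$lineage)[1:2], ]
  clf2 <- train_classifier(build_structured_db(two))
  cl <- classify_reads(clf2, random_seq(60, seed = 95), seed = 96)
  # label symmetry: top genus split is binomial(n, 0.5)
  n1 <- sum(cl$results$top_genus == "Genus_1")
  expect_lt(abs(n1 - 30), 3 * sqrt(60 * 0.25))
  # confidence is far below that of genuine reads
  expect_lt(mean(cl$results$support_genus > 0.8), 0.9)
  expect_lt(mean(cl$results$support_genus), 0.9)
})

test_that("acceptance picks the deepest rank meeting the threshold", {
  mk <- function(sup) {
    res <- tibble::tibble(read_id = "r", top_genus = "Genus_1")
    ranks <- c("domain", "phylum", "class", "order", "family", "genus")
    for (k in seq_along(ranks)) {
      res[[paste0("label_", ranks[k])]] <- paste0("L", k)
      res[[paste0("support_", ranks[k])]] <- sup[k]
    }
    structure(list(results = res, n_boot = 100),
              class = "siseq_classification")
  }
  a <- assign_taxonomy(mk(c(1, 1, 1, 0.99, 0.95, 0.95)), 0.8, ">")
  expect_equal(a$accepted_rank, "genus")
  b <- assign_taxonomy(mk(c(1, 1, 1, 0.95, 0.9, 0.6)), 0.8, ">")
  expect_equal(b$accepted_rank, "family")
  expect_true(is.na(b$label_genus))
  expect_equal(b$label_family, "L5")
  # boundary: exactly 0.7 accepted under >=, rejected under >
  c1 <- assign_taxonomy(mk(c(1, 1, 1, 1, 1, 0.7)), 0.7, ">=")
  expect_equal(c1$accepted_rank, "genus")
  c2 <- assign_taxonomy(mk(c(1, 1, 1, 1, 1, 0.7)), 0.7, ">")
  expect_equal(c2$accepted_rank, "family")
  d <- assign_taxonomy(mk(rep(0.5, 6)), 0.8, ">")
  expect_true(is.na(d$accepted_rank))
  expect_equal(d$accepted_depth, 0L)
})

test_that("rolled-up supports are monotone non-increasing with rank depth", {
  clf <- fx_clf()
  pairs <- simulate_reads(fx_sref(), community = default_mock_community(fx_sref()),
                          n_reads = 300,
                          em = error_model(substitution_rate = 0.05), seed = 97)
  ori <- resolve_orientation(pairs, fx_sref())
  cl <- classify_reads(clf, ori[c("read_id", "sequence")], seed = 98)
  sup <- as.matrix(cl$results[paste0("support_",
                                     c("domain", "phylum", "class",
                                       "order", "family", "genus"))])
  expect_true(all(diff(t(sup)) <= 1e-12))
})

test_that("all-N queries are unclassified at every rank", {
  cl <- classify_reads(fx_clf(), strrep("N", 144), seed = 99)
  expect_true(is.na(cl$results$top_genus))
  expect_true(is.na(cl$results$support_genus))
  asg <- assign_taxonomy(cl, 0.8, ">")
  expect_equal(asg$accepted_depth, 0L)
})

test_that("permuting genus labels permutes classifications identically", {
  db <- fx_db()
  swapped <- db
  swapped$lineage <- sub("Genus_1$", "Genus_TMP", swapped$lineage)
  swapped$lineage <- sub("Genus_2$", "Genus_1", swapped$lineage)
  swapped$lineage <- sub("Genus_TMP$", "Genus_2", swapped$lineage)
  clf_a <- train_classifier(build_structured_db(db))
  clf_b <- train_classifier(build_structured_db(swapped))
  q <- tidy(fx_sref())$sequence[c(1, 6, 21)]
  ra <- classify_reads(clf_a, q, seed = 100)$results
  rb <- classify_reads(clf_b, q, seed = 100)$results
  relabel <- function(x) {
    ifelse(x == "Genus_1", "Genus_2", ifelse(x == "Genus_2", "Genus_1", x))
  }
  expect_equal(relabel(ra$top_genus), rb$top_genus)
  expect_equal(ra$support_genus, rb$support_genus)
})

test_that("structure-matched training beats full-length training on structured reads", {
  db <- fx_db()
  sref <- fx_sref()
  clf_m <- fx_clf()
  clf_fl <- train_classifier(build_structured_db(db, layout = "full_length"))
  pairs <- simulate_reads(sref, taxa = "G01_S01", n_reads = 600,
                          em = error_model(substitution_rate = 0.05), seed = 101)
  ori <- resolve_orientation(pairs, sref)
  reads <- ori[ori$oriented, c("read_id", "sequence")]
  cl_m <- classify_reads(clf_m, reads, seed = 102)
  cl_fl <- classify_reads(clf_fl, reads, seed = 102)
  acc <- function(cl) {
    mean(assign_taxonomy(cl, 0.8, ">")$accepted_rank == "genus", na.rm = FALSE)
  }
  expect_gt(acc(cl_m), acc(cl_fl))
  expect_gt(mean(cl_m$results$support_genus),
            mean(cl_fl$results$support_genus))
})

test_that("misclassification counting follows the conflict definition", {
  mk_asg <- function(genus, depth = 6L) {
    tibble::tibble(read_id = paste0("r", seq_along(genus)),
                   accepted_rank = ifelse(depth > 0, "genus", NA),
                   accepted_depth = depth,
                   label_domain = "Bacteria", label_phylum = "Phylum_1",
                   label_class = "Class_1", label_order = "Order_1",
                   label_family = "Family_1", label_genus = genus)
  }
  truth <- "Bacteria;Phylum_1;Class_1;Order_1;Family_1;Genus_1"
  all_ok <- misclassification_rate(mk_asg(rep("Genus_1", 3000)), truth)
  expect_equal(all_ok$rate, 0)
  one_bad <- misclassification_rate(
    mk_asg(c(rep("Genus_1", 2999), "Genus_2")), truth)
  expect_equal(one_bad$rate, 1 / 3000, tolerance = 1e-12)
  none <- misclassification_rate(mk_asg(character(0), integer(0)), truth)
  expect_true(is.na(none$rate))
})

test_that("genus assignability rises with read length on the same fixture", {
  db <- fx_db()
  long <- build_structured_db(db, segment_length = 36)
  short <- build_structured_db(db, segment_length = 9)
  q_long <- tidy(long)[c("id", "sequence")]
  q_short <- tidy(short)[c("id", "sequence")]
  names(q_long)[1] <- names(q_short)[1] <- "read_id"
  ga_long <- genus_assignability(train_classifier(long), q_long, seed = 103)
  ga_short <- genus_assignability(train_classifier(short, word_size = 8),
                                  q_short, seed = 104)
  expect_gte(ga_long$fraction_genus, ga_short$fraction_genus)
  expect_equal(ga_long$fraction_genus, 1.0)
  expect_error(genus_assignability(fx_clf(), character(0), seed = 1), "empty")
})
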
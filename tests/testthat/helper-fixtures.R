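# Shared fixtures, built once per test run (all data is generated in code).
.fx <- new.env(parent = emptyenv())

fx_db <- function() {
  if (is.null(.fx$db)) .fx$db <- generate_fixture_db(seed = 1)
  .fx$db
}

fx_sref <- function() {
  if (is.null(.fx$sref)) .fx$sref <- build_structured_db(fx_db())
  .fx$sref
}

fx_clf <- function() {
  if (is.null(.fx$clf)) .fx$clf <- train_classifier(fx_sref())
  .fx$clf
}

fx_barcodes <- function() {
  barcode_map(c("S1", "S2"),
              c("ACGTACGT", "GGTTAACC"),
              c("TGCATGCA", "CCAATTGG"))
}

fx_lineage <- function(id) {
  db <- fx_db()
  db$lineage[db$id == id][1]
}

# independent ungapped identity (R implementation, used as oracle)
oracle_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- min(length(ca), length(cb))
  sum(ca[seq_len(n)] == cb[seq_len(n)]) / max(length(ca), length(cb))
}

# independent first-fit greedy clustering over pre-ordered sequences
oracle_cluster <- function(seqs, cutoff) {
  centroids <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (c in seq_along(centroids)) {
      if (oracle_identity(seqs[i], seqs[centroids[c]]) >= cutoff) {
        hit <- c
        break
      }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      hit <- length(centroids)
    }
    assign[i] <- hit
  }
  assign
}

# mutate exactly k positions of a sequence (to a different base)
mutate_k <- function(seq, k, seed) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

random_seq <- function(n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 144, replace = TRUE), collapse = "")
  }, character(1))
}
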
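recs <- function(...) {
  x <- c(...)
  Biostrings::AAStringSet(x)
}

test_that("keyword harvest is case-insensitive substring matching", {
  r <- recs(c("p1 putative sterol Esterase" = "MAAA",
              "p2 kinase" = "MCCC",
              "p3 TRIACYLGLYCEROL LIPASE precursor" = "MDDD"))
  kept <- keyword_harvest(r)
  expect_identical(sub("\\s.*$", "", names(kept)), c("p1", "p3"))
  expect_error(keyword_harvest(r, screen_config(keywords = character(0))),
               "empty")
})

test_that("keyword harvest matches an independent header scan on synthetic data", {
  pr <- generate_proteome(proteome_spec(n_background = 200L, n_planted = 0L,
                                        keyword_fraction = 0.3, seed = 21L))
  kept <- keyword_harvest(pr$records)
  byhand <- sum(grepl("esterase|lipase", tolower(names(pr$records))))
  expect_identical(length(kept), byhand)
  expect_identical(length(kept), sum(pr$truth$has_keyword))
})

test_that("deduplicate keeps first occurrences and reports a mapping", {
  r <- recs(c("a first" = "MSEQA", "b dup-of-a" = "MSEQA", "c other" = "MSEQC"))
  out <- deduplicate(r)
  expect_identical(sub("\\s.*$", "", names(out)), c("a", "c"))
  expect_identical(attr(out, "removed"),
                   data.frame(removed_id = "b", kept_id = "a",
                              stringsAsFactors = FALSE))
  # identity on unique input
  u <- recs(c(x = "MA", y = "MC"))
  expect_identical(as.character(deduplicate(u)), as.character(u))
})

test_that("deduplicate agrees with a hash-set oracle on planted duplicates", {
  set.seed(33)
  base <- vapply(1:460, function(i) rand_seq(80), character(1))
  dups <- sample(base, 40, replace = TRUE)
  all <- sample(c(base, dups))
  names(all) <- sprintf("s%03d", seq_along(all))
  out <- deduplicate(recs(all))
  expect_identical(length(out), length(unique(all)))
})

test_that("motif filter requires every motif and records exact positions", {
  r <- recs(c("hit both" = "AAGESAGAAGGGFAA",
              "only shoulder" = "AAGESAGAA",
              "only ox" = "AAGGGFAA"))
  res <- motif_filter(r)
  expect_identical(sub("\\s.*$", "", names(res$records)), "hit")
  expect_identical(res$hits$pos[res$hits$motif == "GESAG"], 3L)
  expect_identical(res$hits$pos[res$hits$motif == "GGGF"], 10L)
  any_cfg <- screen_config(require_all_motifs = FALSE)
  expect_identical(length(motif_filter(r, any_cfg)$records), 3L)
})

test_that("overlapping motif occurrences are all recorded", {
  r <- recs(c(ov = "GGGGFGGGF"))
  res <- motif_filter(r, screen_config(motifs = "GGGF",
                                       require_all_motifs = TRUE))
  expect_identical(sort(res$hits$pos), c(2L, 6L))
})

test_that("re-extracting reported positions reproduces the motif exactly", {
  pr <- generate_proteome(proteome_spec(n_background = 120L, n_planted = 5L,
                                        seed = 14L))
  res <- motif_filter(pr$records)
  seqs <- setNames(as.character(pr$records), sub("\\s.*$", "", names(pr$records)))
  for (k in seq_len(nrow(res$hits))) {
    h <- res$hits[k, ]
    expect_identical(substr(seqs[[h$id]], h$pos, h$pos + nchar(h$motif) - 1L),
                     h$motif)
  }
})

test_that("filter chain is idempotent and order-invariant", {
  pr <- generate_proteome(proteome_spec(n_background = 80L, n_planted = 4L,
                                        seed = 3L))
  res <- motif_filter(pr$records)
  res2 <- motif_filter(res$records)
  expect_identical(as.character(res2$records), as.character(res$records))
  expect_identical(res2$hits, res$hits)
  kw <- keyword_harvest(pr$records)
  expect_identical(names(keyword_harvest(kw)), names(kw))
  # reorder records: same survivor set
  perm <- sample(length(pr$records))
  resp <- motif_filter(pr$records[perm])
  expect_setequal(sub("\\s.*$", "", names(resp$records)),
                  sub("\\s.*$", "", names(res$records)))
})

test_that("screen tallies are monotone along the chain", {
  pr <- generate_proteome(proteome_spec(n_background = 150L, n_planted = 6L,
                                        seed = 8L))
  res <- screen_proteome(pr$records)
  t <- res$tallies[!is.na(res$tallies)]
  expect_true(all(diff(t) <= 0))
  expect_identical(unname(res$tallies[["scanned"]]), 156L)
})

test_that("both dedup orders are available via config", {
  r <- recs(c("a lipase" = "GESAGGGGF", "b lipase" = "GESAGGGGF"))
  first <- screen_proteome(r, screen_config(dedup_first = TRUE))
  last <- screen_proteome(r, screen_config(dedup_first = FALSE))
  expect_identical(length(first$records), 1L)
  expect_identical(length(last$records), 1L)
})

test_that("screen TSV export has one row per surviving hit", {
  pr <- generate_proteome(proteome_spec(n_background = 20L, n_planted = 2L,
                                        seed = 2L))
  res <- screen_proteome(pr$records)
  f <- tempfile(fileext = ".tsv")
  write_screen_tsv(res, f)
  tab <- read.delim(f)
  expect_identical(nrow(tab), nrow(res$hits))
  expect_named(tab, c("id", "genome", "motif", "position"))
})
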
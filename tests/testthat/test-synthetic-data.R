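test_that("proteome spec validates its invariants", {
  expect_s3_class(proteome_spec(), "proteome_spec")
  expect_error(proteome_spec(length_range = c(40, 100)), "60")
  expect_error(proteome_spec(background_freqs = rep(0.05, 19)), "20 entries")
  bad <- rep(0.05, 20); bad[1] <- 0.06
  expect_error(proteome_spec(background_freqs = bad), "sum to 1")
  expect_error(proteome_spec(keyword_fraction = 1.2), "keyword_fraction")
})

test_that("planted candidate constraints are enforced with field names", {
  expect_error(planted_candidate(oxyanion_pos = 300, shoulder_pos = 222),
               "oxyanion_pos")
  expect_error(planted_candidate(cys_positions = c(112, 75)),
               "cys_positions")
  # lid span 5 residues cannot host 6 hydrophobics (pigeonhole)
  expect_error(planted_candidate(cys_positions = c(75, 81),
                                 lid_hydrophobic_count = 6),
               "lid_hydrophobic_count")
  # GESAG overlapping the His position
  expect_error(planted_candidate(shoulder_pos = 222, triad_his_pos = 224),
               "overlap")
})

test_that("planted records carry every feature exactly as specified", {
  p <- planted_candidate(shoulder_pos = 200L, oxyanion_pos = 120L,
                         cys_positions = c(60L, 95L),
                         lid_hydrophobic_count = 9L,
                         triad_glu_pos = 320L, triad_his_pos = 420L,
                         sequon_count = 2L)
  pr <- generate_proteome(proteome_spec(n_background = 0L, n_planted = 1L,
                                        seed = 11L), list(p))
  s <- as.character(pr$records)[[1]]
  expect_identical(substr(s, 200, 204), "GESAG")
  expect_identical(substr(s, 120, 123), "GGGF")
  expect_identical(substr(s, 60, 60), "C")
  expect_identical(substr(s, 95, 95), "C")
  expect_identical(substr(s, 320, 320), "E")
  expect_identical(substr(s, 420, 420), "H")
  lid <- strsplit(substr(s, 61, 94), "")[[1]]
  expect_identical(sum(lid %in% hydrophobic_set()), 9L)
  expect_identical(find_sequons(s), pr$sequons[[1]])
  expect_length(find_sequons(s), 2L)
})

test_that("ground-truth collisions come from an independent scan", {
  pr <- generate_proteome(proteome_spec(n_background = 100L, n_planted = 7L,
                                        seed = 5L))
  seqs <- as.character(pr$records)
  ids <- sub("\\s.*$", "", names(pr$records))
  for (m in c("GESAG", "GGGF")) {
    byhand <- unlist(lapply(seq_along(seqs), function(i) {
      length(scan_positions(seqs[i], m))
    }))
    tabled <- vapply(ids, function(id) {
      sum(pr$hits$id == id & pr$hits$motif == m)
    }, integer(1))
    expect_identical(unname(tabled), byhand)
  }
  both <- vapply(ids, function(id) {
    all(c("GESAG", "GGGF") %in% pr$hits$motif[pr$hits$id == id])
  }, logical(1))
  expect_identical(pr$truth$collision, unname(both) & !pr$truth$planted)
})

test_that("regeneration with the same seed is byte-identical", {
  a <- generate_proteome(proteome_spec(n_background = 30L, n_planted = 2L,
                                       seed = 42L))
  b <- generate_proteome(proteome_spec(n_background = 30L, n_planted = 2L,
                                       seed = 42L))
  expect_identical(as.character(a$records), as.character(b$records))
  expect_identical(a$truth, b$truth)
  s1 <- generate_structure(toy_structure_spec(seed = 8L))
  s2 <- generate_structure(toy_structure_spec(seed = 8L))
  expect_identical(s1$pdb, s2$pdb)
  expect_identical(s1$lining, s2$lining)
})

test_that("toy structure ground truth follows the stated geometry", {
  expect_equal(generate_structure(toy_structure_spec(seed = 1))$straightness,
               1.0)
  bent <- generate_structure(toy_structure_spec(seed = 1, bend_angle = 90))
  expect_equal(bent$straightness, sqrt(2) / 2, tolerance = 1e-12)
  expect_error(toy_structure_spec(tunnel_radius = 1.0), "1.4")
  expect_error(toy_structure_spec(bend_angle = 150), "0, 120")
})

test_that("toy lining ground truth equals a brute-force distance scan", {
  toy <- generate_structure(toy_structure_spec(seed = 4))
  at <- toy$structure$atoms
  X <- as.matrix(at[, c("x", "y", "z")])
  # independent point-to-segment computation
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- min(max(sum((p - a) * ab) / sum(ab^2), 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  d <- apply(X, 1, function(p) {
    min(vapply(seq_len(nrow(toy$axis) - 1), function(s) {
      seg_dist(p, toy$axis[s, ], toy$axis[s + 1, ])
    }, numeric(1)))
  })
  expect_identical(toy$lining, which(d <= 4.0))
})

test_that("toy PDB text round-trips through the parser", {
  toy <- toy_fixture()
  st <- read_structure(toy$pdb)
  expect_identical(nrow(st$atoms), nrow(toy$structure$atoms))
  expect_identical(st$atoms$resseq, seq_len(nrow(st$atoms)))
  expect_true(all(st$atoms$chain == "A"))
  expect_true(all(diff(st$atoms$resseq) > 0))
})

test_that("synthetic panel regenerates deterministically and matches fixtures", {
  sp <- panel_fixture()
  sp2 <- generate_reference_panel()
  expect_identical(as.character(sp$records), as.character(sp2$records))
  pk <- load_packaged_panel()
  expect_identical(unname(as.character(pk$records)),
                   unname(as.character(sp$records)))
  expect_identical(pk$lip3_annotation$sequence, sp$lip3_annotation$sequence)
})
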
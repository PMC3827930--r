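test_that("signal peptide stripping follows the cleavage contract", {
  expect_identical(strip_signal_peptide("MAVLK", 0), "MAVLK")
  prec <- paste(rep("A", 549), collapse = "")
  expect_identical(nchar(strip_signal_peptide(prec, 15)), 534L)
  expect_error(strip_signal_peptide("MAVLK", 5), "cleavage_pos")
  expect_error(strip_signal_peptide("MAVLK", -1), "cleavage_pos")
})

test_that("sequon scanner implements N-X(!=P)-[S/T] with overlaps", {
  expect_identical(find_sequons("NGS"), 1L)
  expect_identical(find_sequons("NPS"), integer(0))
  expect_identical(find_sequons("NNST"), c(1L, 2L))
  expect_identical(find_sequons("ANGT"), 2L)
  expect_identical(find_sequons("NG"), integer(0))
})

test_that("sequon scan agrees with an independent pattern oracle", {
  set.seed(12)
  for (r in 1:10) {
    s <- rand_seq(200)
    byhand <- which(vapply(1:(nchar(s) - 2), function(i) {
      ch <- substring(s, i:(i + 2), i:(i + 2))
      ch[1] == "N" && ch[2] != "P" && ch[3] %in% c("S", "T")
    }, logical(1)))
    expect_identical(find_sequons(s), as.integer(byhand))
  }
})

test_that("sequon scan is invariant to FASTA line wrapping and whitespace", {
  sp <- panel_fixture()
  s <- as.character(sp$records)[[3]]
  f <- tempfile(fileext = ".fasta")
  write_proteins(Biostrings::AAStringSet(setNames(s, "x")), f, width = 37L)
  back <- as.character(read_proteins(f))[[1]]
  expect_identical(find_sequons(back), find_sequons(s))
  expect_identical(find_sequons(paste0(s, "\n \n")), find_sequons(s))
})

test_that("reference annotation validates its invariants", {
  seqc <- paste0(strrep("A", 59), "C", strrep("A", 36), "C",
                 strrep("A", 20), "GGGF", strrep("A", 20), "GESAG",
                 strrep("A", 50))
  ra <- reference_annotation("ref", seqc, gggf_start = 118, gesag_start = 142,
                             ser = 144, glu = 100, his = 130, cys = c(60, 97))
  expect_s3_class(ra, "reference_annotation")
  expect_error(reference_annotation("ref", seqc, 118, 142, ser = 150,
                                    glu = 100, his = 130, cys = c(60, 97)),
               "GESAG")
  expect_error(reference_annotation("ref", seqc, 118, 142, ser = 144,
                                    glu = 100, his = 130, cys = c(97, 60)),
               "ordered")
  expect_error(reference_annotation("ref", seqc, 118, 142, ser = 144,
                                    glu = 100, his = 130, cys = c(61, 97)),
               "Cys")
})

test_that("identity transfer maps every feature onto itself", {
  sp <- panel_fixture()
  ra <- sp$lip3_annotation
  a <- transfer_annotation(ra$sequence, ra, "self")
  expect_identical(a$features$cand_pos, a$features$ref_pos)
  expect_true(all(a$features$status == "mapped"))
  expect_identical(a$lid_start, ra$cys[1] + 1L)
  expect_identical(a$lid_end, ra$cys[2] - 1L)
  expect_equal(a$identity_percent, 100)
})

test_that("an insertion before the lid shifts mapped positions as computed by hand", {
  sp <- panel_fixture()
  ra <- sp$lip3_annotation
  # pad the reference with 5 residues ahead of the first Cys: every feature
  # at/after position 50 moves +5 in the padded reference, so transferring
  # back onto the unpadded candidate must recover the original coordinates
  padded <- paste0(substr(ra$sequence, 1, 49), "WWWWW",
                   substr(ra$sequence, 50, nchar(ra$sequence)))
  ra2 <- reference_annotation("padded", padded,
                              gggf_start = ra$gggf_start + 5L,
                              gesag_start = ra$gesag_start + 5L,
                              ser = ra$ser + 5L, glu = ra$glu + 5L,
                              his = ra$his + 5L, cys = ra$cys + 5L)
  a <- transfer_annotation(ra$sequence, ra2, "orig")
  expect_identical(a$features$cand_pos[a$features$feature == "cys1"],
                   ra$cys[1])
  expect_identical(a$features$cand_pos[a$features$feature == "cys2"],
                   ra$cys[2])
  expect_identical(a$features$cand_pos[a$features$feature == "ser"], ra$ser)
  expect_identical(a$lid_seq,
                   substr(ra$sequence, ra$cys[1] + 1L, ra$cys[2] - 1L))
})

test_that("a non-Cys residue at a mapped Cys column is flagged, lid still computed", {
  sp <- panel_fixture()
  ra <- sp$lip3_annotation
  ch <- strsplit(ra$sequence, "")[[1]]
  ch[ra$cys[1]] <- "A"
  expect_warning(a <- transfer_annotation(paste(ch, collapse = ""), ra, "mut"),
                 "not Cys")
  expect_identical(a$features$status[a$features$feature == "cys1"],
                   "mismatch")
  expect_false(is.na(a$lid_hydrophobic_count))
})

test_that("lid count follows the hydrophobic set and is monotone under enlargement", {
  fake <- list(lid_seq = "GGGGG")
  expect_identical(lid_hydrophobic_count(fake), 0L)
  expect_error(lid_hydrophobic_count(list(lid_seq = NA_character_)),
               "undefined")
  set.seed(5)
  for (r in 1:10) {
    lid <- rand_seq(30)
    a <- list(lid_seq = lid)
    base_set <- hydrophobic_set()
    n1 <- lid_hydrophobic_count(a, base_set)
    expect_identical(n1, sum(strsplit(lid, "")[[1]] %in% base_set))
    bigger <- hydrophobic_set(c(base_set, "G", "Y"))
    expect_gte(lid_hydrophobic_count(a, bigger), n1)
  }
  expect_error(hydrophobic_set(character(0)), "non-empty")
  expect_error(hydrophobic_set(c("A", "J")), "non-standard")
})

test_that("annotate_candidates applies cleavage and summarises per candidate", {
  sp <- panel_fixture()
  lips <- sp$records[grepl("SYN_LIP", names(sp$records))]
  fs <- annotate_candidates(lips, sp$lip3_annotation,
                            cleavage = sp$cleavage)
  expect_identical(nrow(fs$table), 5L)
  expect_identical(fs$table$signal_len, rep(15L, 5))
  expect_identical(fs$table$lid_hydrophobic_count,
                   sp$truth$lid_hydrophobic_count[1:5])
})
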
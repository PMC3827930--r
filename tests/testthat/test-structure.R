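test_that("PDB parsing handles altloc, interleaved records, and errors", {
  toy <- toy_fixture()
  st <- read_structure(toy$pdb)
  expect_identical(nrow(st$atoms), nrow(toy$structure$atoms))

  # interleave TER / remarks: same atoms as the stripped file
  lines <- strsplit(toy$pdb, "\n")[[1]]
  fat <- c("REMARK generated toy", lines[1:10], "TER",
           lines[11:length(lines)], "MASTER")
  st2 <- read_structure(fat)
  expect_identical(st2$atoms, st$atoms)

  # altloc B records are excluded with a warning
  bline <- lines[1]
  substr(bline, 17, 17) <- "B"
  expect_warning(st3 <- read_structure(c(bline, lines[2:5])), "altloc")
  expect_identical(nrow(st3$atoms), 4L)

  # malformed coordinates -> parse error naming the line
  bad <- lines[1]
  substr(bad, 31, 38) <- "  xx.xxx"
  expect_error(read_structure(c(bad, lines[2])), "line 1")
  expect_error(read_structure("REMARK nothing here"), "no ATOM")
})

test_that("straight toy tunnels recover the constructed ground truth", {
  toy <- toy_fixture()
  tns <- find_tunnels(toy$structure, toy$seed_resseq)
  expect_length(tns, 1L)
  sc <- score_tunnel(toy$structure, tns)
  jac <- length(intersect(sc$lining$resseq, toy$lining)) /
    length(union(sc$lining$resseq, toy$lining))
  expect_gte(jac, 0.9)
  expect_gte(tns[[1]]$straightness, 0.97)
  expect_identical(classify_shape(tns[[1]]), "straight")
  expect_true(all(tns[[1]]$radii > 0))
  expect_equal(tns[[1]]$straightness,
               sqrt(sum((tns[[1]]$centerline[nrow(tns[[1]]$centerline), ] -
                           tns[[1]]$centerline[1, ])^2)) /
                 tns[[1]]$arc_length,
               tolerance = 1e-9)
})

test_that("solid block around the seed yields an empty tunnel set", {
  g <- as.matrix(expand.grid(x = seq(0, 12, 1.2), y = seq(0, 12, 1.2),
                             z = seq(0, 12, 1.2)))
  lines <- vapply(seq_len(nrow(g)), function(i) {
    lipmine:::pdb_atom_line(i, "CA", "GLY", "A", i, g[i, 1], g[i, 2], g[i, 3])
  }, character(1))
  st <- read_structure(lines)
  seed <- which.min(rowSums((g - 6)^2))
  out <- find_tunnels(st, seed)
  expect_s3_class(out, "tunnel_set")
  expect_length(out, 0L)
  expect_error(find_tunnels(st, 99999), "not present")
})

test_that("two planted exits give two tunnels with distant mouths", {
  toy <- generate_structure(toy_structure_spec(seed = 6, open_both_ends = TRUE,
                                               tunnel_length = 24))
  tns <- find_tunnels(toy$structure, toy$seed_resseq)
  expect_length(tns, 2L)
  sep <- sqrt(sum((tns[[1]]$mouth - tns[[2]]$mouth)^2))
  expect_gt(sep, 8)
})

test_that("shape classification separates planted bends analytically", {
  toy <- toy_fixture()
  tns <- find_tunnels(toy$structure, toy$seed_resseq)
  expect_identical(classify_shape(tns[[1]]), "straight")
  bent <- generate_structure(toy_structure_spec(seed = 2, bend_angle = 90,
                                                tunnel_length = 28))
  tb <- find_tunnels(bent$structure, bent$seed_resseq)
  expect_identical(classify_shape(tb[[1]]), "bent")
  # detection-based sweep up to 90 degrees (sharper toy elbows pinch the
  # bore below the default grid resolution; see the methods vignette)
  for (ang in c(0, 40, 70, 90)) {
    gt <- cos(ang * pi / 180 / 2)
    gen <- generate_structure(toy_structure_spec(seed = 9, bend_angle = ang,
                                                 tunnel_length = 28))
    expect_equal(gen$straightness, gt, tolerance = 1e-9)
    tn <- find_tunnels(gen$structure, gen$seed_resseq)
    expect_identical(classify_shape(tn[[1]]),
                     if (gt >= 0.85) "straight" else "bent")
  }
  # classification boundary over the full 0-120 analytic range
  for (ang in seq(0, 120, by = 10)) {
    gt <- cos(ang * pi / 180 / 2)
    fake <- base::structure(list(straightness = gt), class = "tunnel")
    expect_identical(classify_shape(fake),
                     if (gt >= 0.85) "straight" else "bent")
  }
})

test_that("tunnel scoring counts hydrophobic lining and rounds the percent", {
  toy <- toy_fixture()
  tns <- find_tunnels(toy$structure, toy$seed_resseq)
  sc <- score_tunnel(toy$structure, tns)
  expect_identical(sc$fraction,
                   as.integer(round(100 * sc$n_hydrophobic / sc$n_lining)))
  expect_lte(sc$n_hydrophobic, sc$n_lining)
  expect_error(score_tunnel(toy$structure,
                            base::structure(list(), class = "tunnel_set")),
               "empty")

  # all-glycine toy: 0% hydrophobic lining
  gly <- generate_structure(toy_structure_spec(seed = 3,
                                               resname_pool = "GLY",
                                               seed_residue = "GLY"))
  tg <- find_tunnels(gly$structure, gly$seed_resseq)
  expect_identical(score_tunnel(gly$structure, tg)$fraction, 0L)
})

test_that("scores are invariant to residue renumbering", {
  toy <- toy_fixture()
  tns <- find_tunnels(toy$structure, toy$seed_resseq)
  sc <- score_tunnel(toy$structure, tns)
  st2 <- toy$structure
  st2$atoms$resseq <- st2$atoms$resseq + 500L
  st2$atoms$resid <- paste0(st2$atoms$chain, st2$atoms$resseq)
  tns2 <- find_tunnels(st2, toy$seed_resseq + 500L)
  sc2 <- score_tunnel(st2, tns2)
  expect_identical(sc2$fraction, sc$fraction)
  expect_identical(sc2$lining$resseq - 500L, sc$lining$resseq)
})

test_that("rigid motions leave tunnels and scores exactly unchanged", {
  toy <- toy_fixture()
  tns <- find_tunnels(toy$structure, toy$seed_resseq)
  sc <- score_tunnel(toy$structure, tns)
  st2 <- rigid_transform(toy$structure, seed = 7)
  tns2 <- find_tunnels(st2, toy$seed_resseq)
  sc2 <- score_tunnel(st2, tns2)
  expect_identical(sc2$lining$resid, sc$lining$resid)
  expect_identical(sc2$fraction, sc$fraction)
  expect_equal(tns2[[1]]$straightness, tns[[1]]$straightness,
               tolerance = 1e-6)
  expect_equal(tns2[[1]]$arc_length, tns[[1]]$arc_length, tolerance = 1e-6)
})

test_that("halving the grid step barely changes the lining set", {
  toy <- toy_fixture()
  sc1 <- score_tunnel(toy$structure,
                      find_tunnels(toy$structure, toy$seed_resseq))
  sc2 <- score_tunnel(toy$structure,
                      find_tunnels(toy$structure, toy$seed_resseq,
                                   tunnel_params(grid_step = 0.4)))
  jac <- length(intersect(sc1$lining$resid, sc2$lining$resid)) /
    length(union(sc1$lining$resid, sc2$lining$resid))
  expect_gt(jac, 0.9)
})

test_that("centerline pseudo-atom PDB export is loadable", {
  toy <- toy_fixture()
  tns <- find_tunnels(toy$structure, toy$seed_resseq)
  f <- tempfile(fileext = ".pdb")
  write_tunnel_pdb(tns[[1]], f)
  back <- read_structure(f)
  expect_identical(nrow(back$atoms), nrow(tns[[1]]$centerline))
})
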
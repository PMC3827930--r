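# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so generators are reproducible and side-effect
# free.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample()-pitfall-safe helpers
sample1 <- function(x) x[sample.int(length(x), 1L)]
shuffle <- function(x) x[sample.int(length(x))]

default_background_freqs <- function() {
  f <- rep((1 - 0.01) / 19, 20)
  names(f) <- AA20
  f["C"] <- 0.01  # down-weighted so accidental lid-delimiter Cys are rare
  f
}

#' Synthetic proteome specification
#'
#' Describes a proteome with background records (a fraction of which carry
#' "esterase"/"lipase" keywords in their headers, emulating a portal search
#' space) plus planted candidate records with fully known features.
#'
#' @param n_background number of background records (>= 0).
#' @param n_planted number of planted candidates (>= 0).
#' @param length_range min/max background record length in residues
#'   (min >= 60).
#' @param background_freqs amino-acid probability vector over the 20
#'   standard letters (default: uniform with Cys down-weighted to 0.01).
#' @param keyword_fraction fraction of background headers containing a
#'   keyword.
#' @param seed integer RNG seed.
#' @return list of class `proteome_spec`.
#' @export
proteome_spec <- function(n_background = 200L, n_planted = 7L,
                          length_range = c(350L, 650L),
                          background_freqs = default_background_freqs(),
                          keyword_fraction = 0.3,
                          seed = 1L) {
  if (length(background_freqs) != 20L) {
    stop("background_freqs needs 20 entries", call. = FALSE)
  }
  if (abs(sum(background_freqs) - 1) > 1e-9) {
    stop("background_freqs must sum to 1", call. = FALSE)
  }
  if (n_background < 0L || n_planted < 0L) {
    stop("record counts must be non-negative", call. = FALSE)
  }
  if (length_range[1] < 60L) {
    stop("minimum length must be >= 60 (room for planted features)",
         call. = FALSE)
  }
  if (keyword_fraction < 0 || keyword_fraction > 1) {
    stop("keyword_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_background = as.integer(n_background),
                 n_planted = as.integer(n_planted),
                 length_range = as.integer(length_range),
                 background_freqs = setNames(background_freqs, AA20),
                 keyword_fraction = keyword_fraction,
                 seed = as.integer(seed)),
            class = "proteome_spec")
}

#' Planted candidate specification
#'
#' Feature layout of one planted record, in precursor (whole-record) 1-based
#' coordinates. Defaults mirror the classic Lip3-like layout: 15-residue
#' signal peptide, GGGF oxyanion motif at 137, GESAG catalytic shoulder at
#' 222 (catalytic Ser at 224), lid delimited by Cys 75/112.
#'
#' @param oxyanion_pos GGGF start.
#' @param shoulder_pos GESAG start (must exceed `oxyanion_pos`).
#' @param cys_positions ordered pair of lid-delimiting Cys positions.
#' @param lid_hydrophobic_count exact number of hydrophobic residues planted
#'   strictly between the Cys pair.
#' @param triad_his_pos,triad_glu_pos catalytic His/Glu positions.
#' @param sequon_count exact number of N-X(!=P)-[S/T] sequons in the record.
#' @param signal_len signal peptide length (0 = none).
#' @return list of class `planted_candidate`.
#' @export
planted_candidate <- function(oxyanion_pos = 137L, shoulder_pos = 222L,
                              cys_positions = c(75L, 112L),
                              lid_hydrophobic_count = 10L,
                              triad_his_pos = 464L, triad_glu_pos = 356L,
                              sequon_count = 1L, signal_len = 15L) {
  p <- list(oxyanion_pos = as.integer(oxyanion_pos),
            shoulder_pos = as.integer(shoulder_pos),
            cys_positions = as.integer(cys_positions),
            lid_hydrophobic_count = as.integer(lid_hydrophobic_count),
            triad_his_pos = as.integer(triad_his_pos),
            triad_glu_pos = as.integer(triad_glu_pos),
            sequon_count = as.integer(sequon_count),
            signal_len = as.integer(signal_len))
  if (p$oxyanion_pos >= p$shoulder_pos) {
    stop("constraint violated: oxyanion_pos must precede shoulder_pos",
         call. = FALSE)
  }
  if (p$cys_positions[1] >= p$cys_positions[2]) {
    stop("constraint violated: cys_positions must be strictly ordered",
         call. = FALSE)
  }
  lid_len <- p$cys_positions[2] - p$cys_positions[1] - 1L
  if (lid_len < p$lid_hydrophobic_count) {
    stop("constraint violated: lid_hydrophobic_count exceeds lid span (",
         lid_len, " residues between the Cys pair)", call. = FALSE)
  }
  spans <- rbind(c(p$oxyanion_pos, p$oxyanion_pos + 3L),
                 c(p$shoulder_pos, p$shoulder_pos + 4L),
                 c(p$cys_positions[1], p$cys_positions[1]),
                 c(p$cys_positions[2], p$cys_positions[2]),
                 c(p$triad_his_pos, p$triad_his_pos),
                 c(p$triad_glu_pos, p$triad_glu_pos))
  o <- order(spans[, 1])
  spans <- spans[o, , drop = FALSE]
  fields <- c("oxyanion_pos", "shoulder_pos", "cys_positions", "cys_positions",
              "triad_his_pos", "triad_glu_pos")[o]
  for (i in seq_len(nrow(spans) - 1L)) {
    if (spans[i + 1L, 1] <= spans[i, 2]) {
      stop("constraint violated: planted features overlap (",
           fields[i], " / ", fields[i + 1L], ")", call. = FALSE)
    }
  }
  structure(p, class = "planted_candidate")
}

# Independent brute-force scan: all occurrences of each motif in each record.
scan_motifs <- function(seqs, ids, motifs) {
  rows <- lapply(seq_along(seqs), function(i) {
    do.call(rbind, lapply(motifs, function(m) {
      # overlap-tolerant scan via lookahead
      g <- gregexpr(paste0("(?=", m, ")"), seqs[i], perl = TRUE)[[1]]
      if (g[1] == -1L) return(NULL)
      data.frame(id = ids[i], motif = m, pos = as.integer(g),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0), motif = character(0),
                      pos = integer(0), stringsAsFactors = FALSE)
  }
  out
}

build_planted_sequence <- function(p, length_range, freqs) {
  need <- max(p$shoulder_pos + 4L, p$cys_positions[2], p$triad_his_pos,
              p$triad_glu_pos, p$oxyanion_pos + 3L) + 30L
  L <- max(need, sample1(seq(length_range[1], length_range[2])))
  # filler excludes Asn (keeps sequon count exact) and Cys (keeps the lid
  # delimiters unambiguous)
  chars <- sample_residues(L, freqs, exclude = c("N", "C"))
  chars[1] <- "M"
  put <- function(chars, pos, s) {
    chars[pos:(pos + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
    chars
  }
  chars <- put(chars, p$oxyanion_pos, "GGGF")
  chars <- put(chars, p$shoulder_pos, "GESAG")
  chars[p$cys_positions] <- "C"
  chars[p$triad_glu_pos] <- "E"
  chars[p$triad_his_pos] <- "H"
  # lid: exactly lid_hydrophobic_count hydrophobics; filler avoids G so no
  # accidental GESAG/GGGF can arise inside the lid
  lid_idx <- (p$cys_positions[1] + 1L):(p$cys_positions[2] - 1L)
  k <- p$lid_hydrophobic_count
  hyd <- sample(c("A", "V", "L", "I", "M", "F", "W", "P"), k, replace = TRUE)
  pol <- sample(c("S", "T", "D", "E", "Q", "K", "R", "H", "Y"),
                length(lid_idx) - k, replace = TRUE)
  chars[lid_idx] <- shuffle(c(hyd, pol))
  # sequons: exact count, planted as N-A-S in feature-free territory
  sequon_pos <- integer(0)
  if (p$sequon_count > 0L) {
    blocked <- rep(FALSE, L)
    blocked[p$oxyanion_pos:(p$oxyanion_pos + 3L)] <- TRUE
    blocked[p$shoulder_pos:(p$shoulder_pos + 4L)] <- TRUE
    blocked[lid_idx] <- TRUE
    blocked[c(p$cys_positions, p$triad_his_pos, p$triad_glu_pos, 1L)] <- TRUE
    if (p$signal_len > 0L) blocked[seq_len(p$signal_len)] <- TRUE
    free <- which(!blocked[seq_len(L - 2L)] &
                    !blocked[seq_len(L - 2L) + 1L] &
                    !blocked[seq_len(L - 2L) + 2L])
    chosen <- integer(0)
    for (cand in shuffle(free)) {
      if (all(abs(cand - chosen) >= 3L)) chosen <- c(chosen, cand)
      if (length(chosen) == p$sequon_count) break
    }
    if (length(chosen) < p$sequon_count) {
      stop("constraint violated: sequon_count does not fit in the record",
           call. = FALSE)
    }
    for (cp in chosen) chars <- put(chars, cp, "NAS")
    sequon_pos <- sort(chosen)
  }
  list(seq = paste(chars, collapse = ""), length = L, sequons = sequon_pos)
}

#' Generate a synthetic proteome with planted candidates
#'
#' Emits `n_background + n_planted` protein records. Every planted record
#' carries GESAG and GGGF exactly at the specified positions, the
#' lid-delimiting Cys pair with an exact lid hydrophobic count, the planted
#' triad residues and exactly the requested number of sequons. Background
#' records that *accidentally* contain all motifs are recorded as collisions
#' in the ground-truth table (detected by an independent scan), never
#' resampled away.
#'
#' @param spec a [proteome_spec()].
#' @param planted list of [planted_candidate()] of length `spec$n_planted`.
#' @return list of class `synthetic_proteome`: `records`
#'   ([Biostrings::AAStringSet]), `truth` (per-record table with `planted`
#'   and `collision` flags), `hits` (independent motif scan, all
#'   occurrences), `planted_truth` (per-candidate feature table),
#'   `sequons` (list of planted sequon positions).
#' @export
generate_proteome <- function(spec,
                              planted = replicate(spec$n_planted,
                                                  planted_candidate(),
                                                  simplify = FALSE)) {
  stopifnot(inherits(spec, "proteome_spec"))
  if (length(planted) != spec$n_planted) {
    stop("planted list length must equal n_planted", call. = FALSE)
  }
  motifs <- c("GESAG", "GGGF")
  with_seed(spec$seed, {
    genomes <- paste0("genome", seq_len(5L))
    kw_pool <- c("putative sterol esterase", "triacylglycerol lipase",
                 "secreted lipase precursor", "carboxylesterase family protein")
    decoy_pool <- c("protein kinase", "hypothetical protein",
                    "cytochrome p450", "abc transporter", "glycosyl hydrolase")
    n_bg <- spec$n_background
    bg_seqs <- character(n_bg)
    bg_desc <- character(n_bg)
    if (n_bg > 0L) {
      kw_flag <- runif(n_bg) < spec$keyword_fraction
      for (i in seq_len(n_bg)) {
        L <- sample1(seq(spec$length_range[1], spec$length_range[2]))
        bg_seqs[i] <- paste(sample_residues(L, spec$background_freqs),
                            collapse = "")
        bg_desc[i] <- if (kw_flag[i]) sample(kw_pool, 1L) else
          sample(decoy_pool, 1L)
      }
    }
    pl <- lapply(planted, build_planted_sequence,
                 length_range = spec$length_range,
                 freqs = spec$background_freqs)
    ids <- c(sprintf("bg%04d", seq_len(n_bg)),
             sprintf("cand%02d", seq_len(spec$n_planted)))
    seqs <- c(bg_seqs, vapply(pl, `[[`, character(1), "seq"))
    desc <- c(bg_desc,
              rep("putative sterol esterase/lipase", spec$n_planted))
    genome <- sample(genomes, length(ids), replace = TRUE)
    headers <- paste0(ids, " ", desc, " genome=", genome)
    records <- Biostrings::AAStringSet(setNames(seqs, headers))

    hits <- scan_motifs(seqs, ids, motifs)
    has_all <- vapply(ids, function(id) {
      all(motifs %in% hits$motif[hits$id == id])
    }, logical(1))
    is_planted <- c(rep(FALSE, n_bg), rep(TRUE, spec$n_planted))
    truth <- data.frame(id = ids,
                        genome = genome,
                        planted = is_planted,
                        has_all_motifs = unname(has_all),
                        collision = unname(has_all) & !is_planted,
                        has_keyword = grepl("esterase|lipase",
                                            tolower(desc)),
                        stringsAsFactors = FALSE)
    planted_truth <- if (spec$n_planted > 0L) {
      do.call(rbind, lapply(seq_along(planted), function(i) {
        p <- planted[[i]]
        data.frame(id = sprintf("cand%02d", i),
                   oxyanion_pos = p$oxyanion_pos,
                   shoulder_pos = p$shoulder_pos,
                   cys1 = p$cys_positions[1], cys2 = p$cys_positions[2],
                   lid_hydrophobic_count = p$lid_hydrophobic_count,
                   triad_glu_pos = p$triad_glu_pos,
                   triad_his_pos = p$triad_his_pos,
                   sequon_count = p$sequon_count,
                   signal_len = p$signal_len,
                   length = pl[[i]]$length,
                   stringsAsFactors = FALSE)
      }))
    } else {
      NULL
    }
    structure(list(records = records, truth = truth, hits = hits,
                   planted_truth = planted_truth,
                   sequons = lapply(pl, `[[`, "sequons"),
                   spec = spec),
              class = "synthetic_proteome")
  })
}

#' Write a ground-truth table as TSV
#'
#' @param truth a data.frame (e.g. `$truth` of a [generate_proteome()]
#'   result).
#' @param path output path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
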
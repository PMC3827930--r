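#' Generate the synthetic reference panel
#'
#' Builds a deterministic, clearly synthetic stand-in for the family-labelled
#' reference panel of versatile lipases/sterol esterases (the real panel -
#' Candida rugosa Lip1-Lip5, the Ophiostoma piceae sterol esterase OPE, the
#' Melanocarpus albomyces esterase, plus representatives of the Yarrowia,
#' brefeldin, organellar, pancreatic and bacterial families - requires
#' downloads and is not shipped). The construction encodes the canonical
#' ground truth of the real family so pipeline statistics are auditable
#' offline:
#'
#' * Lip precursors are 549 residues (15-residue signal peptide, 534-residue
#'   mature chain); OPE/Malb carry an 18-residue signal.
#' * GGGF starts at mature 122 (precursor 137) and GESAG at mature 207
#'   (precursor 222), putting the catalytic Ser at mature 209; Glu 341 and
#'   His 449 complete the triad; Cys 60/97 delimit the lid (mature 61-96).
#' * Lid hydrophobic counts under the default [hydrophobic_set()]:
#'   Lip1 = 8, Lip2 = 12, Lip3 = 10, Lip4 = 11, Lip5 = 9, OPE = 13,
#'   Malb = 13.
#' * Lip2-Lip5 are derived from Lip1 at 5.5% point substitution, realising
#'   the canonical 77-88% pairwise mature identity band; OPE diverges
#'   from Lip1 at 55% (identity to the Lips just above 40%); Malb diverges
#'   from OPE at 20%.
#' * Non-crugosa families are independent random sequences (two members
#'   each for yarrowia and brefeldin at 15% divergence).
#'
#' @param seed integer RNG seed; the packaged fixtures use the default.
#' @return list of class `synthetic_panel`: `records` (precursor
#'   [Biostrings::AAStringSet] with `family=`, `versatile=`, `cleavage=`
#'   header fields), `panel` (a [reference_panel()]), `cleavage` (named
#'   vector), `lip3_annotation` (mature-chain [reference_annotation()]),
#'   `truth` (per-record table of planted lid counts and layout).
#' @export
generate_reference_panel <- function(seed = 101L) {
  mature_len <- 534L
  signal_lip <- 15L
  signal_ope <- 18L
  gggf <- 122L; gesag <- 207L; ser <- 209L; glu <- 341L; his <- 449L
  cys <- c(60L, 97L)
  lid_idx <- (cys[1] + 1L):(cys[2] - 1L)
  lid_counts <- c(SYN_LIP1 = 8L, SYN_LIP2 = 12L, SYN_LIP3 = 10L,
                  SYN_LIP4 = 11L, SYN_LIP5 = 9L, SYN_OPE = 13L,
                  SYN_MALB = 13L)
  hyd_pool <- c("A", "V", "L", "I", "M", "F", "W")
  pol_pool <- c("S", "T", "D", "E", "Q", "K", "R", "H", "Y")
  freqs <- default_background_freqs()

  with_seed(seed, {
    fixed_pos <- sort(c(gggf:(gggf + 3L), gesag:(gesag + 4L), cys, glu, his))
    write_features <- function(chars) {
      chars[gggf:(gggf + 3L)] <- c("G", "G", "G", "F")
      chars[gesag:(gesag + 4L)] <- c("G", "E", "S", "A", "G")
      chars[cys] <- "C"
      chars[glu] <- "E"
      chars[his] <- "H"
      chars
    }
    write_lid <- function(chars, k) {
      m <- length(lid_idx)
      chars[lid_idx] <- shuffle(c(sample(hyd_pool, k, replace = TRUE),
                                  sample(pol_pool, m - k, replace = TRUE)))
      chars
    }
    plant_sequon <- function(chars, pos) {
      chars[pos:(pos + 2L)] <- c("N", "A", "S")
      chars
    }
    mutate <- function(chars, rate, protect) {
      hit <- which(runif(length(chars)) < rate)
      hit <- setdiff(hit, protect)
      for (i in hit) {
        chars[i] <- sample1(setdiff(setdiff(AA20, c("C", "N")), chars[i]))
      }
      chars
    }
    protect <- c(fixed_pos, lid_idx, 300L:302L)

    base <- sample_residues(mature_len, freqs, exclude = c("N", "C"))
    base <- write_features(base)
    base <- plant_sequon(base, 300L)

    mats <- list()
    mats$SYN_LIP1 <- write_lid(base, lid_counts["SYN_LIP1"])
    for (nm in c("SYN_LIP2", "SYN_LIP3", "SYN_LIP4", "SYN_LIP5")) {
      m <- mutate(base, 0.055, protect)
      mats[[nm]] <- write_lid(m, lid_counts[nm])
    }
    ope <- mutate(base, 0.55, protect)
    mats$SYN_OPE <- write_lid(ope, lid_counts["SYN_OPE"])
    malb <- mutate(mats$SYN_OPE, 0.20, protect)
    mats$SYN_MALB <- write_lid(malb, lid_counts["SYN_MALB"])

    signal_of <- c(SYN_LIP1 = signal_lip, SYN_LIP2 = signal_lip,
                   SYN_LIP3 = signal_lip, SYN_LIP4 = signal_lip,
                   SYN_LIP5 = signal_lip, SYN_OPE = signal_ope,
                   SYN_MALB = signal_ope)
    precursors <- lapply(names(mats), function(nm) {
      sig <- c("M", sample_residues(signal_of[nm] - 1L, freqs,
                                    exclude = c("N", "C")))
      paste(c(sig, mats[[nm]]), collapse = "")
    })
    names(precursors) <- names(mats)

    other <- list()
    for (fam in c("yarrowia", "brefeldin", "organellar", "pancreatic",
                  "bacterial")) {
      L <- sample1(420:560)
      b <- sample_residues(L, freqs)
      b[1] <- "M"
      nm1 <- paste0("SYN_", toupper(substr(fam, 1, 4)), "1")
      other[[nm1]] <- list(seq = paste(b, collapse = ""), family = fam)
      if (fam %in% c("yarrowia", "brefeldin")) {
        b2 <- mutate(b, 0.15, integer(0))
        nm2 <- paste0("SYN_", toupper(substr(fam, 1, 4)), "2")
        other[[nm2]] <- list(seq = paste(b2, collapse = ""), family = fam)
      }
    }

    desc <- c(SYN_LIP1 = "synthetic lipase 1 stand-in",
              SYN_LIP2 = "synthetic lipase 2 stand-in",
              SYN_LIP3 = "synthetic lipase 3 stand-in (annotation anchor)",
              SYN_LIP4 = "synthetic lipase 4 stand-in",
              SYN_LIP5 = "synthetic lipase 5 stand-in",
              SYN_OPE = "synthetic sterol esterase stand-in (OPE-like)",
              SYN_MALB = "synthetic sterol esterase stand-in (Malb-like)")
    headers <- c(
      vapply(names(precursors), function(nm) {
        paste0(nm, " family=crugosa_like versatile=yes cleavage=",
               signal_of[nm], " ", desc[nm])
      }, character(1)),
      vapply(names(other), function(nm) {
        paste0(nm, " family=", other[[nm]]$family,
               " synthetic reference stand-in")
      }, character(1)))
    seqs <- c(unlist(precursors), vapply(other, `[[`, character(1), "seq"))
    records <- Biostrings::AAStringSet(setNames(unname(seqs),
                                                unname(headers)))

    cleavage <- c(signal_of,
                  setNames(rep(0L, length(other)), names(other)))
    lip3_annot <- reference_annotation(
      id = "SYN_LIP3",
      sequence = paste(mats$SYN_LIP3, collapse = ""),
      gggf_start = gggf, gesag_start = gesag,
      ser = ser, glu = glu, his = his, cys = cys,
      note = paste("synthetic Lip3 stand-in; mature-chain numbering,",
                   "precursor = mature + 15 (GGGF 137, GESAG 222)"))
    truth <- data.frame(id = names(lid_counts),
                        family = "crugosa_like",
                        signal_len = unname(signal_of),
                        mature_length = mature_len,
                        lid_hydrophobic_count = unname(lid_counts),
                        stringsAsFactors = FALSE)
    base::structure(list(records = records,
                         panel = reference_panel(records),
                         cleavage = cleavage,
                         lip3_annotation = lip3_annot,
                         truth = truth,
                         seed = seed),
                    class = "synthetic_panel")
  })
}

#' Load the packaged synthetic reference panel fixtures
#'
#' Reads the FASTA + JSON fixtures under `inst/extdata/` (written by
#' `scripts/make_panel_fixtures.R` from [generate_reference_panel()] with
#' its default seed).
#'
#' @return Same shape as [generate_reference_panel()] minus `truth`.
#' @export
load_packaged_panel <- function() {
  fa <- system.file("extdata", "synthetic_reference_panel.fasta",
                    package = "lipmine")
  an <- system.file("extdata", "lip3_synthetic_annotation.json",
                    package = "lipmine")
  records <- read_proteins(fa)
  cl <- header_field(records, "cleavage")
  cleavage <- setNames(ifelse(is.na(cl), 0L, as.integer(cl)),
                       record_ids(records))
  list(records = records,
       panel = reference_panel(records),
       cleavage = cleavage,
       lip3_annotation = read_reference_annotation(an))
}
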
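#' Reference feature annotation
#'
#' Mature-chain, 1-based positions of the functional features of an anchor
#' sequence (canonically Candida rugosa Lip3): the GGGF oxyanion-hole motif
#' start, the GESAG catalytic-shoulder start, the catalytic triad
#' (Ser-Glu-His; the Ser is the S inside GESAG) and the two conserved
#' cysteines whose disulfide delimits the lid.
#'
#' @param id reference identifier.
#' @param sequence mature reference sequence (character).
#' @param gggf_start,gesag_start motif start positions.
#' @param ser,glu,his catalytic triad positions.
#' @param cys ordered pair of lid-delimiting cysteine positions.
#' @param note free-text provenance note (e.g. numbering convention).
#' @return list of class `reference_annotation`.
#' @export
reference_annotation <- function(id, sequence, gggf_start, gesag_start,
                                 ser, glu, his, cys, note = "") {
  sequence <- clean_seq(sequence)
  n <- nchar(sequence)
  pos <- c(gggf_start, gesag_start, ser, glu, his, cys)
  if (any(pos < 1L) || any(pos > n)) {
    stop("annotation positions outside reference length", call. = FALSE)
  }
  if (length(cys) != 2L || cys[1] >= cys[2]) {
    stop("cys must be a strictly ordered pair", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars[cys] == "C")) {
    stop("cys positions do not hold Cys in the reference", call. = FALSE)
  }
  if (substr(sequence, gesag_start, gesag_start + 4L) != "GESAG") {
    stop("gesag_start does not point at a GESAG occurrence", call. = FALSE)
  }
  if (!(ser >= gesag_start && ser <= gesag_start + 4L) || chars[ser] != "S") {
    stop("catalytic Ser must lie inside the GESAG occurrence", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence,
                 gggf_start = as.integer(gggf_start),
                 gesag_start = as.integer(gesag_start),
                 ser = as.integer(ser), glu = as.integer(glu),
                 his = as.integer(his), cys = as.integer(cys),
                 note = note),
            class = "reference_annotation")
}

#' Read a reference annotation from a JSON config file
#'
#' The packaged annotation for the synthetic Lip3 stand-in lives at
#' `system.file("extdata", "lip3_synthetic_annotation.json", package =
#' "lipmine")`.
#'
#' @param path JSON file with the [reference_annotation()] fields.
#' @return A `reference_annotation`.
#' @export
read_reference_annotation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  reference_annotation(id = x$id, sequence = x$sequence,
                       gggf_start = x$gggf_start, gesag_start = x$gesag_start,
                       ser = x$ser, glu = x$glu, his = x$his,
                       cys = x$cys, note = x$note %||% "")
}

clean_seq <- function(x) {
  if (inherits(x, "AAString") || inherits(x, "AAStringSet")) {
    x <- as.character(x)[1]
  }
  gsub("\\s", "", toupper(as.character(x)[1]))
}

#' Strip a signal peptide
#'
#' Returns the mature chain after an externally supplied cleavage position
#' (signal-peptide prediction itself is out of scope). All downstream
#' coordinates are mature-chain, 1-based.
#'
#' @param record a protein sequence (character or `AAString`).
#' @param cleavage_pos number of N-terminal residues removed
#'   (`0 <= cleavage_pos < length`); 0 is the identity.
#' @return The mature sequence (character).
#' @export
strip_signal_peptide <- function(record, cleavage_pos) {
  s <- clean_seq(record)
  n <- nchar(s)
  if (cleavage_pos < 0L || cleavage_pos >= n) {
    stop("cleavage_pos must satisfy 0 <= cleavage_pos < sequence length",
         call. = FALSE)
  }
  substr(s, cleavage_pos + 1L, n)
}

#' Find N-glycosylation sequons
#'
#' All 1-based positions i with residue i = N, residue i+1 != P and residue
#' i+2 in \{S, T\} (the N-X(!=P)-[S/T] acceptor pattern). Overlapping sequons
#' are all reported.
#'
#' @param sequence protein sequence.
#' @return Integer vector of sequon start positions (possibly empty).
#' @export
#' @examples
#' find_sequons("NGS")  # 1
#' find_sequons("NNST") # 1 2
find_sequons <- function(sequence) {
  s <- clean_seq(sequence)
  m <- gregexpr("N(?=[^P][ST])", s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Map every reference position to its aligned candidate position (NA = gap).
alignment_position_map <- function(aligned_ref, aligned_cand) {
  ra <- strsplit(aligned_ref, "")[[1]]
  ca <- strsplit(aligned_cand, "")[[1]]
  ref_pos <- cumsum(ra != "-")
  cand_pos <- cumsum(ca != "-")
  keep <- ra != "-"
  out <- ifelse(ca[keep] != "-", cand_pos[keep], NA_integer_)
  as.integer(out)
}

#' Transfer reference features onto a candidate
#'
#' Globally aligns the candidate against the annotated reference and maps
#' each feature position through the alignment columns. Features aligned to
#' a candidate gap are reported `"absent"`; mapped cysteines that are not Cys
#' in the candidate are flagged `"mismatch"` (with a warning) but the lid is
#' still computed from the mapped columns.
#'
#' @param candidate candidate mature sequence (character or `AAString`).
#' @param ref_annot a [reference_annotation()] (carries the reference
#'   sequence).
#' @param candidate_id id used in the output (default "candidate").
#' @param hset a [hydrophobic_set()] for the lid count.
#' @param params an [align_params()].
#' @return list of class `feature_annotation`: `features` data.frame
#'   (feature, ref_pos, cand_pos, status), `lid_start`, `lid_end`, `lid_seq`,
#'   `lid_hydrophobic_count`, `sequons`, `identity_percent`.
#' @export
transfer_annotation <- function(candidate, ref_annot,
                                candidate_id = "candidate",
                                hset = hydrophobic_set(),
                                params = align_params()) {
  cand <- clean_seq(candidate)
  al <- global_align(ref_annot$sequence, cand, params)
  pmap <- alignment_position_map(al$aligned_a, al$aligned_b)
  feats <- c(gggf_start = ref_annot$gggf_start,
             gesag_start = ref_annot$gesag_start,
             ser = ref_annot$ser, glu = ref_annot$glu, his = ref_annot$his,
             cys1 = ref_annot$cys[1], cys2 = ref_annot$cys[2])
  mapped <- setNames(pmap[feats], names(feats))
  status <- ifelse(is.na(mapped), "absent", "mapped")
  chars <- strsplit(cand, "")[[1]]
  for (cy in c("cys1", "cys2")) {
    p <- mapped[[cy]]
    if (!is.na(p) && chars[p] != "C") {
      status[names(feats) == cy] <- "mismatch"
      warning("mapped ", cy, " column holds ", chars[p], " (not Cys) in ",
              candidate_id, call. = FALSE)
    }
  }
  lid_start <- lid_end <- NA_integer_
  lid_seq <- NA_character_
  lid_count <- NA_integer_
  c1 <- mapped[["cys1"]]; c2 <- mapped[["cys2"]]
  if (!is.na(c1) && !is.na(c2) && c2 - c1 >= 2L) {
    lid_start <- c1 + 1L
    lid_end <- c2 - 1L
    lid_seq <- substr(cand, lid_start, lid_end)
    lid_count <- sum(strsplit(lid_seq, "")[[1]] %in% hset)
  }
  structure(list(candidate_id = candidate_id,
                 reference_id = ref_annot$id,
                 features = data.frame(feature = names(feats),
                                       ref_pos = unname(feats),
                                       cand_pos = unname(mapped),
                                       status = unname(status),
                                       stringsAsFactors = FALSE),
                 lid_start = lid_start, lid_end = lid_end,
                 lid_seq = lid_seq,
                 lid_hydrophobic_count = lid_count,
                 sequons = find_sequons(cand),
                 identity_percent = al$identity_percent),
            class = "feature_annotation")
}

#' Lid hydrophobic residue count
#'
#' Number of residues in the lid span (strictly between the mapped cysteine
#' pair) belonging to the hydrophobic set.
#'
#' @param annotation a `feature_annotation` (or any list with a `lid_seq`).
#' @param hset a [hydrophobic_set()].
#' @return Integer count.
#' @export
lid_hydrophobic_count <- function(annotation, hset = hydrophobic_set()) {
  if (is.null(annotation$lid_seq) || is.na(annotation$lid_seq)) {
    stop("lid is undefined (cysteine pair not mapped)", call. = FALSE)
  }
  sum(strsplit(annotation$lid_seq, "")[[1]] %in% hset)
}

#' Annotate a set of candidates against a reference
#'
#' Convenience loop over [transfer_annotation()], with optional external
#' signal-peptide cleavage positions applied first.
#'
#' @param candidates an [Biostrings::AAStringSet].
#' @param ref_annot a [reference_annotation()].
#' @param cleavage optional named integer vector (id -> cleavage position).
#' @param hset a [hydrophobic_set()].
#' @param params an [align_params()].
#' @return list of class `feature_set`: `annotations` (list of
#'   `feature_annotation`) and `table` (one summary row per candidate).
#' @export
annotate_candidates <- function(candidates, ref_annot, cleavage = NULL,
                                hset = hydrophobic_set(),
                                params = align_params()) {
  candidates <- as_aa_set(candidates)
  ids <- record_ids(candidates)
  seqs <- as.character(candidates)
  annots <- vector("list", length(ids))
  names(annots) <- ids
  for (i in seq_along(ids)) {
    s <- seqs[i]
    cl <- 0L
    if (!is.null(cleavage) && ids[i] %in% names(cleavage)) {
      cl <- as.integer(cleavage[[ids[i]]])
      s <- strip_signal_peptide(s, cl)
    }
    a <- transfer_annotation(s, ref_annot, candidate_id = ids[i],
                             hset = hset, params = params)
    a$signal_len <- cl
    annots[[i]] <- a
  }
  tab <- do.call(rbind, lapply(annots, function(a) {
    data.frame(candidate = a$candidate_id,
               identity_percent = a$identity_percent,
               lid_start = a$lid_start, lid_end = a$lid_end,
               lid_hydrophobic_count = a$lid_hydrophobic_count,
               sequon_count = length(a$sequons),
               signal_len = a$signal_len,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(annotations = annots, table = tab), class = "feature_set")
}
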
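#' Screening configuration
#'
#' Configuration for the proteome screening stage: free-text keyword harvest,
#' exact-sequence de-duplication, and conserved-motif filtering. The defaults
#' reproduce the classical Candida rugosa-like family screen: headers
#' mentioning "esterase" or "lipase", and sequences carrying both the GESAG
#' catalytic shoulder and the GGGF oxyanion-hole motif.
#'
#' @param keywords lowercase keywords matched case-insensitively as substrings
#'   of the full description line (mirroring a portal free-text search).
#' @param motifs exact amino-acid motif strings (uppercase, standard alphabet).
#' @param require_all_motifs if `TRUE` (default) a record must contain every
#'   motif to survive; otherwise any one suffices.
#' @param dedup drop records with byte-identical residue strings before motif
#'   filtering.
#' @param dedup_first order of the dedup and motif stages in
#'   [screen_proteome()]: `TRUE` (default) de-duplicates first.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(keywords = c("esterase", "lipase"),
                          motifs = c("GESAG", "GGGF"),
                          require_all_motifs = TRUE,
                          dedup = TRUE,
                          dedup_first = TRUE) {
  motifs <- as.character(motifs)
  if (length(motifs) == 0L) stop("motifs must be non-empty", call. = FALSE)
  if (any(motifs != toupper(motifs))) {
    stop("motifs must be uppercase", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(paste(motifs, collapse = ""), "")[[1]]), AA20)
  if (length(bad) > 0L) {
    stop("motif alphabet outside the 20 standard amino acids: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(keywords = tolower(as.character(keywords)),
                 motifs = motifs,
                 require_all_motifs = isTRUE(require_all_motifs),
                 dedup = isTRUE(dedup),
                 dedup_first = isTRUE(dedup_first)),
            class = "screen_config")
}

#' Keyword harvest
#'
#' Keeps records whose description line contains any configured keyword,
#' case-insensitively, as a plain substring (no word boundaries), preserving
#' input order.
#'
#' @param records an [Biostrings::AAStringSet] (headers as names).
#' @param config a [screen_config()].
#' @return The surviving subset of `records`.
#' @export
keyword_harvest <- function(records, config = screen_config()) {
  records <- as_aa_set(records)
  if (length(config$keywords) == 0L) {
    stop("keyword list is empty: nothing to harvest", call. = FALSE)
  }
  desc <- tolower(names(records))
  keep <- Reduce(`|`, lapply(config$keywords, function(k) {
    grepl(k, desc, fixed = TRUE)
  }))
  records[keep]
}

#' Exact-sequence de-duplication
#'
#' Removes records whose residue strings are byte-identical to an earlier
#' record, keeping the first occurrence.
#'
#' @param records an [Biostrings::AAStringSet].
#' @return The surviving subset, with attribute `removed`: a data.frame
#'   mapping each removed id to the id of its kept representative.
#' @export
deduplicate <- function(records) {
  records <- as_aa_set(records)
  seqs <- as.character(records)
  ids <- record_ids(records)
  dup <- duplicated(seqs)
  rep_id <- ids[match(seqs, seqs)]  # first occurrence per sequence
  removed <- data.frame(removed_id = ids[dup],
                        kept_id = rep_id[dup],
                        stringsAsFactors = FALSE)
  out <- records[!dup]
  attr(out, "removed") <- removed
  out
}

#' Conserved-motif filter
#'
#' Retains records containing the configured motifs as exact substrings
#' (every motif when `require_all_motifs`, any motif otherwise) and records
#' all occurrence positions, overlaps included.
#'
#' @inheritParams keyword_harvest
#' @return An object of class `screen_result`: list with `records` (the
#'   survivors), `hits` (data.frame id/motif/pos over survivors, 1-based motif
#'   start positions) and `tallies`.
#' @export
motif_filter <- function(records, config = screen_config()) {
  records <- as_aa_set(records)
  ids <- record_ids(records)
  # presence per record *index*, robust to duplicate ids
  mh <- lapply(config$motifs, function(m) {
    Biostrings::startIndex(Biostrings::vmatchPattern(m, records,
                                                     fixed = TRUE))
  })
  present <- vapply(mh, function(s) lengths(s) > 0L, logical(length(records)))
  present <- matrix(present, nrow = length(records))
  keep <- if (config$require_all_motifs) {
    rowSums(present) == length(config$motifs)
  } else {
    rowSums(present) > 0L
  }
  survivors <- records[keep]
  hits <- do.call(rbind, lapply(seq_along(config$motifs), function(k) {
    starts <- mh[[k]][keep]
    n <- lengths(starts)
    data.frame(id = rep(ids[keep], n),
               motif = rep(config$motifs[k], sum(n)),
               pos = unlist(starts, use.names = FALSE) %||% integer(0),
               stringsAsFactors = FALSE)
  }))
  rownames(hits) <- NULL
  structure(list(records = survivors,
                 hits = hits,
                 tallies = c(scanned = length(records),
                             survivors = sum(keep))),
            class = "screen_result")
}

#' Full screening stage
#'
#' Chains keyword harvest, de-duplication and motif filtering in the
#' configured order, collecting per-stage tallies (monotone non-increasing
#' along the chain).
#'
#' @inheritParams keyword_harvest
#' @return A `screen_result` whose `tallies` cover every stage:
#'   `scanned`, `keyword`, `dedup`, `motif`.
#' @export
screen_proteome <- function(records, config = screen_config()) {
  records <- as_aa_set(records)
  n0 <- length(records)
  kw <- keyword_harvest(records, config)
  removed <- data.frame(removed_id = character(0), kept_id = character(0),
                        stringsAsFactors = FALSE)
  if (config$dedup && config$dedup_first) {
    kw2 <- deduplicate(kw)
    removed <- attr(kw2, "removed")
    kw <- kw2
  }
  res <- motif_filter(kw, config)
  if (config$dedup && !config$dedup_first) {
    surv <- deduplicate(res$records)
    removed <- attr(surv, "removed")
    res$hits <- res$hits[res$hits$id %in% record_ids(surv), , drop = FALSE]
    res$records <- surv
  }
  res$tallies <- c(scanned = n0,
                   keyword = length(kw) + if (config$dedup_first) nrow(removed) else 0L,
                   dedup = if (config$dedup && config$dedup_first) length(kw) else NA_integer_,
                   motif = length(res$records))
  res$removed <- removed
  res
}

#' Write a screening result as TSV
#'
#' One row per surviving record and motif occurrence: id, genome, motif,
#' 1-based start position. The genome is taken from a `genome=` header field
#' when present.
#'
#' @param result a `screen_result`.
#' @param path output TSV path.
#' @export
write_screen_tsv <- function(result, path) {
  genome <- header_field(result$records, "genome")
  gmap <- setNames(ifelse(is.na(genome), "NA", genome), record_ids(result$records))
  out <- data.frame(id = result$hits$id,
                    genome = unname(gmap[result$hits$id]),
                    motif = result$hits$motif,
                    position = result$hits$pos,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Proteome screen:", x$tallies[["scanned"]], "records scanned ->",
      length(x$records), "survivors\n")
  if (!is.null(x$tallies) && !is.na(x$tallies["keyword"])) {
    cat("  tallies:", paste(names(x$tallies), x$tallies, sep = "=",
                            collapse = ", "), "\n")
  }
  invisible(x)
}
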
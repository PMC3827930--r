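#' Assemble a labelled reference panel
#'
#' A reference panel is a set of family-labelled lipase/esterase records used
#' to anchor candidate placement. Families are read from a `family=` header
#' field and the versatile subset (enzymes active on both triglycerides and
#' sterol esters, e.g. the Candida rugosa Lip1-Lip5 / OPE set) from a
#' `versatile=yes` field.
#'
#' @param records an [Biostrings::AAStringSet] with `family=` (and optional
#'   `versatile=yes`) header fields.
#' @return list of class `reference_panel`: `records`, `family` (named
#'   character, id -> family), `versatile` (character ids).
#' @export
reference_panel <- function(records) {
  records <- as_aa_set(records)
  ids <- record_ids(records)
  fam <- header_field(records, "family")
  if (anyNA(fam)) {
    stop("panel records missing family= header field: ",
         paste(ids[is.na(fam)], collapse = ", "), call. = FALSE)
  }
  if (length(unique(fam)) < 2L) {
    stop("reference panel must contain at least 2 families", call. = FALSE)
  }
  vers <- ids[!is.na(header_field(records, "versatile")) &
                header_field(records, "versatile") == "yes"]
  if (length(vers) > 0L && !all(fam[match(vers, ids)] == "crugosa_like")) {
    stop("versatile subset must lie within the crugosa_like family",
         call. = FALSE)
  }
  structure(list(records = records,
                 family = setNames(fam, ids),
                 versatile = vers),
            class = "reference_panel")
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d))) {
    stop("distance matrix needs matching row/col taxon labels", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  invisible(TRUE)
}

#' Neighbor-joining tree
#'
#' Classic neighbor joining (Saitou-Nei with the Studier-Keppler Q-matrix and
#' branch lengths). Ties in the Q minimisation are broken deterministically:
#' the joined pair whose (lexicographically smallest member label, then other
#' label) sorts first wins. Negative branch lengths are clamped to zero with
#' the deficit added to the sister edge, preserving the path length between
#' the joined taxa. The result is an unrooted tree (trifurcation at the
#' arbitrary root node).
#'
#' @param d symmetric distance matrix with taxon labels (>= 3 taxa). Triangle
#'   violations are tolerated: alignment distances are not metric.
#' @return An [ape] `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  check_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  labels <- rownames(d)
  # each active node: newick fragment + representative (lexicographically
  # smallest contained leaf label) used only for tie-breaking
  nwk <- setNames(labels, labels)
  rep_lab <- setNames(labels, labels)
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_lab[rownames(D)[ij[1]]], rep_lab[rownames(D)[ij[2]]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    ni <- rownames(D)[i]; nj <- rownames(D)[j]
    new_lab <- paste0("_nj", m)
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[ni], li, nwk[nj], lj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], new_lab)
    D <- D2
    nwk <- c(nwk[rownames(D)[seq_len(length(keep))]], setNames(new_nwk, new_lab))
    rep_lab <- c(rep_lab[rownames(D)[seq_len(length(keep))]],
                 setNames(min(rep_lab[ni], rep_lab[nj]), new_lab))
  }
  la <- rownames(D)
  v <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
         (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
         (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  v <- pmax(v, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nwk[la[1]], v[1], nwk[la[2]], v[2], nwk[la[3]], v[3])
  ape::read.tree(text = txt)
}

# Tip labels below every node of a phylo tree (index = node number).
tips_below <- function(tree) {
  n <- length(tree$tip.label)
  res <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) res[[i]] <- tree$tip.label[i]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    res[[p]] <- c(res[[p]], res[[ch]])
  }
  res
}

#' Assign a candidate to a reference family
#'
#' Finds, over all edge-induced bipartitions of the unrooted tree, the
#' smallest side containing both the candidate and at least one panel
#' reference. If every reference in that side belongs to one family, that
#' family is returned; a mixed side yields `"unplaced"`.
#'
#' @param tree a `phylo` tree containing the candidate and panel tips.
#' @param panel a [reference_panel()].
#' @param candidate candidate tip label.
#' @return A family string or `"unplaced"`.
#' @export
assign_family <- function(tree, panel, candidate) {
  if (!candidate %in% tree$tip.label) {
    stop("candidate ", candidate, " is not a tip of the tree", call. = FALSE)
  }
  ref_ids <- names(panel$family)
  below <- tips_below(tree)
  all_tips <- tree$tip.label
  sides <- list()
  for (e in seq_len(nrow(tree$edge))) {
    s1 <- below[[tree$edge[e, 2L]]]
    s2 <- setdiff(all_tips, s1)
    side <- if (candidate %in% s1) s1 else s2
    sides[[length(sides) + 1L]] <- sort(side)
  }
  sides <- unique(sides)
  sides <- Filter(function(s) any(ref_ids %in% s), sides)
  if (length(sides) == 0L) return("unplaced")
  sz <- lengths(sides)
  minimal <- sides[sz == min(sz)]
  # every minimal side must agree on a single pure family; a candidate
  # sitting at the midpoint between two families' subtrees stays unplaced
  fams <- unique(unlist(lapply(minimal, function(s) {
    f <- unique(panel$family[intersect(ref_ids, s)])
    if (length(f) == 1L) f else "unplaced"
  })))
  if (length(fams) == 1L && fams != "unplaced") unname(fams) else "unplaced"
}

#' Place candidates against a reference panel
#'
#' Full placement stage: aligns candidates plus panel, builds the distance
#' matrix and NJ tree, assigns each candidate a family and ranks
#' crugosa_like candidates by mean alignment distance to the versatile
#' subset.
#'
#' @param candidates candidate records ([Biostrings::AAStringSet]).
#' @param panel a [reference_panel()].
#' @param k number of top candidates to select (default 6).
#' @param params an [align_params()].
#' @return list of class `placement_result`: `tree` (phylo), `distances`
#'   (matrix), `table` (data.frame candidate/family/mean_dist_versatile/rank),
#'   `selected` (ids).
#' @export
place_candidates <- function(candidates, panel, k = 6L,
                             params = align_params()) {
  candidates <- as_aa_set(candidates)
  cand_ids <- record_ids(candidates)
  all_rec <- c(candidates, panel$records)
  d <- build_distance_matrix(all_rec, params)
  tree <- neighbor_joining(d)
  fam <- vapply(cand_ids, function(id) assign_family(tree, panel, id),
                character(1))
  mean_dist <- vapply(cand_ids, function(id) {
    mean(d[id, panel$versatile])
  }, numeric(1))
  tab <- data.frame(candidate = cand_ids,
                    family = unname(fam),
                    mean_dist_versatile = unname(mean_dist),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$mean_dist_versatile, tab$candidate), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  res <- structure(list(tree = tree, distances = d, table = tab),
                   class = "placement_result")
  res$selected <- select_top_candidates(res, k)
  res
}

#' Select the top candidates closest to the versatile set
#'
#' Among candidates assigned to the crugosa_like family, returns the `k` ids
#' with the smallest mean distance to the versatile subset (stable
#' lexicographic tie-break). If fewer than `k` qualify, all are returned with
#' a warning.
#'
#' @param placement a `placement_result`.
#' @param k number of candidates to keep (>= 1).
#' @return Character vector of candidate ids, best first.
#' @export
select_top_candidates <- function(placement, k) {
  stopifnot(k >= 1L)
  tab <- placement$table
  placed <- tab[tab$family == "crugosa_like", , drop = FALSE]
  placed <- placed[order(placed$mean_dist_versatile, placed$candidate), ,
                   drop = FALSE]
  if (nrow(placed) < k) {
    warning("only ", nrow(placed), " placed candidates available (k = ", k,
            "); returning all", call. = FALSE)
    return(placed$candidate)
  }
  placed$candidate[seq_len(k)]
}

#' @export
print.placement_result <- function(x, ...) {
  cat("Family placement of", nrow(x$table), "candidates;",
      sum(x$table$family == "crugosa_like"), "grouped crugosa_like\n")
  print(utils::head(x$table, 10))
  invisible(x)
}
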
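# Shared fixtures, built once per test run.

# the deterministic synthetic reference panel (default seed)
panel_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_reference_panel()
    cache
  }
})

# mature chains of the panel's crugosa_like members, as a named character
mature_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- panel_fixture()
      seqs <- as.character(sp$records)
      names(seqs) <- sub("\\s.*$", "", names(sp$records))
      ids <- names(sp$cleavage)[grepl("^SYN_(LIP|OPE|MALB)", names(sp$cleavage))]
      cache <<- vapply(ids, function(id) {
        strip_signal_peptide(seqs[[id]], sp$cleavage[[id]])
      }, character(1))
    }
    cache
  }
})

# a small straight toy structure reused across structure tests
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_structure(toy_structure_spec(seed = 3L))
    cache
  }
})

# independent exhaustive global-alignment oracle: enumerates every monotone
# alignment path and scores it directly (gap of length k costs
# open + k * extend, end gaps included), no dynamic programming
oracle_align_score <- function(a, b, sub, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  score_moves <- function(moves) {
    s <- 0
    i <- 0L; j <- 0L
    run <- ""  # current gap-run type
    for (mv in moves) {
      if (mv == "D") {
        i <- i + 1L; j <- j + 1L
        s <- s + sub[ca[i], cb[j]]
        run <- ""
      } else {
        if (mv != run) s <- s - open
        s <- s - ext
        run <- mv
        if (mv == "U") i <- i + 1L else j <- j + 1L
      }
    }
    s
  }
  recurse <- function(i, j, moves) {
    if (i == n && j == m) {
      best <<- max(best, score_moves(moves))
      return(invisible(NULL))
    }
    if (i < n && j < m) recurse(i + 1L, j + 1L, c(moves, "D"))
    if (i < n) recurse(i + 1L, j, c(moves, "U"))
    if (j < m) recurse(i, j + 1L, c(moves, "L"))
  }
  recurse(0L, 0L, character(0))
  best
}

# brute-force overlapping substring scan (independent of vmatchPattern)
scan_positions <- function(seq, motif) {
  g <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  if (g[1] == -1L) integer(0) else as.integer(g)
}

# random AA sequence helper
rand_seq <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H", "I",
                                     "K", "L", "M", "N", "P", "Q", "R", "S",
                                     "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# proper random rotation + translation applied to a protein_structure
rigid_transform <- function(st, seed = 1L) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3)
  Rz <- matrix(c(cos(th[2]), sin(th[2]), 0, -sin(th[2]), cos(th[2]), 0,
                 0, 0, 1), 3)
  X <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% (Rx %*% Rz)
  X <- sweep(X, 2, runif(3, -30, 30), `+`)
  st$atoms$x <- X[, 1]; st$atoms$y <- X[, 2]; st$atoms$z <- X[, 3]
  st
}
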
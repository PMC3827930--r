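#' Tunnel detection parameters
#'
#' Settings for the simplified grid/BFS tunnel finder. A voxel is free when
#' its center lies farther than `atom_radius + probe_radius` from every atom
#' center (united-atom radius 1.7 Angstrom, water probe 1.4). A free voxel is
#' "bulk solvent" when that clearance additionally exceeds `bulk_margin`;
#' tunnels run from the catalytic-seed voxel to the first bulk voxel.
#'
#' @param grid_step voxel edge in Angstrom (default 0.8).
#' @param probe_radius probe radius (default 1.4, water).
#' @param atom_radius united-atom radius applied to every atom (default 1.7).
#' @param max_tunnels maximum number of tunnels returned (default 2).
#' @param bulk_margin extra clearance defining bulk solvent (default 1.2).
#' @param mouth_sep minimum Euclidean separation between tunnel mouths
#'   (default 8).
#' @param box_margin padding around the atom bounding box (default 4).
#' @param max_seed_dist maximum distance from the seed reference atom to the
#'   nearest free voxel; farther means no cavity at the seed (default 4.5).
#' @param canonical_frame voxelize in the structure's PCA frame so results
#'   are exactly invariant to rigid motions (default TRUE).
#' @return list of class `tunnel_params`.
#' @export
tunnel_params <- function(grid_step = 0.8, probe_radius = 1.4,
                          atom_radius = 1.7, max_tunnels = 2L,
                          bulk_margin = 1.2, mouth_sep = 8,
                          box_margin = 4, max_seed_dist = 4.5,
                          canonical_frame = TRUE) {
  stopifnot(grid_step > 0, probe_radius > 0, atom_radius > 0,
            max_tunnels >= 1L)
  structure(list(grid_step = grid_step, probe_radius = probe_radius,
                 atom_radius = atom_radius, max_tunnels = as.integer(max_tunnels),
                 bulk_margin = bulk_margin, mouth_sep = mouth_sep,
                 box_margin = box_margin, max_seed_dist = max_seed_dist,
                 canonical_frame = isTRUE(canonical_frame)),
            class = "tunnel_params")
}

# Deterministic canonical frame anchored in the data itself, so it commutes
# with proper rigid motions: first axis = leading covariance eigenvector,
# sign fixed by the coordinate skewness along it (falls back to the farthest
# atom when the distribution is symmetric); second axis points at the atom
# farthest from the first axis; third completes a right-handed frame.
# Near-spherical atom clouds with a degenerate leading eigenvalue remain
# frame-unstable; the package's toy structures are strongly elongated.
canonical_rotation <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X))
  e <- eigen(cov(Xc), symmetric = TRUE)
  v1 <- e$vectors[, 1]
  s <- sum((Xc %*% v1)^3)
  if (abs(s) < 1e-8) {
    far <- which.max(rowSums(Xc^2))
    s <- sum(Xc[far, ] * v1)
  }
  if (s < 0) v1 <- -v1
  t1 <- as.vector(Xc %*% v1)
  perp <- Xc - outer(t1, v1)
  far <- which.max(rowSums(perp^2))
  v2 <- perp[far, ]
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  cbind(v1, v2, v3)
}

# Min distance from each row of `pts` to the atom centers (atom loop keeps
# memory flat).
nearest_atom_dist <- function(pts, atoms) {
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(atoms))) {
    d2 <- pmin(d2, (pts[, 1] - atoms[i, 1])^2 +
                 (pts[, 2] - atoms[i, 2])^2 +
                 (pts[, 3] - atoms[i, 3])^2)
  }
  sqrt(d2)
}

# Re-centre path points toward the local medial axis: greedy clearance
# maximisation, displacement capped so points cannot slide along the tunnel.
recentre_path <- function(pts, atoms, max_shift) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- pts
  for (i in seq_len(nrow(pts))) {
    p0 <- pts[i, ]
    p <- p0
    best <- nearest_atom_dist(rbind(p), atoms)
    for (step in c(0.3, 0.15, 0.05)) {
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (k in 1:6) {
          q <- p + step * dirs[k, ]
          if (sqrt(sum((q - p0)^2)) > max_shift) next
          dq <- nearest_atom_dist(rbind(q), atoms)
          if (dq > best + 1e-9) {
            p <- q; best <- dq; improved <- TRUE
          }
        }
      }
    }
    out[i, ] <- p
  }
  out
}

# Centered moving average over interior points (endpoints fixed): removes
# the 6-connected staircase zigzag that would inflate arc length.
smooth_path <- function(pts, window = 3L, passes = 1L) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  half <- window %/% 2L
  for (p in seq_len(passes)) {
    out <- pts
    for (i in 2:(n - 1L)) {
      j <- max(1L, i - half):min(n, i + half)
      out[i, ] <- colMeans(pts[j, , drop = FALSE])
    }
    pts <- out
  }
  pts
}

# Drop interior points lying within `tol` of the chord of their neighbours.
elide_collinear <- function(pts, tol = 0.01) {
  if (nrow(pts) <= 2L) return(pts)
  keep <- rep(TRUE, nrow(pts))
  last <- 1L
  for (i in 2:(nrow(pts) - 1L)) {
    a <- pts[last, ]; b <- pts[i + 1L, ]; p <- pts[i, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    d <- sqrt(sum((p - (a + t * ab))^2))
    if (d < tol) keep[i] <- FALSE else last <- i
  }
  pts[keep, , drop = FALSE]
}

path_arc_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Detect intramolecular tunnels from a seed residue
#'
#' Simplified Caver-like tunnel detection: the structure's bounding box
#' (plus margin) is voxelized; free voxels are those whose centers clear
#' every atom by more than `atom_radius + probe_radius`; a breadth-first
#' search starts at the free voxel nearest the seed residue's reference atom
#' (OG if present, else CA) and runs until it reaches bulk solvent. Distinct
#' tunnels are shortest BFS paths to mouths separated by more than
#' `mouth_sep`; centerlines are re-centred by local clearance maximisation
#' and smoothed by collinear-point elision. Tunnels are ranked by bottleneck
#' radius, then arc length.
#'
#' @param structure a [read_structure()] object.
#' @param seed_residue residue number (resseq) or residue id (e.g. `"A12"`)
#'   of the catalytic serine.
#' @param params a [tunnel_params()].
#' @return list of class `tunnel_set`; each element is a `tunnel`: list with
#'   `centerline` (points in the input frame), `radii` (per-point bottleneck
#'   radius), `mouth`, `arc_length`, `straightness`, `bottleneck`,
#'   `seed_residue`. Empty list (still `tunnel_set`) when the seed has no
#'   path to the surface.
#' @export
find_tunnels <- function(structure, seed_residue, params = tunnel_params()) {
  atoms_df <- structure$atoms
  sel <- if (is.numeric(seed_residue)) {
    atoms_df$resseq == seed_residue
  } else {
    atoms_df$resid == as.character(seed_residue)
  }
  if (!any(sel)) {
    stop("seed residue ", seed_residue, " not present in structure",
         call. = FALSE)
  }
  seed_atoms <- atoms_df[sel, , drop = FALSE]
  ref_row <- if ("OG" %in% seed_atoms$name) {
    seed_atoms[seed_atoms$name == "OG", , drop = FALSE][1, ]
  } else if ("CA" %in% seed_atoms$name) {
    seed_atoms[seed_atoms$name == "CA", , drop = FALSE][1, ]
  } else {
    seed_atoms[1, ]
  }
  X <- atom_coords(structure)
  c0 <- colMeans(X)
  R <- if (params$canonical_frame) canonical_rotation(X) else diag(3)
  Y_all <- sweep(X, 2L, c0) %*% R
  # the seed residue's own atoms line the pocket mouth; they are excluded
  # from the obstacle model so the search can start beside the catalytic Ser
  Y <- Y_all[!sel, , drop = FALSE]
  if (nrow(Y) == 0L) stop("structure has no non-seed atoms", call. = FALSE)
  seed_pt <- as.numeric((c(ref_row$x, ref_row$y, ref_row$z) - c0) %*% R)

  h <- params$grid_step
  lo <- apply(Y, 2L, min) - params$box_margin
  hi <- apply(Y, 2L, max) + params$box_margin
  nx <- as.integer(ceiling((hi[1] - lo[1]) / h)) + 1L
  ny <- as.integer(ceiling((hi[2] - lo[2]) / h)) + 1L
  nz <- as.integer(ceiling((hi[3] - lo[3]) / h)) + 1L
  nvox <- as.double(nx) * ny * nz
  if (nvox > 6e6) {
    stop("voxel grid too large (", format(nvox, big.mark = ","),
         " voxels); increase grid_step", call. = FALSE)
  }
  gx <- lo[1] + h * (seq_len(nx) - 1L)
  gy <- lo[2] + h * (seq_len(ny) - 1L)
  gz <- lo[3] + h * (seq_len(nz) - 1L)
  centers <- cbind(rep(gx, times = ny * nz),
                   rep(rep(gy, each = nx), times = nz),
                   rep(gz, each = nx * ny))
  clearance <- nearest_atom_dist(centers, Y)
  block_r <- params$atom_radius + params$probe_radius
  free <- clearance > block_r
  bulk <- clearance > block_r + params$bulk_margin

  empty <- base::structure(list(), class = "tunnel_set")
  free_idx <- which(free)
  if (length(free_idx) == 0L) return(empty)
  d2seed <- (centers[free_idx, 1] - seed_pt[1])^2 +
    (centers[free_idx, 2] - seed_pt[2])^2 +
    (centers[free_idx, 3] - seed_pt[3])^2
  if (min(d2seed) > params$max_seed_dist^2) return(empty)
  start <- free_idx[which.min(d2seed)]

  # BFS over the 6-neighbourhood of free voxels
  nxy <- nx * ny
  ix <- ((start - 1L) %% nx) + 1L
  iy <- (((start - 1L) %/% nx) %% ny) + 1L
  iz <- ((start - 1L) %/% nxy) + 1L
  parent <- integer(nvox)
  visited <- logical(nvox)
  visited[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0L) {
    cand <- integer(0)
    par <- integer(0)
    fx <- ((frontier - 1L) %% nx) + 1L
    fy <- (((frontier - 1L) %/% nx) %% ny) + 1L
    fz <- ((frontier - 1L) %/% nxy) + 1L
    for (s in list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                   c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))) {
      qx <- fx + s[1]; qy <- fy + s[2]; qz <- fz + s[3]
      ok <- qx >= 1L & qx <= nx & qy >= 1L & qy <= ny & qz >= 1L & qz <= nz
      q <- (qz[ok] - 1L) * nxy + (qy[ok] - 1L) * nx + qx[ok]
      good <- free[q] & !visited[q]
      cand <- c(cand, q[good])
      par <- c(par, frontier[ok][good])
    }
    if (length(cand) > 0L) {
      first <- !duplicated(cand)
      cand <- cand[first]
      par <- par[first]
      visited[cand] <- TRUE
      parent[cand] <- par
    }
    frontier <- cand
  }

  # mouths: bulk voxels first entered from a non-bulk voxel; the "portal"
  # (that non-bulk parent) sits inside the bore and is what separates
  # distinct mouths - bulk voxels of one mouth fan out laterally
  reached_bulk <- which(visited & bulk)
  entries <- reached_bulk[parent[reached_bulk] > 0L &
                            !bulk[parent[reached_bulk]]]
  portals <- parent[entries]
  if (length(entries) == 0L) {
    # fallback: grid-boundary voxels reached by the search
    bx <- ((which(visited) - 1L) %% nx) + 1L
    by <- (((which(visited) - 1L) %/% nx) %% ny) + 1L
    bz <- ((which(visited) - 1L) %/% nxy) + 1L
    onb <- bx == 1L | bx == nx | by == 1L | by == ny | bz == 1L | bz == nz
    entries <- which(visited)[onb]
    portals <- entries
  }
  if (length(entries) == 0L) return(empty)

  backtrack <- function(v) {
    path <- v
    while (v != start) {
      v <- parent[v]
      path <- c(v, path)
    }
    path
  }
  # surface voxels: free voxels within 2 voxels (Chebyshev) of bulk solvent;
  # every path is truncated at its first surface contact (the mouth), which
  # collapses paths that creep around the outside of the structure onto the
  # genuine mouth
  barr <- array(bulk, dim = c(nx, ny, nz))
  dil <- barr
  sh <- function(a, d, k) {
    # shift array `a` along dim d by k, zero(FALSE)-filled
    out <- array(FALSE, dim = dim(a))
    n <- dim(a)[d]
    if (abs(k) >= n) return(out)
    src <- if (k >= 0) 1:(n - k) else (1 - k):n
    dst <- if (k >= 0) (1 + k):n else 1:(n + k)
    ix <- list(1:nx, 1:ny, 1:nz)
    ixs <- ix; ixs[[d]] <- src
    ixd <- ix; ixd[[d]] <- dst
    out[ixd[[1]], ixd[[2]], ixd[[3]]] <- a[ixs[[1]], ixs[[2]], ixs[[3]]]
    out
  }
  for (d in 1:3) {
    acc <- dil
    for (k in c(-2L, -1L, 1L, 2L)) acc <- acc | sh(dil, d, k)
    dil <- acc
  }
  surface <- as.vector(dil) & free
  paths <- lapply(entries, function(v) {
    p <- backtrack(v)
    hit <- which(surface[p])
    if (length(hit) > 0L) p[seq_len(hit[1])] else p
  })
  portals <- vapply(paths, function(p) p[length(p)], integer(1))
  plen <- lengths(paths)
  ord <- order(plen)
  portal_xyz <- centers[portals, , drop = FALSE]
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) == params$max_tunnels) break
    if (all(vapply(chosen, function(j) {
      sqrt(sum((portal_xyz[i, ] - portal_xyz[j, ])^2)) > params$mouth_sep
    }, logical(1)))) {
      chosen <- c(chosen, i)
    }
  }

  tunnels <- lapply(chosen, function(i) {
    pts <- centers[paths[[i]], , drop = FALSE]
    pts <- recentre_path(pts, Y, max_shift = 2.5 * h)
    pts <- smooth_path(pts)
    # second, tightly-capped pass: smoothing drags high-curvature points
    # (e.g. an elbow) off the medial axis; pull them back
    pts <- recentre_path(pts, Y, max_shift = 0.6 * h)
    pts <- elide_collinear(pts)
    radii <- nearest_atom_dist(pts, Y) - params$atom_radius
    arc <- path_arc_length(pts)
    stra <- if (arc > 0) {
      sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)) / arc
    } else {
      1
    }
    back <- sweep(pts %*% t(R), 2L, c0, `+`)  # back to the input frame
    base::structure(list(centerline = back,
                   radii = radii,
                   mouth = back[nrow(back), ],
                   arc_length = arc,
                   straightness = stra,
                   bottleneck = min(radii),
                   seed_residue = seed_residue),
              class = "tunnel")
  })
  ord2 <- order(-vapply(tunnels, `[[`, numeric(1), "bottleneck"),
                vapply(tunnels, `[[`, numeric(1), "arc_length"))
  base::structure(tunnels[ord2], class = "tunnel_set")
}

#' @export
print.tunnel_set <- function(x, ...) {
  cat("tunnel_set with", length(x), "tunnel(s)\n")
  for (i in seq_along(x)) {
    t <- x[[i]]
    cat(sprintf("  [%d] arc %.1f A, bottleneck %.2f A, straightness %.3f\n",
                i, t$arc_length, t$bottleneck, t$straightness))
  }
  invisible(x)
}

#' Score tunnel-lining hydrophobicity
#'
#' Lining residues are those with any atom within `cutoff` (default 4
#' Angstrom) of any centerline point, pooled over all supplied tunnels (the
#' per-structure "tunnels area"). The hydrophobic fraction is the rounded
#' percentage of lining residues whose one-letter code belongs to the
#' hydrophobic set.
#'
#' @param structure a [read_structure()] object.
#' @param tunnels a `tunnel_set` or single `tunnel` from [find_tunnels()].
#' @param hset a [hydrophobic_set()].
#' @param cutoff lining distance in Angstrom (default 4.0).
#' @return list of class `tunnel_score`: `lining` data.frame (resid,
#'   resname, resseq, min_dist, hydrophobic), `n_lining`, `n_hydrophobic`,
#'   `fraction` (integer percent), `shape_class` (of the best tunnel).
#' @export
score_tunnel <- function(structure, tunnels, hset = hydrophobic_set(),
                         cutoff = 4.0) {
  if (inherits(tunnels, "tunnel")) tunnels <- list(tunnels)
  if (length(tunnels) == 0L) {
    stop("empty tunnel set: nothing to score", call. = FALSE)
  }
  atoms <- structure$atoms
  X <- atom_coords(structure)
  # distance to the centerline polyline (continuous, robust to the
  # collinear-point elision of the stored centerline)
  dmin <- rep(Inf, nrow(X))
  for (tn in tunnels) {
    dmin <- pmin(dmin, dist_to_polyline(X, tn$centerline))
  }
  per_res <- tapply(dmin, atoms$resid, min)
  lining_ids <- names(per_res)[per_res <= cutoff]
  info <- atoms[!duplicated(atoms$resid), c("resid", "resname", "resseq")]
  info <- info[match(lining_ids, info$resid), , drop = FALSE]
  letter <- unname(AA3TO1[info$resname])
  hydro <- !is.na(letter) & letter %in% hset
  lining <- data.frame(resid = info$resid, resname = info$resname,
                       resseq = info$resseq,
                       min_dist = unname(per_res[lining_ids]),
                       hydrophobic = hydro,
                       stringsAsFactors = FALSE)
  lining <- lining[order(lining$min_dist), , drop = FALSE]
  rownames(lining) <- NULL
  n <- nrow(lining)
  nh <- sum(lining$hydrophobic)
  base::structure(list(lining = lining,
                 n_lining = n,
                 n_hydrophobic = nh,
                 fraction = hydrophobic_fraction(nh, n),
                 shape_class = if (length(tunnels) > 0L)
                   classify_shape(tunnels[[1]]) else NA_character_),
            class = "tunnel_score")
}

#' Hydrophobic lining fraction as a rounded percent
#'
#' @param n_hydrophobic,n_total hydrophobic and total lining residue counts.
#' @return Integer percent `round(100 * n_hydrophobic / n_total)`.
#' @export
#' @examples
#' hydrophobic_fraction(13, 22) # 59
#' hydrophobic_fraction(8, 22)  # 36
hydrophobic_fraction <- function(n_hydrophobic, n_total) {
  stopifnot(n_hydrophobic <= n_total)
  if (n_total == 0L) return(NA_integer_)
  as.integer(round(100 * n_hydrophobic / n_total))
}

#' Classify tunnel shape
#'
#' A tunnel is `"straight"` when its straightness (end-to-end distance over
#' arc length) reaches the threshold, `"bent"` otherwise. The default 0.85
#' separates a straight exit tunnel from a bent one (a 90-degree bend has
#' straightness sqrt(2)/2 = 0.707).
#'
#' @param tunnel a `tunnel`.
#' @param threshold straightness threshold (default 0.85).
#' @return `"straight"` or `"bent"`.
#' @export
classify_shape <- function(tunnel, threshold = 0.85) {
  if (tunnel$straightness >= threshold) "straight" else "bent"
}

#' Write a tunnel centerline as a pseudo-atom PDB
#'
#' Produces HETATM pseudo-atoms along the centerline, loadable next to the
#' parent structure in a molecular viewer.
#'
#' @param tunnel a `tunnel`.
#' @param path output path.
#' @export
write_tunnel_pdb <- function(tunnel, path) {
  p <- tunnel$centerline
  lines <- vapply(seq_len(nrow(p)), function(i) {
    sprintf("HETATM%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, " O  ", " ", "TUN", "T", i, " ",
            p[i, 1], p[i, 2], p[i, 3], 1.00, 0.00, " O")
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
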
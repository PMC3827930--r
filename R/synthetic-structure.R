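#' Toy structure specification
#'
#' Describes a CA-only shell around a hollow straight or bent axis, standing
#' in for a homology model when testing tunnel detection. `tunnel_radius` is
#' the bore radius measured to the shell atoms' van der Waals surface (shell
#' ring radius = tunnel_radius + 1.7 Angstrom united-atom radius), so a
#' 1.4 Angstrom water probe passes exactly when `tunnel_radius >= 1.4`. The
#' default 2.1 leaves a guaranteed free axial corridor on the default
#' 0.8 Angstrom voxel grid.
#'
#' @param n_shell_residues approximate total number of shell CA residues.
#' @param tunnel_radius bore radius in Angstrom (>= 1.4).
#' @param tunnel_length total axis arc length in Angstrom.
#' @param bend_angle bend of the axis in degrees, 0-120; 0 = straight. A bent
#'   axis has two equal-length segments.
#' @param seed_residue residue name given to the pseudo catalytic Ser placed
#'   at the buried axis end (default `"SER"`).
#' @param lattice_jitter SD in Angstrom of Gaussian jitter on shell atoms.
#' @param seed integer RNG seed.
#' @param open_both_ends leave both axis ends open (two mouths); the seed
#'   residue then sits at the axis midpoint.
#' @param resname_pool residue names sampled for non-seed shell residues.
#' @return list of class `toy_structure_spec`.
#' @export
toy_structure_spec <- function(n_shell_residues = 170L, tunnel_radius = 2.1,
                               tunnel_length = 20, bend_angle = 0,
                               seed_residue = "SER", lattice_jitter = 0.05,
                               seed = 1L, open_both_ends = FALSE,
                               resname_pool = c("LEU", "ALA", "VAL", "PHE",
                                                "ILE", "SER", "THR", "ASP",
                                                "LYS", "GLY", "ASN", "GLU")) {
  if (tunnel_radius < 1.4) {
    stop("tunnel_radius must be >= 1.4 (probe passable)", call. = FALSE)
  }
  if (bend_angle < 0 || bend_angle > 120) {
    stop("bend_angle must lie in [0, 120] degrees", call. = FALSE)
  }
  if (tunnel_length < 6) stop("tunnel_length too short", call. = FALSE)
  structure(list(n_shell_residues = as.integer(n_shell_residues),
                 tunnel_radius = tunnel_radius,
                 tunnel_length = tunnel_length,
                 bend_angle = bend_angle,
                 seed_residue = seed_residue,
                 lattice_jitter = lattice_jitter,
                 seed = as.integer(seed),
                 open_both_ends = isTRUE(open_both_ends),
                 resname_pool = resname_pool),
            class = "toy_structure_spec")
}

# Axis polyline for a spec: vertices of one segment (straight) or two equal
# segments meeting at bend_angle.
toy_axis <- function(spec) {
  L <- spec$tunnel_length
  if (spec$bend_angle == 0) {
    rbind(c(0, 0, 0), c(L, 0, 0))
  } else {
    th <- spec$bend_angle * pi / 180
    a <- c(L / 2, 0, 0)
    rbind(c(0, 0, 0), a, a + (L / 2) * c(cos(th), sin(th), 0))
  }
}

# Minimum distance from each row of `pts` to a polyline given by vertex
# matrix `verts`.
dist_to_polyline <- function(pts, verts) {
  if (nrow(verts) == 1L) {
    return(sqrt(rowSums(sweep(pts, 2L, verts[1, ])^2)))
  }
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(verts) - 1L)) {
    a <- verts[s, ]; b <- verts[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2L, a)
    t <- pmin(pmax((ap %*% ab) / len2, 0), 1)
    proj <- sweep(outer(as.vector(t), ab), 2L, a, `+`)
    dmin <- pmin(dmin, sqrt(rowSums((pts - proj)^2)))
  }
  dmin
}

# Arc-length parameterised point + perpendicular frame on the axis.
axis_point_frame <- function(spec, t) {
  verts <- toy_axis(spec)
  seg_len <- sqrt(rowSums((verts[-1, , drop = FALSE] -
                             verts[-nrow(verts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg_len))
  tc <- min(max(t, cum[1] - 10), cum[length(cum)] + 10)
  s <- findInterval(min(max(t, 0), cum[length(cum)] - 1e-9), cum,
                    rightmost.closed = TRUE)
  s <- min(max(s, 1L), nrow(verts) - 1L)
  d <- (verts[s + 1L, ] - verts[s, ]) / seg_len[s]
  p <- verts[s, ] + (t - cum[s]) * d
  u <- c(-d[2], d[1], 0)
  if (sum(u^2) < 1e-12) u <- c(0, 1, 0)
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(p = p, d = d, u = u, v = v)
}

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z) {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", name), " ", resname, chain, resseq, " ",
          x, y, z, 1.00, 0.00, " C")
}

#' Generate a toy structure with a known tunnel
#'
#' Builds CA-only shell coordinates around a hollow straight or bent axis.
#' The buried axis end is closed by extension rings and a cap (unless
#' `open_both_ends`); the other end is the tunnel mouth. Ground truth:
#' lining residues are those whose CA lies within 4 Angstrom of the axis
#' polyline (computed by exact point-to-segment distances), and straightness
#' is end-to-end distance over arc length of the axis.
#'
#' @param spec a [toy_structure_spec()].
#' @return list of class `toy_structure`: `pdb` (PDB-format text, CA-only
#'   ATOM records, chain A, sequential 1-based residue numbers), `structure`
#'   (parsed [read_structure()] object), `lining` (ground-truth residue
#'   numbers), `straightness` (ground truth), `axis` (vertex matrix),
#'   `seed_resseq` (residue number of the pseudo catalytic Ser), `spec`.
#' @export
generate_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_structure_spec"))
  atom_radius <- 1.7
  shell_radius <- spec$tunnel_radius + atom_radius
  ring_spacing <- 1.5
  with_seed(spec$seed, {
    axis <- toy_axis(spec)
    arc <- spec$tunnel_length
    ts <- seq(0, arc, by = ring_spacing)
    n_rings <- length(ts)
    per_ring <- max(8L, round(spec$n_shell_residues / n_rings))
    pts <- list()
    ring_points <- function(center, d, radius, m) {
      u <- c(-d[2], d[1], 0)
      if (sum(u^2) < 1e-12) u <- c(0, 1, 0)
      u <- u / sqrt(sum(u^2))
      v <- c(d[2] * u[3] - d[3] * u[2],
             d[3] * u[1] - d[1] * u[3],
             d[1] * u[2] - d[2] * u[1])
      phase <- runif(1, 0, 2 * pi)
      ang <- phase + 2 * pi * seq_len(m) / m
      r <- radius + rnorm(m, 0, spec$lattice_jitter)
      t(vapply(seq_len(m), function(k) {
        center + r[k] * (cos(ang[k]) * u + sin(ang[k]) * v) +
          rnorm(3, 0, spec$lattice_jitter) * 0.5
      }, numeric(3)))
    }
    add_ring <- function(t, radius = shell_radius, m = per_ring) {
      fr <- axis_point_frame(spec, t)
      pts[[length(pts) + 1L]] <<- ring_points(fr$p, fr$d, radius, m)
    }
    for (t in ts) add_ring(t)
    if (spec$bend_angle > 0) {
      # miter joint: fan of rings at the elbow vertex, directions rotated
      # between the two segment axes; bore-intruding atoms culled below
      th <- spec$bend_angle * pi / 180
      vtx <- axis[2, ]
      alphas <- seq(0, th, length.out = max(3L, ceiling(th / 0.25)))
      for (a in alphas) {
        da <- c(cos(a), sin(a), 0)
        pts[[length(pts) + 1L]] <- ring_points(vtx, da, shell_radius, per_ring)
      }
    }
    if (!spec$open_both_ends) {
      # extension rings walling off the buried end, then a cap disk
      add_ring(-1.5)
      add_ring(-3.0)
      fr <- axis_point_frame(spec, -3.8)
      cap <- rbind(fr$p,
                   t(vapply(seq_len(6L), function(k) {
                     a <- 2 * pi * k / 6
                     fr$p + (shell_radius / 2) *
                       (cos(a) * c(0, 1, 0) + sin(a) * c(0, 0, 1))
                   }, numeric(3))))
      pts[[length(pts) + 1L]] <- cap
    }
    coords <- do.call(rbind, pts)
    n_cap <- if (spec$open_both_ends) 0L else 7L
    # cull atoms intruding into the bore (miter fans overlap the axis side);
    # the cap disk is exempt, it deliberately sits on the extended axis
    ext_axis <- rbind(axis[1, ] - 3.2 * c(1, 0, 0), axis)
    keep <- dist_to_polyline(coords, ext_axis) >= shell_radius - 0.45
    if (n_cap > 0L) keep[(nrow(coords) - n_cap + 1L):nrow(coords)] <- TRUE
    coords <- coords[keep, , drop = FALSE]
    # seed residue (pseudo catalytic Ser) sits on the axis itself: at the
    # buried end, or at the midpoint when both ends are open; the finder
    # excludes the seed residue from its obstacle model
    seed_xyz <- if (spec$open_both_ends) {
      axis_point_frame(spec, arc / 2)$p
    } else {
      axis[1, ]
    }
    coords <- rbind(seed_xyz, coords)
    n <- nrow(coords)
    seed_idx <- 1L
    resnames <- sample(spec$resname_pool, n, replace = TRUE)
    resnames[seed_idx] <- spec$seed_residue
    lines <- vapply(seq_len(n), function(i) {
      pdb_atom_line(i, "CA", resnames[i], "A", i,
                    coords[i, 1], coords[i, 2], coords[i, 3])
    }, character(1))
    pdb <- paste(c(lines, "END"), collapse = "\n")
    d_axis <- dist_to_polyline(coords, axis)
    lining <- which(d_axis <= 4.0)
    straightness <- sqrt(sum((axis[nrow(axis), ] - axis[1, ])^2)) / arc
    if (length(lining) == 0L) {
      stop("degenerate toy: ground-truth lining set is empty", call. = FALSE)
    }
    structure(list(pdb = pdb,
                   structure = read_structure(pdb),
                   lining = as.integer(lining),
                   straightness = straightness,
                   axis = axis,
                   seed_resseq = as.integer(seed_idx),
                   spec = spec),
              class = "toy_structure")
  })
}
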
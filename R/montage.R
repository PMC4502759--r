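#' Electrode montage for the 33-channel modified 10/20 cap
#'
#' Builds the electrode montage used throughout the package: 33 electrodes of
#' the modified international 10/20 placement system (Fz, FPz, FP1, FP2, F3,
#' F4, F7, F8, FC1, FC2, FC5, FC6, Cz, CPz, C3, C4, CP1, CP2, CP5, CP6, Pz,
#' P3, P4, P7, P8, T7, T8, M1, M2, POz, Oz, O1, O2), with idealized positions
#' on the unit sphere, a nearest-neighbor adjacency derived from a Delaunay
#' triangulation, and an exclusion list (ear electrodes M1/M2 by default,
#' which are dropped from all analyses).
#'
#' Positions are computed from the idealized spherical 10/20 construction:
#' the head is a unit sphere with the vertex (Cz) at inclination 0 and the
#' nasion-inion / preauricular plane at inclination 90 degrees. The
#' circumferential ring (FPz, FP1/2, F7/8, T7/8, P7/8, O1/2, Oz) sits at
#' inclination 72 degrees; midline electrodes step by 18 degrees; interior
#' electrodes (F3/4, FC1/2, FC5/6, CP1/2, CP5/6, P3/4) are placed by
#' fractional interpolation along the spherical circle through their row's
#' endpoints and midline electrode. M1/M2 are placed just below the equator
#' near the ears; they carry no analysis weight because they are excluded.
#'
#' Adjacency is the edge set of a 2-D Delaunay triangulation of the
#' azimuthal-equidistant projection of the non-excluded electrodes, with
#' edges longer than `prune_factor` times the median great-circle edge length
#' removed. This yields a symmetric nearest-neighbor graph without any
#' electrode being its own neighbor.
#'
#' @param excluded Character vector of electrode labels dropped from analysis.
#' @param prune_factor Multiplier on the median great-circle edge length above
#'   which Delaunay edges are discarded.
#' @return An object of class `eeg_montage`: a list with `positions` (tibble
#'   with columns `label`, `x`, `y`, `z`), `adjacency` (named list of
#'   character vectors over non-excluded electrodes), and `excluded`.
#' @examples
#' mon <- default_montage()
#' nrow(mon$positions)     # 33 electrodes
#' length(mon$adjacency)   # 31 analyzable electrodes
#' @export
default_montage <- function(excluded = c("M1", "M2"), prune_factor = 1.6) {
  pos <- montage_positions_10_20()
  stopifnot(all(excluded %in% pos$label))
  mon <- structure(
    list(positions = pos, adjacency = NULL, excluded = excluded),
    class = "eeg_montage"
  )
  mon$adjacency <- montage_adjacency(mon, prune_factor = prune_factor)
  mon
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", nrow(x$positions), " electrodes (",
      length(montage_channels(x)), " analyzable; excluded: ",
      paste(x$excluded, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Analyzable channel labels of a montage
#'
#' @param montage An `eeg_montage`.
#' @return Character vector of non-excluded electrode labels, montage order.
#' @export
montage_channels <- function(montage) {
  setdiff(montage$positions$label, montage$excluded)
}

# Unit-sphere position from inclination (deg from vertex) and azimuth
# (deg from anterior midline, positive to the right).
# Axes: +x right ear, +y nasion, +z vertex.
sph_pos <- function(incl, az) {
  ti <- incl * pi / 180
  ta <- az * pi / 180
  c(x = sin(ti) * sin(ta), y = sin(ti) * cos(ta), z = cos(ti))
}

# Point at fraction `frac` (0 = start, 1 = end) of the spherical circle arc
# running start -> mid -> end; the three points define a plane whose
# intersection with the sphere is the circle the 10/20 row lies on.
arc_point <- function(p_start, p_mid, p_end, frac) {
  P <- rbind(p_start, p_mid, p_end)
  # circle center c satisfies (p_i - c) . n = 0 in-plane with equal radii;
  # solve |p_i|^2 - 2 p_i . c = const together with planarity
  n <- pracma_cross(P[2, ] - P[1, ], P[3, ] - P[1, ])
  n <- n / sqrt(sum(n^2))
  A <- rbind(2 * (P[2, ] - P[1, ]), 2 * (P[3, ] - P[1, ]), n)
  b <- c(sum(P[2, ]^2) - sum(P[1, ]^2), sum(P[3, ]^2) - sum(P[1, ]^2),
         sum(n * P[1, ]))
  ctr <- solve(A, b)
  u <- P[1, ] - ctr
  r <- sqrt(sum(u^2))
  u <- u / r
  v <- pracma_cross(n, u)
  ang <- function(p) {
    w <- p - ctr
    atan2(sum(w * v), sum(w * u))
  }
  a_mid <- ang(P[2, ])
  a_end <- ang(P[3, ])
  # orient the parameterization so the path start -> mid -> end is monotone
  if (a_mid < 0) { a_mid <- a_mid + 2 * pi; a_end <- a_end + 2 * pi }
  if (a_end < a_mid) a_end <- a_end + 2 * pi
  a <- frac * a_end
  p <- ctr + r * (cos(a) * u + sin(a) * v)
  p / sqrt(sum(p^2))  # numeric guard; the circle already lies on the sphere
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

montage_positions_10_20 <- function() {
  p <- list()
  # circumferential ring, inclination 72, azimuth from anterior midline
  ring <- c(FPz = 0, FP2 = 18, F8 = 54, T8 = 90, P8 = 126, O2 = 162,
            Oz = 180, O1 = -162, P7 = -126, T7 = -90, F7 = -54, FP1 = -18)
  for (lab in names(ring)) p[[lab]] <- sph_pos(72, ring[[lab]])
  # midline
  p$Fz  <- sph_pos(36, 0)
  p$Cz  <- sph_pos(0, 0)
  p$CPz <- sph_pos(18, 180)
  p$Pz  <- sph_pos(36, 180)
  p$POz <- sph_pos(54, 180)
  # central coronal arc (great circle): C3/C4 20% out from Cz
  p$C3 <- sph_pos(36, -90)
  p$C4 <- sph_pos(36, 90)
  # interior rows by arc interpolation (9 equally spaced sites -> 8 steps)
  fcz <- sph_pos(18, 0)
  ft7 <- sph_pos(72, -72); ft8 <- sph_pos(72, 72)
  tp7 <- sph_pos(72, -108); tp8 <- sph_pos(72, 108)
  p$F3  <- arc_point(p$F7, p$Fz, p$F8, 2 / 8)
  p$F4  <- arc_point(p$F7, p$Fz, p$F8, 6 / 8)
  p$FC5 <- arc_point(ft7, fcz, ft8, 1 / 8)
  p$FC1 <- arc_point(ft7, fcz, ft8, 3 / 8)
  p$FC2 <- arc_point(ft7, fcz, ft8, 5 / 8)
  p$FC6 <- arc_point(ft7, fcz, ft8, 7 / 8)
  p$CP5 <- arc_point(tp7, p$CPz, tp8, 1 / 8)
  p$CP1 <- arc_point(tp7, p$CPz, tp8, 3 / 8)
  p$CP2 <- arc_point(tp7, p$CPz, tp8, 5 / 8)
  p$CP6 <- arc_point(tp7, p$CPz, tp8, 7 / 8)
  p$P3  <- arc_point(p$P7, p$Pz, p$P8, 2 / 8)
  p$P4  <- arc_point(p$P7, p$Pz, p$P8, 6 / 8)
  # idealized mastoids, just below the equator near the ears
  p$M1 <- sph_pos(105, -100)
  p$M2 <- sph_pos(105, 100)
  order33 <- c("Fz", "FPz", "FP1", "FP2", "F3", "F4", "F7", "F8",
               "FC1", "FC2", "FC5", "FC6", "Cz", "CPz", "C3", "C4",
               "CP1", "CP2", "CP5", "CP6", "Pz", "P3", "P4", "P7", "P8",
               "T7", "T8", "M1", "M2", "POz", "Oz", "O1", "O2")
  m <- do.call(rbind, p[order33])
  tibble::tibble(label = order33,
                 x = unname(m[, 1]), y = unname(m[, 2]), z = unname(m[, 3]))
}

#' Great-circle distances between electrodes
#'
#' Distances along the scalp surface are modeled as great-circle arcs on the
#' unit sphere (no individual head geometry is assumed).
#'
#' @param montage An `eeg_montage`.
#' @param labels Electrode labels to include (default: analyzable channels).
#' @return Symmetric matrix of great-circle distances (radians on the unit
#'   sphere), dimnames set to the labels.
#' @export
montage_distances <- function(montage, labels = montage_channels(montage)) {
  pos <- montage$positions
  idx <- match(labels, pos$label)
  if (anyNA(idx)) stop("unknown electrode label(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  P <- as.matrix(pos[idx, c("x", "y", "z")])
  G <- P %*% t(P)
  G[G > 1] <- 1; G[G < -1] <- -1
  D <- acos(G)
  dimnames(D) <- list(labels, labels)
  D
}

# Azimuthal-equidistant projection about the vertex: radius = inclination,
# direction = azimuth. Used only to obtain a planar Delaunay triangulation.
project_azimuthal <- function(positions) {
  incl <- acos(pmin(pmax(positions$z, -1), 1))
  az <- atan2(positions$x, positions$y)
  cbind(px = incl * sin(az), py = incl * cos(az))
}

montage_adjacency <- function(montage, prune_factor = 1.6) {
  labels <- montage_channels(montage)
  pos <- montage$positions[match(labels, montage$positions$label), ]
  xy <- project_azimuthal(pos)
  tri <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
  edges <- unique(tri$delsgs[, c("ind1", "ind2")])
  D <- montage_distances(montage, labels)
  elen <- D[cbind(edges$ind1, edges$ind2)]
  keep <- elen <= prune_factor * stats::median(elen)
  edges <- edges[keep, , drop = FALSE]
  adj <- stats::setNames(vector("list", length(labels)), labels)
  for (k in seq_len(nrow(edges))) {
    i <- edges$ind1[k]; j <- edges$ind2[k]
    adj[[labels[i]]] <- c(adj[[labels[i]]], labels[j])
    adj[[labels[j]]] <- c(adj[[labels[j]]], labels[i])
  }
  lapply(adj, function(v) sort(unique(v)))
}
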
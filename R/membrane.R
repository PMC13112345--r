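#' Membrane snapshot
#'
#' Labeled coordinates needed by the insertion and deformation calculators:
#' the titratable-site reference position and the phosphate-group
#' pseudo-atoms of both leaflets, plus the box for minimum-image distance
#' tests in the membrane plane.
#'
#' @param site_position Numeric length-3 `(x, y, z)` in nm.
#' @param phosphate Data.frame with columns `x`, `y`, `z` (nm) and `leaflet`
#'   (`"upper"` / `"lower"`); at least one atom per leaflet.
#' @param box Numeric length-3 box lengths `(Lx, Ly, Lz)` in nm, all > 0.
#' @param time,replicate,pH Optional frame metadata.
#' @return An object of class `membrane_snapshot`.
#' @export
membrane_snapshot <- function(site_position, phosphate, box,
                              time = NA_real_, replicate = NA_integer_,
                              pH = NA_real_) {
  stopifnot(is.numeric(site_position), length(site_position) == 3L,
            is.data.frame(phosphate),
            all(c("x", "y", "z", "leaflet") %in% names(phosphate)),
            all(phosphate$leaflet %in% c("upper", "lower")),
            is.numeric(box), length(box) == 3L, all(box > 0))
  for (lf in c("upper", "lower"))
    if (!any(phosphate$leaflet == lf))
      stop("no phosphate atoms in ", lf, " leaflet")
  structure(list(site_position = as.numeric(site_position),
                 phosphate = phosphate, box = as.numeric(box),
                 time = time, replicate = replicate, pH = pH),
            class = "membrane_snapshot")
}

#' @export
print.membrane_snapshot <- function(x, ...) {
  cat(sprintf(
    "membrane_snapshot: site at (%.3f, %.3f, %.3f) nm, %d phosphate atoms (%d upper / %d lower)\n",
    x$site_position[1], x$site_position[2], x$site_position[3],
    nrow(x$phosphate), sum(x$phosphate$leaflet == "upper"),
    sum(x$phosphate$leaflet == "lower")))
  invisible(x)
}

# GRO fixed columns: resid(1-5) resname(6-10) atom(11-15) serial(16-20)
# then x, y, z in %8.3f nm (velocities, if present, follow and are ignored)
parse_gro_atoms <- function(lines, start_line) {
  n <- length(lines)
  out <- data.frame(
    resname = character(n), atom = character(n),
    x = numeric(n), y = numeric(n), z = numeric(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ln <- lines[i]
    if (nchar(ln) < 44)
      stop("malformed GRO atom line ", start_line + i - 1L,
           ": fewer than 44 characters")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                         substr(ln, 29, 36),
                                         substr(ln, 37, 44))))
    if (any(!is.finite(xyz)))
      stop("malformed GRO atom line ", start_line + i - 1L,
           ": non-numeric coordinates")
    out$resname[i] <- trimws(substr(ln, 6, 10))
    out$atom[i] <- trimws(substr(ln, 11, 15))
    out$x[i] <- xyz[1]; out$y[i] <- xyz[2]; out$z[i] <- xyz[3]
  }
  out
}

#' Read a (possibly multi-frame) GRO coordinate file
#'
#' Parses the fixed-column GRO dialect (coordinates in nm; velocity columns,
#' if present, are ignored) and builds one [membrane_snapshot()] per frame.
#' The site position is the centre of geometry of the atoms matching
#' `site_select`; phosphate pseudo-atoms are the atoms matching
#' `phosphate_select`; leaflets are assigned by z relative to the phosphate
#' median.
#'
#' @param path Path to a `.gro` file (frames concatenated back to back).
#' @param site_select List with optional `atom` and `resname` character
#'   vectors selecting the titratable-site reference atom(s), e.g.
#'   `list(atom = "CG", resname = "ASP")` for a carboxylic carbon.
#' @param phosphate_select Same shape, selecting the phosphate-group atoms
#'   (phosphorus plus its four bound oxygens in all-atom data).
#' @return List of [membrane_snapshot()]s.
#' @export
read_gro <- function(path,
                     site_select = list(atom = "SITE"),
                     phosphate_select = list(atom = c("P", "O1", "O2",
                                                      "O3", "O4"))) {
  lines <- readLines(path)
  snaps <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    if (i + 1L > length(lines)) stop("truncated GRO file at line ", i)
    n_atoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n_atoms) || n_atoms <= 0)
      stop("invalid atom count at line ", i + 1L)
    if (i + 2L + n_atoms > length(lines))
      stop("truncated GRO file: frame starting at line ", i,
           " declares ", n_atoms, " atoms")
    atoms <- parse_gro_atoms(lines[(i + 2L):(i + 1L + n_atoms)], i + 2L)
    boxfields <- as.numeric(strsplit(trimws(lines[i + 2L + n_atoms]),
                                     "\\s+")[[1]])
    if (length(boxfields) < 3 || any(!is.finite(boxfields[1:3])))
      stop("malformed box line ", i + 2L + n_atoms)
    sel <- function(spec, what) {
      keep <- rep(TRUE, nrow(atoms))
      if (!is.null(spec$atom)) keep <- keep & atoms$atom %in% spec$atom
      if (!is.null(spec$resname))
        keep <- keep & atoms$resname %in% spec$resname
      if (!any(keep))
        stop("selection for ", what, " (",
             paste(unlist(spec), collapse = ","),
             ") matches no atoms in frame starting at line ", i)
      atoms[keep, , drop = FALSE]
    }
    site <- sel(site_select, "titratable site")
    phos <- sel(phosphate_select, "phosphate groups")
    med <- stats::median(phos$z)
    phosphate <- data.frame(
      x = phos$x, y = phos$y, z = phos$z,
      leaflet = ifelse(phos$z >= med, "upper", "lower"),
      stringsAsFactors = FALSE)
    snaps[[length(snaps) + 1L]] <- membrane_snapshot(
      site_position = c(mean(site$x), mean(site$y), mean(site$z)),
      phosphate = phosphate, box = boxfields[1:3])
    i <- i + 3L + n_atoms
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (length(snaps) == 0) stop("no frames found in ", path)
  snaps
}

# squared distance site->atoms, minimum image in xy, z non-periodic;
# lateral = TRUE ignores z (lateral-only neighbourhood)
site_dist2 <- function(snapshot, lateral = FALSE) {
  p <- snapshot$phosphate
  dx <- p$x - snapshot$site_position[1]
  dy <- p$y - snapshot$site_position[2]
  dx <- dx - snapshot$box[1] * round(dx / snapshot$box[1])
  dy <- dy - snapshot$box[2] * round(dy / snapshot$box[2])
  d2 <- dx^2 + dy^2
  if (!lateral) d2 <- d2 + (p$z - snapshot$site_position[3])^2
  d2
}

closest_leaflet <- function(snapshot) {
  zs <- snapshot$site_position[3]
  mz <- tapply(snapshot$phosphate$z, snapshot$phosphate$leaflet, mean)
  names(which.min(abs(mz - zs)))
}

#' Membrane insertion of the titratable site
#'
#' Signed distance (Angstrom; water side positive) between the site and the
#' local phosphate surface of the closest leaflet: the mean z of the
#' phosphate atoms within `radius` of the site.  If fewer than `min_atoms`
#' phosphate atoms lie inside the radius the whole closest leaflet is used
#' as reference and the result is flagged (`fallback_used`).
#'
#' @param snapshot A [membrane_snapshot()].
#' @param radius Neighbourhood radius in Angstrom (default 6).
#' @param min_atoms Minimum atoms required for the local reference
#'   (default 5).
#' @param lateral Use a lateral (xy-only) neighbourhood instead of the
#'   default 3-D Euclidean radius.
#' @param orientation `"auto"` orients water-positive by the closest
#'   leaflet (site above an upper leaflet is in water); `+1`/`-1` force the
#'   sign, for trajectories where the orientation is fixed once.
#' @return List of class `insertion_result`: `insertion` (Angstrom),
#'   `n_local_atoms`, `fallback_used`, `leaflet`.
#' @export
compute_insertion <- function(snapshot, radius = 6, min_atoms = 5,
                              lateral = FALSE, orientation = "auto") {
  lf <- closest_leaflet(snapshot)
  in_leaflet <- snapshot$phosphate$leaflet == lf
  if (!any(in_leaflet)) stop("empty closest leaflet")
  d2 <- site_dist2(snapshot, lateral = lateral)
  local <- in_leaflet & d2 <= (radius / 10)^2
  n_local <- sum(local)
  fallback <- n_local < min_atoms
  ref_z <- if (fallback) mean(snapshot$phosphate$z[in_leaflet])
           else mean(snapshot$phosphate$z[local])
  sgn <- if (identical(orientation, "auto")) {
    if (lf == "upper") 1 else -1
  } else as.numeric(orientation)
  structure(list(insertion = sgn * (snapshot$site_position[3] - ref_z) * 10,
                 n_local_atoms = n_local, fallback_used = fallback,
                 leaflet = lf),
            class = "insertion_result")
}

#' Local membrane deformation at the site
#'
#' Difference (Angstrom, water-positive) between the mean phosphate z of the
#' closest leaflet within `r_local` of the site and that of the bulk
#' phosphates of the same leaflet farther than `r_bulk` away.  Negative
#' values mean the membrane surface is pulled down (toward the acyl region)
#' under the solute.  Frames lacking local or bulk atoms yield `NA` (the
#' missing value is counted by callers, never fabricated).
#'
#' @inheritParams compute_insertion
#' @param r_local Local neighbourhood radius, Angstrom (default 6).
#' @param r_bulk Bulk exclusion radius, Angstrom (default 15).
#' @return Deformation in Angstrom, or `NA_real_`.
#' @export
local_deformation <- function(snapshot, r_local = 6, r_bulk = 15,
                              lateral = FALSE, orientation = "auto") {
  lf <- closest_leaflet(snapshot)
  in_leaflet <- snapshot$phosphate$leaflet == lf
  d2 <- site_dist2(snapshot, lateral = lateral)
  local <- in_leaflet & d2 <= (r_local / 10)^2
  bulk <- in_leaflet & d2 > (r_bulk / 10)^2
  if (!any(local) || !any(bulk)) return(NA_real_)
  sgn <- if (identical(orientation, "auto")) {
    if (lf == "upper") 1 else -1
  } else as.numeric(orientation)
  sgn * (mean(snapshot$phosphate$z[local]) -
         mean(snapshot$phosphate$z[bulk])) * 10
}

#' Synthetic membrane-surface generator
#'
#' Builds a series of snapshots whose phosphate pseudo-atoms sit on a
#' jittered square lattice in each leaflet (default spacing 0.25 nm, a
#' phosphate pseudo-atom density high enough that any site within ~5
#' Angstrom of the surface keeps at least 5 atoms in its 6 Angstrom
#' neighbourhood), with the upper leaflet
#' dimpled under the site and optional Gaussian vertical roughness.  The
#' dimple displaces the surface by exactly `-A` for lateral distances up to
#' `dimple_width`, decays smoothly (cosine taper) to zero at `dimple_cut`,
#' and is exactly zero beyond — so with zero roughness the deformation
#' estimator's local set (within 6 Angstrom) sits entirely on the `-A`
#' plateau and its bulk set (beyond 15 Angstrom) on undisplaced surface,
#' making the generator's ground truth exact rather than approximate.
#' The truth is recorded in each snapshot's attributes for validation.
#'
#' @param n_frames Number of snapshots.
#' @param lattice_spacing Lattice constant, nm (default 0.25: 16 phosphate
#'   pseudo-atoms per nm^2, about twice the areal atom density of a DMPC
#'   leaflet counting P plus its four bound oxygens — the flat surrogate
#'   concentrates in one plane what the real headgroup region spreads over
#'   several Angstrom of depth).
#' @param box Box lengths `(Lx, Ly, Lz)` nm.
#' @param dimple_amplitude Dimple depth `A`, Angstrom (>= 0; the surface is
#'   displaced downward by `A` under the site).
#' @param dimple_width Plateau radius of the dimple, Angstrom (default 6,
#'   matching the local neighbourhood of [local_deformation()]).
#' @param dimple_cut Lateral distance at which the dimple vanishes,
#'   Angstrom (default 14, inside the 15 Angstrom bulk exclusion).
#' @param roughness_sd Per-atom vertical noise sd, Angstrom.
#' @param leaflet_separation Distance between mean leaflet planes, nm.
#' @param site_track Function `frame_index -> c(x, y, z)` (nm) giving the
#'   site position per frame, or a single length-3 vector reused for all
#'   frames.  Default: centre of the box, 0.3 nm above the undisplaced
#'   upper leaflet.
#' @param jitter_sd Lateral lattice jitter sd, nm.
#' @return List of [membrane_snapshot()]s; each carries attributes
#'   `true_deformation` (`-A`, Angstrom) and `true_insertion` (site height
#'   above the dimpled surface under the site, Angstrom).
#' @export
synth_membrane_surface <- function(n_frames = 1,
                                   lattice_spacing = 0.25,
                                   box = c(7, 7, 10),
                                   dimple_amplitude = 0,
                                   dimple_width = 6,
                                   dimple_cut = 14,
                                   roughness_sd = 0,
                                   leaflet_separation = 3.5,
                                   site_track = NULL,
                                   jitter_sd = 0.03) {
  stopifnot(n_frames >= 1, lattice_spacing > 0, all(box > 0),
            dimple_amplitude >= 0, dimple_width > 0,
            dimple_cut > dimple_width, roughness_sd >= 0,
            leaflet_separation > 0)
  z_up <- (box[3] + leaflet_separation) / 2
  z_lo <- (box[3] - leaflet_separation) / 2
  if (is.null(site_track))
    site_track <- c(box[1] / 2, box[2] / 2, z_up + 0.3)
  if (!is.function(site_track)) {
    fixed <- site_track
    site_track <- function(i) fixed
  }
  gx <- seq(lattice_spacing / 2, box[1] - 1e-9, by = lattice_spacing)
  gy <- seq(lattice_spacing / 2, box[2] - 1e-9, by = lattice_spacing)
  lat <- expand.grid(x = gx, y = gy)
  A_nm <- dimple_amplitude / 10
  w_nm <- dimple_width / 10
  cut_nm <- dimple_cut / 10
  rough_nm <- roughness_sd / 10
  dimple_profile <- function(r) {
    g <- numeric(length(r))
    g[r <= w_nm] <- 1
    mid <- r > w_nm & r < cut_nm
    g[mid] <- 0.5 * (1 + cos(pi * (r[mid] - w_nm) / (cut_nm - w_nm)))
    g
  }

  lapply(seq_len(n_frames), function(i) {
    site <- site_track(i)
    one_leaflet <- function(z0, leaflet, dimpled) {
      x <- lat$x + stats::rnorm(nrow(lat), 0, jitter_sd)
      y <- lat$y + stats::rnorm(nrow(lat), 0, jitter_sd)
      x <- x %% box[1]; y <- y %% box[2]
      dx <- x - site[1]; dx <- dx - box[1] * round(dx / box[1])
      dy <- y - site[2]; dy <- dy - box[2] * round(dy / box[2])
      z <- rep(z0, nrow(lat))
      if (dimpled && A_nm > 0)
        z <- z - A_nm * dimple_profile(sqrt(dx^2 + dy^2))
      if (rough_nm > 0) z <- z + stats::rnorm(nrow(lat), 0, rough_nm)
      data.frame(x = x, y = y, z = z, leaflet = leaflet,
                 stringsAsFactors = FALSE)
    }
    phosphate <- rbind(one_leaflet(z_up, "upper", TRUE),
                       one_leaflet(z_lo, "lower", FALSE))
    snap <- membrane_snapshot(site, phosphate, box, time = i)
    z_surface_site <- z_up - A_nm  # site sits on the plateau
    attr(snap, "true_deformation") <- -dimple_amplitude
    attr(snap, "true_insertion") <- (site[3] - z_surface_site) * 10
    snap
  })
}
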
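#' Multiphoton vessel image stacks
#'
#' A three-channel 3-D volume of a cannulated vessel imaged at loaded
#' conditions: second-harmonic collagen signal, elastin autofluorescence
#' and labeled cell nuclei.  Array axes are (axial, lateral, depth): the
#' imaging plane (axial x lateral) has isotropic in-plane resolution
#' \code{dxy_um} (default 0.48 um/pixel) and the depth step is
#' \code{dz_um} (default 1 um).  A lateral-depth plane at fixed axial
#' position is a circumferential-radial slice through the near-cylindrical
#' wall.
#'
#' @param collagen,elastin,nuclei 3-D numeric arrays of equal dimension.
#' @param dxy_um in-plane pixel size (um).
#' @param dz_um depth step (um).
#' @return object of class \code{"vessel_stack"}.
#' @export
vessel_stack <- function(collagen, elastin, nuclei, dxy_um = 0.48,
                         dz_um = 1) {
  d <- dim(collagen)
  stopifnot(length(d) == 3, identical(dim(elastin), d),
            identical(dim(nuclei), d), dxy_um > 0, dz_um > 0)
  structure(list(collagen = collagen, elastin = elastin, nuclei = nuclei,
                 dxy_um = dxy_um, dz_um = dz_um, dim = d),
            class = "vessel_stack")
}

#' Read a three-channel vessel stack from TIFF files
#'
#' Reads one multi-page grayscale TIFF per channel (pages are the depth
#' slices; page rows are the vessel's axial direction).  Voxel sizes are
#' not reliably carried in TIFF metadata across microscope vendors, so
#' they are passed explicitly.
#'
#' @param collagen_path,elastin_path,nuclei_path TIFF file paths.
#' @param dxy_um,dz_um voxel sizes (um); defaults match the acquisition
#'   (0.48 um in-plane, 1 um depth step).
#' @return a \code{\link{vessel_stack}}.
#' @export
read_vessel_stack_tiff <- function(collagen_path, elastin_path,
                                   nuclei_path, dxy_um = 0.48, dz_um = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package")
  read_chan <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    arr
  }
  vessel_stack(read_chan(collagen_path), read_chan(elastin_path),
               read_chan(nuclei_path), dxy_um = dxy_um, dz_um = dz_um)
}

#' @export
print.vessel_stack <- function(x, ...) {
  cat(sprintf(
    "Vessel image stack: %d x %d x %d voxels (%.2f um in-plane, %.2f um depth)\n",
    x$dim[1], x$dim[2], x$dim[3], x$dxy_um, x$dz_um))
  invisible(x)
}

# bilinear sampling of matrix M (spacing dy, dz along rows/cols) at
# physical coordinates (y, z) in um; outside points return 0
interp_bilinear <- function(M, dy, dz, y, z) {
  fi <- y / dy + 1
  fj <- z / dz + 1
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  n1 <- nrow(M); n2 <- ncol(M)
  val <- function(i, j) {
    ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2
    out <- numeric(length(i))
    out[ok] <- M[cbind(i[ok], j[ok])]
    out
  }
  (1 - wi) * (1 - wj) * val(i0, j0) + wi * (1 - wj) * val(i0 + 1, j0) +
    (1 - wi) * wj * val(i0, j0 + 1) + wi * wj * val(i0 + 1, j0 + 1)
}

# grayscale 2-D Gaussian blur on a plain matrix
gblur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

# Otsu threshold for a numeric vector of intensities
otsu_vec <- function(v) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  x <- (v - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(x, ncol = 1)), range = c(0, 1))
  rng[1] + th * diff(rng)
}

#' Fit a circle to the mid-thickness profile of the wall
#'
#' From a coarse intensity centroid, rays are cast across the slice and
#' the intensity-weighted radial centroid of the wall signal along each
#' ray provides a mid-thickness point; an algebraic least-squares (Kasa)
#' circle is fit to those points.  Coordinates are physical (um), so
#' anisotropic voxels are handled.
#'
#' @param slice 2-D matrix (lateral x depth) of wall signal at one axial
#'   position (typically elastin + collagen).
#' @param dy_um,dz_um pixel spacings along the two slice axes.
#' @param n_rays number of rays.
#' @return list with \code{center_um} (length 2: lateral, depth),
#'   \code{radius_um}, and the fitted \code{points_um}.
#' @export
fit_midwall_circle <- function(slice, dy_um = 0.48, dz_um = 1,
                               n_rays = 90) {
  thr <- otsu_vec(as.numeric(slice))
  w <- pmax(slice - thr, 0)
  if (sum(w) <= 0) stop("no wall signal above background")
  ys <- (seq_len(nrow(slice)) - 1) * dy_um
  zs <- (seq_len(ncol(slice)) - 1) * dz_um
  cy <- sum(rowSums(w) * ys) / sum(w)
  cz <- sum(colSums(w) * zs) / sum(w)
  r_max <- sqrt(max(ys)^2 + max(zs)^2)
  step <- min(dy_um, dz_um) / 2
  s <- seq(step, r_max, by = step)
  ang <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  pts <- matrix(NA_real_, 0, 2)
  for (a in ang) {
    y <- cy + s * cos(a); z <- cz + s * sin(a)
    inten <- interp_bilinear(slice, dy_um, dz_um, y, z)
    inten <- pmax(inten - thr, 0)
    if (sum(inten) > 0) {
      rc <- sum(s * inten) / sum(inten)
      pts <- rbind(pts, c(cy + rc * cos(a), cz + rc * sin(a)))
    }
  }
  if (nrow(pts) < 20)
    stop("too few wall points for a circle fit (need >= 20)")
  # Kasa: minimize || y^2 + z^2 - 2ay - 2bz - c ||
  A <- cbind(2 * pts[, 1], 2 * pts[, 2], 1)
  b <- pts[, 1]^2 + pts[, 2]^2
  sol <- qr.solve(A, b)
  list(center_um = c(sol[1], sol[2]),
       radius_um = sqrt(sol[3] + sol[1]^2 + sol[2]^2),
       points_um = pts)
}

#' Unwrap a vessel stack from Cartesian to polar coordinates
#'
#' Fits the mid-wall circle on a subsample of circumferential-radial
#' slices (median center/radius, assuming a straight cylindrical segment),
#' then resamples every channel of every slice onto a regular
#' (angle, radius) grid by bilinear interpolation.  The angular sampling
#' is chosen so the arc length per sample at the mid-wall radius is about
#' one in-plane pixel.
#'
#' @param stack a \code{\link{vessel_stack}}.
#' @param r_range_um radial extent of the grid (um, around the circle
#'   center); default half to 1.5 times the mid-wall radius, clipped to
#'   the image bounds (with a warning when clipping occurs).
#' @param n_fit_slices number of axial slices used for the circle fits.
#' @param n_theta number of angular samples; default matches the
#'   mid-wall arc length per sample to one in-plane pixel.
#' @return object of class \code{"polar_stack"}: channels as arrays of
#'   dimension (angle, radius, axial), plus \code{theta_rad}, \code{r_um},
#'   \code{circle}, and the stack's voxel sizes.
#' @export
unwrap_to_polar <- function(stack, r_range_um = NULL, n_fit_slices = 8,
                            n_theta = NULL) {
  stopifnot(inherits(stack, "vessel_stack"))
  d <- stack$dim
  wall <- stack$elastin + stack$collagen
  idx <- unique(round(seq(1, d[1], length.out = min(n_fit_slices, d[1]))))
  fits <- lapply(idx, function(i)
    fit_midwall_circle(wall[i, , ], stack$dxy_um, stack$dz_um))
  ctr <- c(stats::median(vapply(fits, function(f) f$center_um[1], 0)),
           stats::median(vapply(fits, function(f) f$center_um[2], 0)))
  R <- stats::median(vapply(fits, function(f) f$radius_um, 0))
  if (is.null(r_range_um)) r_range_um <- c(0.5 * R, 1.5 * R)
  max_y <- (d[2] - 1) * stack$dxy_um
  max_z <- (d[3] - 1) * stack$dz_um
  r_img <- min(ctr[1], max_y - ctr[1], ctr[2], max_z - ctr[2])
  if (r_range_um[2] > r_img) {
    if (r_range_um[2] - r_img > 0.1 * R)
      warning("radius grid exceeds image bounds; clipping")
    r_range_um[2] <- r_img
  }
  dr <- min(stack$dxy_um, stack$dz_um)
  r_um <- seq(r_range_um[1], r_range_um[2], by = dr)
  if (is.null(n_theta)) n_theta <- max(64, round(2 * pi * R / stack$dxy_um))
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ygrid <- ctr[1] + outer(cos(theta), r_um)
  zgrid <- ctr[2] + outer(sin(theta), r_um)
  chans <- lapply(stack[c("collagen", "elastin", "nuclei")], function(ch) {
    out <- array(0, c(n_theta, length(r_um), d[1]))
    for (i in seq_len(d[1]))
      out[, , i] <- interp_bilinear(ch[i, , ], stack$dxy_um, stack$dz_um,
                                    as.numeric(ygrid), as.numeric(zgrid))
    out
  })
  structure(c(chans, list(theta_rad = theta, r_um = r_um,
                          circle = list(center_um = ctr, radius_um = R),
                          dxy_um = stack$dxy_um, dz_um = stack$dz_um)),
            class = "polar_stack")
}

#' Segment intima, media and adventitia from the elastin channel
#'
#' The media is bounded by the internal and external elastic laminae,
#' which appear as the innermost and outermost peaks of the radial elastin
#' intensity profile (averaged over angle and axial position).  Intima
#' lies lumen-side of the inner lamina, adventitia outside the outer one;
#' the wall's inner/outer edges are taken where the total signal drops
#' below 10\% of its peak.
#'
#' @param polar a \code{\link{unwrap_to_polar}} result.
#' @param min_peak_frac elastin peaks must exceed this fraction of the
#'   profile maximum.
#' @return list of radial boundaries (um): \code{r_wall_inner_um},
#'   \code{r_iel_um}, \code{r_eel_um}, \code{r_wall_outer_um}, plus
#'   logical index vectors \code{intima}, \code{media}, \code{adventitia}
#'   over the polar radius grid (disjoint; union covers the wall).
#' @export
segment_layers <- function(polar, min_peak_frac = 0.3) {
  stopifnot(inherits(polar, "polar_stack"))
  prof <- apply(polar$elastin, 2, mean)
  pk <- pracma::findpeaks(prof, minpeakheight = min_peak_frac * max(prof))
  if (is.null(pk) || nrow(pk) < 2)
    stop("layer segmentation failed: fewer than 2 elastin peaks")
  pos <- sort(pk[, 2])
  i_iel <- pos[1]; i_eel <- pos[length(pos)]
  total <- apply(polar$elastin + polar$collagen + polar$nuclei, 2, mean)
  lo <- 0.1 * max(total)
  inner <- which(total > lo)[1]
  outer <- rev(which(total > lo))[1]
  r <- polar$r_um
  intima <- seq_along(r) >= inner & seq_along(r) < i_iel
  media <- seq_along(r) >= i_iel & seq_along(r) <= i_eel
  advent <- seq_along(r) > i_eel & seq_along(r) <= outer
  list(r_wall_inner_um = r[inner], r_iel_um = r[i_iel],
       r_eel_um = r[i_eel], r_wall_outer_um = r[outer],
       intima = intima, media = media, adventitia = advent)
}

#' Structure-tensor orientation field of a fiber image
#'
#' Gradients at scale \code{sigma_grad} (pixels) are tensor-averaged at
#' the integration scale \code{sigma_int}; the dominant fiber direction
#' per pixel is the minor eigenvector of the structure tensor, reported as
#' an angle in (-90, 90] measured from the first array axis.  Coherence
#' \eqn{(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)} in [0, 1] serves as a
#' per-pixel weight; pixels whose gradient energy falls below
#' \code{energy_frac} of the mean are masked.
#'
#' @param img 2-D matrix; axis 1 is the reference (axial) direction.
#' @param sigma_grad,sigma_int Gaussian scales in pixels.
#' @param energy_frac energy mask threshold, relative to mean energy.
#' @return list of matrices \code{angle_deg}, \code{coherence},
#'   \code{energy}, and logical \code{mask}; a warning is issued and the
#'   mask is empty for a uniform image.
#' @export
orientation_field <- function(img, sigma_grad = 1, sigma_int = 4,
                              energy_frac = 0.5) {
  stopifnot(is.matrix(img))
  sm <- gblur_mat(img, sigma_grad)
  n1 <- nrow(sm); n2 <- ncol(sm)
  gx <- (sm[c(2:n1, n1), ] - sm[c(1, 1:(n1 - 1)), ]) / 2
  gy <- (sm[, c(2:n2, n2)] - sm[, c(1, 1:(n2 - 1))]) / 2
  Jxx <- gblur_mat(gx * gx, sigma_int)
  Jyy <- gblur_mat(gy * gy, sigma_int)
  Jxy <- gblur_mat(gx * gy, sigma_int)
  energy <- Jxx + Jyy
  if (max(energy) <= 0) {
    warning("uniform image: empty orientation field")
    return(list(angle_deg = img * NA, coherence = img * 0,
                energy = energy, mask = img > Inf))
  }
  angle <- 0.5 * atan2(-2 * Jxy, Jyy - Jxx) * 180 / pi
  coher <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / (energy + 1e-12 * max(energy))
  mask <- energy > energy_frac * mean(energy)
  list(angle_deg = angle, coherence = coher, energy = energy, mask = mask)
}

#' Layer-specific fiber orientation distribution from a stack
#'
#' End-to-end orientation pipeline: unwrap the stack to polar coordinates,
#' then run the structure tensor on every axial-circumferential plane of
#' the requested channel within the layer's radial band (analyzing each
#' radial sample separately keeps crossing fibers at different depths from
#' being tensor-averaged into a spuriously tight distribution), correct
#' the per-pixel angles for the arc length per angular sample at the
#' plane's radius, pool the angles across planes with
#' coherence-squared-times-energy weights, and fit the axial von Mises
#' distribution.
#'
#' @param stack a \code{\link{vessel_stack}} (or a precomputed
#'   \code{polar_stack}).
#' @param layer \code{"adventitia"} (collagen analysis) or \code{"media"}.
#' @param channel channel name; default \code{"collagen"}.
#' @param sigma_grad,sigma_int structure-tensor scales (pixels); a tight
#'   integration scale suits thin fiber stripes.
#' @param coherence_min pixels below this coherence are discarded; strict
#'   by default so only unambiguous fiber pixels enter the fit.
#' @return list with \code{theta_bar_deg}, \code{kappa}, \code{n_eff}
#'   (total weight), \code{angles_deg}, \code{weights}, and the layer
#'   segmentation used.
#' @export
analyze_fiber_orientation <- function(stack, layer = c("adventitia", "media"),
                                      channel = "collagen",
                                      sigma_grad = 1, sigma_int = 2,
                                      coherence_min = 0.8) {
  layer <- match.arg(layer)
  polar <- if (inherits(stack, "polar_stack")) stack
           else unwrap_to_polar(stack)
  seg <- segment_layers(polar)
  band <- which(seg[[layer]])
  if (!length(band)) stop("empty layer band")
  dtheta <- polar$theta_rad[2] - polar$theta_rad[1]
  ang <- list(); w <- list()
  for (b in band) {
    img <- t(polar[[channel]][, b, ])      # axis 1 = axial
    if (max(img) <= 0) next
    of <- orientation_field(img, sigma_grad, sigma_int)
    keep <- of$mask & of$coherence >= coherence_min
    if (!any(keep)) next
    arc <- polar$r_um[b] * dtheta
    bb <- of$angle_deg[keep] * pi / 180
    ang[[length(ang) + 1]] <-
      atan2(sin(bb) * arc, cos(bb) * polar$dxy_um) * 180 / pi
    w[[length(w) + 1]] <- of$coherence[keep]^2 * of$energy[keep]
  }
  if (!length(ang)) stop("no coherent fiber signal in the layer")
  ang <- unlist(ang); w <- unlist(w)
  fit <- fit_von_mises_axial(ang, w)
  list(theta_bar_deg = fit$theta_bar_deg, kappa = fit$kappa,
       n_eff = fit$n, angles_deg = ang, weights = w, layers = seg,
       R_bar = fit$R_bar)
}

# 6-connected 3-D component labeling of a logical array
label_components_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(list(labels = integer(0), index = idx))
  k <- (idx - 1) %/% (d[1] * d[2])
  rem <- (idx - 1) %% (d[1] * d[2])
  j <- rem %/% d[1]
  i <- rem %% d[1]
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    ok <- i + off[1] < d[1] & j + off[2] < d[2] & k + off[3] < d[3]
    nb <- idx[ok] + off[1] + off[2] * d[1] + off[3] * d[1] * d[2]
    has <- pos[nb] > 0
    edges <- c(edges, rbind(which(ok)[has], pos[nb[has]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  list(labels = igraph::components(g)$membership, index = idx)
}

#' Layer-wise nuclear density
#'
#' Counts nuclei in the smoothed, Otsu-thresholded nuclei channel inside a
#' Cartesian layer mask built from the mid-wall circle fit and the layer's
#' radial boundaries: 3-D 6-connected components, a minimum-volume filter,
#' and splitting of merged components by intensity local maxima separated
#' by at least a nuclear diameter.  Medial/adventitial densities are
#' reported per 0.001 mm^3 of layer volume; the intimal density per
#' 0.01 mm^2 of luminal surface.
#'
#' @param stack a \code{\link{vessel_stack}}.
#' @param layer \code{"intima"}, \code{"media"} or \code{"adventitia"}.
#' @param polar optional precomputed \code{\link{unwrap_to_polar}} result.
#' @param sigma_um smoothing scale for the nuclei channel (um).
#' @param min_volume_um3 minimum object volume (um^3); smaller components
#'   are treated as noise.
#' @param min_sep_um minimum separation of intensity maxima when splitting
#'   merged nuclei (um).
#' @return list with \code{count}, \code{density} (per 0.001 mm^3, or per
#'   0.01 mm^2 for the intima), \code{volume_um3} (or \code{area_um2}),
#'   and the layer boundaries used.
#' @export
cell_density <- function(stack, layer = c("media", "adventitia", "intima"),
                         polar = NULL, sigma_um = 1.5,
                         min_volume_um3 = 7, min_sep_um = 4) {
  layer <- match.arg(layer)
  stopifnot(inherits(stack, "vessel_stack"))
  if (is.null(polar)) polar <- unwrap_to_polar(stack)
  seg <- segment_layers(polar)
  bounds <- switch(layer,
    intima = c(seg$r_wall_inner_um, seg$r_iel_um),
    media = c(seg$r_iel_um, seg$r_eel_um),
    adventitia = c(seg$r_eel_um, seg$r_wall_outer_um))
  d <- stack$dim
  ys <- (seq_len(d[2]) - 1) * stack$dxy_um - polar$circle$center_um[1]
  zs <- (seq_len(d[3]) - 1) * stack$dz_um - polar$circle$center_um[2]
  rho <- sqrt(outer(ys^2, zs^2, `+`))
  # detect over the whole wall, then assign peaks to the layer by their
  # radial position, so nuclei straddling a boundary are not double
  # counted as mask-clipped fragments
  pad <- 3
  wall2d <- rho >= seg$r_wall_inner_um - pad &
    rho <= seg$r_wall_outer_um + pad
  mask2d <- rho >= bounds[1] & rho <= bounds[2]
  if (!any(mask2d)) stop("empty layer mask")
  wall <- aperm(array(wall2d, c(d[2], d[3], d[1])), c(3, 1, 2))
  sm <- stack$nuclei
  for (ix in seq_len(d[1]))
    sm[ix, , ] <- gblur_mat(stack$nuclei[ix, , ], sigma_um / stack$dxy_um)
  thr <- otsu_vec(sm[wall])
  fg <- sm > thr & wall
  voxvol <- stack$dxy_um^2 * stack$dz_um
  comp <- label_components_3d(fg)
  ctr_y <- polar$circle$center_um[1]
  ctr_z <- polar$circle$center_um[2]
  in_layer <- function(p)                   # p = (x, y, z) in um
    sqrt((p[2] - ctr_y)^2 + (p[3] - ctr_z)^2) >= bounds[1] &&
    sqrt((p[2] - ctr_y)^2 + (p[3] - ctr_z)^2) <= bounds[2]
  count <- 0L
  if (length(comp$index)) {
    sizes <- tabulate(comp$labels)
    keep_lab <- which(sizes * voxvol >= min_volume_um3)
    dd <- d
    # strict local maxima of the smoothed intensity (26-neighborhood)
    is_lmax <- function(vox) {
      kz <- (vox - 1) %/% (dd[1] * dd[2])
      rem <- (vox - 1) %% (dd[1] * dd[2])
      jy <- rem %/% dd[1]
      ixa <- rem %% dd[1]
      out <- rep(TRUE, length(vox))
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- ixa + di; jj <- jy + dj; kk <- kz + dk
        inb <- ii >= 0 & ii < dd[1] & jj >= 0 & jj < dd[2] &
          kk >= 0 & kk < dd[3]
        nb <- 1 + ii + jj * dd[1] + kk * dd[1] * dd[2]
        out[inb] <- out[inb] & sm[vox[inb]] >= sm[nb[inb]]
      }
      out
    }
    vox_xyz <- function(vox) {
      kz <- (vox - 1) %/% (dd[1] * dd[2])
      rem <- (vox - 1) %% (dd[1] * dd[2])
      cbind((rem %% dd[1]) * stack$dxy_um,
            (rem %/% dd[1]) * stack$dxy_um, kz * stack$dz_um)
    }
    for (lab in keep_lab) {
      vox <- comp$index[comp$labels == lab]
      lm <- vox[is_lmax(vox)]
      if (!length(lm)) {
        w <- sm[vox]
        p <- colSums(vox_xyz(vox) * w) / sum(w)
        if (in_layer(p)) count <- count + 1L
        next
      }
      xyz <- vox_xyz(lm)
      ord <- order(sm[lm], decreasing = TRUE)
      acc <- matrix(numeric(0), 0, 3)
      for (q in ord) {
        p <- xyz[q, ]
        if (!nrow(acc) ||
            min(sqrt(colSums((t(acc) - p)^2))) >= min_sep_um)
          acc <- rbind(acc, p)
      }
      count <- count + sum(apply(acc, 1, in_layer))
    }
  }
  axial_len <- d[1] * stack$dxy_um
  if (layer == "intima") {
    area <- 2 * pi * seg$r_wall_inner_um * axial_len
    list(count = count, density = count / area * 1e4, area_um2 = area,
         bounds_um = bounds)
  } else {
    volume <- pi * (bounds[2]^2 - bounds[1]^2) * axial_len
    list(count = count, density = count / volume * 1e6,
         volume_um3 = volume, bounds_um = bounds)
  }
}
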
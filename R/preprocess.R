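# Pre-processing: landmark detection, tray orientation estimation and
# rectification, pot extraction, HSV background removal. Images are numeric
# arrays H x W x 3 (RGB in [0, 1]); coordinates are (x right, y down) with
# pixel centres at half-integers (pixel (i, j) of the array has centre
# x = j - 0.5, y = i - 0.5).

#' Detect the five white tray landmarks
#'
#' Binarises the value channel at a fixed threshold (lighting is assumed
#' controlled), labels connected components, discards components smaller
#' than `min_area_px`, keeps the five largest by area and returns their
#' centroids with roles assigned via [assign_landmark_roles()].
#'
#' @param image RGB array `H x W x 3` in \[0, 1\].
#' @param intensity_threshold binarisation threshold on the value (max-RGB)
#'   channel, on the 0–255 scale (default 200).
#' @param min_area_px components smaller than this are ignored.
#' @return Tibble of class `landmark_set`: `role` (center/TL/TR/BL/BR),
#'   `x`, `y` (centroid image coordinates), `area`.
#' @examples
#' cfg <- scene_config(grid_rows = 2, grid_cols = 3, pot_size_px = 30,
#'                     frames_total = 2, landmark_radius_px = 4)
#' img <- render_tray_frame(cfg, sample_stage_schedule(cfg), 1)
#' detect_landmarks(img)
#' @export
detect_landmarks <- function(image, intensity_threshold = 200,
                             min_area_px = 20) {
  stopifnot(length(dim(image)) == 3)
  value <- pmax(image[, , 1], image[, , 2], image[, , 3])
  bw <- value > intensity_threshold / 255
  lab <- EBImage::bwlabel(EBImage::Image(t(bw))) # EBImage is x-major
  lab <- t(EBImage::imageData(lab))
  n <- max(lab)
  if (n == 0) {
    ss_abort("found 0 landmark candidates (need 5)",
      class = "seedstage_landmarks_not_found", n_found = 0L
    )
  }
  areas <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(areas >= min_area_px)
  if (length(keep) < 5) {
    ss_abort(
      sprintf("found %d landmark candidate(s) (need 5)", length(keep)),
      class = "seedstage_landmarks_not_found", n_found = length(keep)
    )
  }
  keep <- keep[order(areas[keep], decreasing = TRUE)][1:5]
  idx <- which(matrix(lab %in% keep, nrow(lab)), arr.ind = TRUE)
  comp <- lab[idx]
  cx <- tapply(idx[, 2] - 0.5, comp, mean)[as.character(keep)]
  cy <- tapply(idx[, 1] - 0.5, comp, mean)[as.character(keep)]
  pts <- tibble(x = as.numeric(cx), y = as.numeric(cy),
                area = areas[keep])
  assign_landmark_roles(pts, c(ncol(image[, , 1]) / 2, nrow(image[, , 1]) / 2))
}

#' Assign centre/corner roles to five landmark candidates
#'
#' The candidate nearest the image centre becomes the central landmark
#' (ties broken by row-major scan order); the remaining four are assigned
#' TL/TR/BL/BR by the quadrant of their angle about the central point. The
#' assignment tolerates moderate tray rotation (up to the rotation that
#' pushes a corner across a quadrant boundary, 45 degrees for a square
#' tray).
#'
#' @param candidates data frame with columns `x`, `y` (5 rows).
#' @param image_center numeric `c(x, y)` of the image centre.
#' @return Tibble of class `landmark_set` with a `role` column.
#' @export
assign_landmark_roles <- function(candidates, image_center) {
  if (nrow(candidates) != 5) {
    ss_abort("exactly 5 landmark candidates are required",
      class = "seedstage_config_error"
    )
  }
  d2 <- (candidates$x - image_center[1])^2 + (candidates$y - image_center[2])^2
  ord <- order(d2, round(candidates$y), round(candidates$x)) # row-major ties
  central_i <- ord[1]
  rest <- candidates[-central_i, , drop = FALSE]
  cx <- candidates$x[central_i]
  cy <- candidates$y[central_i]
  dx <- rest$x - cx
  dy <- rest$y - cy
  role <- dplyr::case_when(
    dx < 0 & dy < 0 ~ "TL",
    dx >= 0 & dy < 0 ~ "TR",
    dx < 0 & dy >= 0 ~ "BL",
    TRUE ~ "BR"
  )
  if (anyDuplicated(role)) {
    ss_abort("two corner candidates fall in the same quadrant",
      class = "seedstage_role_assignment_ambiguous"
    )
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(candidates[central_i, , drop = FALSE], role = "center"),
    dplyr::mutate(rest, role = role)
  )
  out <- dplyr::relocate(out, "role")
  class(out) <- c("landmark_set", class(out))
  out
}

#' Estimate tray orientation from the Fourier spectrum
#'
#' The modulus of the 2-D Fourier transform of a (Hann-windowed, mean
#' subtracted) grayscale tray region is treated as a mass distribution
#' about the spectrum centre, and the angle of its principal orientation
#' gives the in-plane orientation of the dominant periodic structure (the
#' pot grid), folded into the canonical range (-45, 45].
#'
#' The grid spectrum has two near-equal orthogonal harmonic arms (from row
#' and column pot boundaries), so it is 4-fold symmetric and plain second
#' moments are degenerate: the principal orientation is therefore computed
#' from the fourth-order circular moment of the spectral mass (the
#' quadrupled-angle resultant), which the 90-degree arm symmetry leaves
#' invariant and isotropic noise cancels out of. Moments are taken in
#' normalised frequency units (cycles/pixel, so non-square regions are not
#' distorted), restricted to a mid-frequency annulus where the grid
#' harmonics live, with an adaptive threshold over the annulus noise floor.
#'
#' @param region grayscale matrix or RGB array of the tray region
#'   (at least 64 x 64).
#' @param annulus `c(rmin, rmax)` radial band in cycles/pixel considered for
#'   the orientation statistic.
#' @param floor_mult multiple of the annulus median modulus below which bins
#'   are treated as noise floor and ignored.
#' @param min_anisotropy minimum resultant length (0..1) of the
#'   quadrupled-angle statistic; below it the spectrum is considered
#'   isotropic and the orientation undefined.
#' @return Angle in degrees, counter-clockwise positive (y down), in
#'   (-45, 45], with attribute `anisotropy` (the resultant length).
#' @export
estimate_tray_orientation <- function(region, annulus = c(0.05, 0.35),
                                      floor_mult = 4, min_anisotropy = 0.05) {
  if (length(dim(region)) == 3) {
    region <- (region[, , 1] + region[, , 2] + region[, , 3]) / 3
  }
  h <- nrow(region)
  w <- ncol(region)
  if (h < 64 || w < 64) {
    ss_abort("region too small for a meaningful spectrum (need >= 64 x 64)",
      class = "seedstage_geometry_error"
    )
  }
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  win <- outer(hann(h), hann(w))
  f <- stats::fft((region - mean(region)) * win)
  mod <- Mod(f)
  # centre the spectrum (fftshift); frequencies in cycles/pixel
  mod <- mod[c((h %/% 2 + 1):h, 1:(h %/% 2)), c((w %/% 2 + 1):w, 1:(w %/% 2))]
  fy <- matrix((seq_len(h) - (h %/% 2 + 1)) / h, h, w)
  fx <- matrix((seq_len(w) - (w %/% 2 + 1)) / w, h, w, byrow = TRUE)
  r <- sqrt(fx^2 + fy^2)
  sel <- r > annulus[1] & r <= annulus[2]
  m <- mod[sel]
  wgt <- ifelse(m > floor_mult * stats::median(m), m^2, 0)
  if (sum(wgt) == 0) {
    ss_abort("no spectral peaks above the noise floor; orientation undefined",
      class = "seedstage_orientation_undefined"
    )
  }
  phi <- atan2(fy[sel], fx[sel])
  cc <- sum(wgt * cos(4 * phi))
  ss <- sum(wgt * sin(4 * phi))
  resultant <- sqrt(cc^2 + ss^2) / sum(wgt)
  if (resultant < min_anisotropy) {
    ss_abort("spectrum is isotropic; orientation undefined",
      class = "seedstage_orientation_undefined"
    )
  }
  ang <- atan2(ss, cc) / 4 * 180 / pi # principal orientation mod 90
  ang <- ((ang + 45) %% 90) - 45
  if (ang <= -45) ang <- ang + 90
  structure(ang, anisotropy = resultant)
}

#' Rectify a rotated tray to an axis-aligned pot grid
#'
#' Rotates the image by `-angle` about the central landmark, then applies
#' the projective transform sending the four (rotated) corner landmarks to
#' configured target positions, so that the pot grid exactly fills the
#' output raster. Bilinear interpolation throughout.
#'
#' By default the corner landmark targets are taken from the tray geometry
#' implied by `grid_rows`/`grid_cols`/`pot_size_px`/`margin_px`: landmarks
#' sit half a margin outside the grid, so the output of size
#' `(grid_rows*pot) x (grid_cols*pot)` contains exactly the grid and
#' [extract_pots()] can tile it directly.
#'
#' @param image RGB array `H x W x 3`.
#' @param landmarks a `landmark_set` from [detect_landmarks()].
#' @param angle tray orientation in degrees (from
#'   [estimate_tray_orientation()]).
#' @param grid_rows,grid_cols,pot_size_px,margin_px output tray geometry.
#' @param targets optional 4 x 2 matrix (rows TL,TR,BL,BR; columns x, y) of
#'   corner-landmark target positions in output coordinates, overriding the
#'   geometry-derived defaults.
#' @return RGB array `(grid_rows*pot_size_px) x (grid_cols*pot_size_px) x 3`.
#' @export
rectify_tray <- function(image, landmarks, angle,
                         grid_rows, grid_cols, pot_size_px,
                         margin_px = max(24L, 32L), targets = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  out_h <- grid_rows * pot_size_px
  out_w <- grid_cols * pot_size_px
  if (is.null(targets)) {
    hm <- margin_px / 2
    targets <- rbind(
      TL = c(-hm, -hm),
      TR = c(out_w + hm, -hm),
      BL = c(-hm, out_h + hm),
      BR = c(out_w + hm, out_h + hm)
    )
  }
  ctr <- landmarks[landmarks$role == "center", ]
  corners <- landmarks[match(c("TL", "TR", "BL", "BR"), landmarks$role), ]
  if (anyNA(corners$x)) {
    ss_abort("landmark set lacks the four corner roles",
      class = "seedstage_geometry_error"
    )
  }
  # 1) rotate corner landmarks by -angle about the central landmark
  rot <- rotmat(-angle)
  rel <- rbind(corners$x - ctr$x, corners$y - ctr$y)
  rotated <- rot %*% rel
  src_rot <- cbind(rotated[1, ] + ctr$x, rotated[2, ] + ctr$y)
  if (abs(polygon_area(src_rot)) < 1e-6) {
    ss_abort("corner landmarks are collinear; homography undefined",
      class = "seedstage_geometry_error"
    )
  }
  # 2) homography sending rotated corners to targets; total inverse map for
  #    each output pixel: inverse homography, then rotation by +angle
  hmat <- homography_from_points(src_rot, targets)
  hinv <- solve(hmat)
  rot_fwd <- rotmat(angle)

  xs <- matrix(seq_len(out_w) - 0.5, out_h, out_w, byrow = TRUE)
  ys <- matrix(seq_len(out_h) - 0.5, out_h, out_w)
  denom <- hinv[3, 1] * xs + hinv[3, 2] * ys + hinv[3, 3]
  xr <- (hinv[1, 1] * xs + hinv[1, 2] * ys + hinv[1, 3]) / denom
  yr <- (hinv[2, 1] * xs + hinv[2, 2] * ys + hinv[2, 3]) / denom
  # undo the rotation step (output -> rotated frame -> original image)
  xo <- rot_fwd[1, 1] * (xr - ctr$x) + rot_fwd[1, 2] * (yr - ctr$y) + ctr$x
  yo <- rot_fwd[2, 1] * (xr - ctr$x) + rot_fwd[2, 2] * (yr - ctr$y) + ctr$y

  out <- array(0, dim = c(out_h, out_w, 3))
  for (ch in 1:3) {
    out[, , ch] <- bilinear_sample(image[, , ch], xo, yo)
  }
  out
}

polygon_area <- function(p) { # shoelace on TL,TR,BR,BL ordering
  p <- p[c(1, 2, 4, 3), ]
  x <- p[, 1]
  y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# direct linear transform from 4 point correspondences (x, y) -> (u, v)
homography_from_points <- function(src, dst) {
  a <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]
    u <- dst[i, 1]; v <- dst[i, 2]
    a[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    a[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- solve(a, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

# bilinear interpolation of matrix `img` at continuous coords (x, y), pixel
# centres at half-integers; out-of-bounds samples return 0
bilinear_sample <- function(img, x, y) {
  h <- nrow(img)
  w <- ncol(img)
  cx <- x - 0.5
  cy <- y - 0.5 # 0-based continuous pixel index
  x0 <- floor(cx)
  y0 <- floor(cy)
  fx <- cx - x0
  fy <- cy - y0
  get <- function(yy, xx) {
    ok <- yy >= 0 & yy <= h - 1 & xx >= 0 & xx <= w - 1
    v <- numeric(length(yy))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  v00 <- get(y0, x0)
  v01 <- get(y0, x0 + 1)
  v10 <- get(y0 + 1, x0)
  v11 <- get(y0 + 1, x0 + 1)
  out <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  matrix(out, nrow(x), ncol(x))
}

#' Extract per-pot crops from a rectified tray
#'
#' Tiles the rectified grid area row-major into disjoint square crops of
#' `pot_size_px`; crop `(r, c)` covers rows `[(r-1)*s+1, r*s]` and columns
#' `[(c-1)*s+1, c*s]`. The crops partition the grid area exactly.
#'
#' @param rectified RGB array from [rectify_tray()].
#' @param grid_rows,grid_cols pot grid dimensions.
#' @param pot_size_px crop side in pixels.
#' @return Tibble with columns `row`, `col`, `image` (list of
#'   `s x s x 3` arrays), in row-major pot order.
#' @export
extract_pots <- function(rectified, grid_rows, grid_cols, pot_size_px) {
  s <- pot_size_px
  if (nrow(rectified) < grid_rows * s || ncol(rectified) < grid_cols * s) {
    ss_abort("pot grid exceeds the rectified image bounds",
      class = "seedstage_geometry_error"
    )
  }
  grid <- tidyr::expand_grid(row = seq_len(grid_rows),
                             col = seq_len(grid_cols))
  grid$image <- purrr::map2(grid$row, grid$col, function(r, c) {
    rectified[((r - 1) * s + 1):(r * s), ((c - 1) * s + 1):(c * s), ,
              drop = FALSE]
  })
  grid
}

#' Remove the soil background by HSV colour filtering
#'
#' Converts the crop to HSV and keeps only pixels whose hue lies in the
#' green band and whose saturation and value exceed the minima; all other
#' pixels are set to black. The default band separates plant green
#' (hue near 110 degrees) from soil brown (hue near 20 degrees). The filter
#' is a pure per-pixel mask (idempotent); optional removal of small
#' connected foreground specks is available behind `min_object_px`.
#'
#' @param crop RGB array (any size) in \[0, 1\].
#' @param hue_band `c(low, high)` hue band in degrees, 0–360.
#' @param min_saturation,min_value minimum S and V (fractions in \[0, 1\]).
#' @param min_object_px if positive, foreground components smaller than this
#'   are also removed (off by default).
#' @return The filtered crop, same dimensions, with attribute `mask`
#'   (logical matrix of kept pixels).
#' @export
remove_background <- function(crop, hue_band = c(70, 160),
                              min_saturation = 0.2, min_value = 0.15,
                              min_object_px = 0) {
  if (length(hue_band) != 2 || hue_band[2] <= hue_band[1]) {
    ss_abort("hue_band must be c(low, high) with low < high",
      class = "seedstage_config_error"
    )
  }
  d <- dim(crop)
  rgb <- rbind(
    as.vector(crop[, , 1]), as.vector(crop[, , 2]), as.vector(crop[, , 3])
  )
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  keep <- hsv[1, ] * 360 >= hue_band[1] & hsv[1, ] * 360 <= hue_band[2] &
    hsv[2, ] >= min_saturation & hsv[3, ] >= min_value
  mask <- matrix(keep, d[1], d[2])
  if (min_object_px > 0 && any(mask)) {
    lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
    sizes <- tabulate(lab[lab > 0])
    mask <- mask & matrix(lab %in% which(sizes >= min_object_px), d[1], d[2])
  }
  out <- crop
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[!mask] <- 0
    out[, , ch] <- plane
  }
  attr(out, "mask") <- mask
  out
}
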
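# Synthetic fundus scenes with exact ground-truth geometry.
#
# A scene places a bright elliptical optic disc nasally and a darker foveal
# region temporal to it at a controlled angle to the horizontal. The label
# map marks the disc ellipse (class 1) and a "virtual macular area" disc of
# fixed radius centered on the fovea (class 2): at the native camera
# resolution of 2584 x 1985 that radius is 400 px, and it scales linearly
# with image width for smaller renders. Vessel arcs and sensor noise are
# nuisance structure only and are never labeled.

NATIVE_WIDTH <- 2584
NATIVE_MACULA_RADIUS <- 400

default_macula_radius <- function(width) NATIVE_MACULA_RADIUS * width / NATIVE_WIDTH

#' Construct a synthetic fundus scene
#'
#' Places the optic disc nasally (with small seeded jitter) and the fovea at
#' distance `disc_fovea_distance` from the disc center such that the signed
#' disc-fovea angle of the two stored centers equals `dfa` up to rounding of
#' the centers to the pixel grid (at most 0.5 px per coordinate). The stored
#' `true_dfa` is recomputed from the rounded centers, so it is exactly
#' consistent with [compute_dfa()].
#'
#' @param width,height Image size in pixels (each at least 64).
#' @param dfa Target disc-fovea angle in degrees, `|dfa| <= 90`. Positive
#'   angles place the fovea above the disc-center horizontal (y grows
#'   downward).
#' @param disc_fovea_distance Center-to-center distance in pixels.
#' @param seed Integer seed controlling placement jitter, vessels and noise.
#' @param disc_radii Optional `(rx, ry)` ellipse semi-axes; default scales
#'   a typical disc size with image width.
#' @param macula_label_radius Virtual-macula label radius; default
#'   `400 * width / 2584`.
#' @param n_vessels Number of vessel arcs rendered (nuisance texture).
#' @param noise_sigma Gaussian noise standard deviation on the `[0, 1]`
#'   intensity scale.
#' @param mirror Mirror the layout (fovea nasal at negative x offset), as in
#'   a fellow-eye image. Default off.
#' @return A `fundus_scene` object (a list of the geometric parameters).
#' @export
make_scene <- function(width, height, dfa, disc_fovea_distance, seed = 1L,
                       disc_radii = NULL, macula_label_radius = NULL,
                       n_vessels = 4L, noise_sigma = 0.02, mirror = FALSE) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 64 || height < 64)
    stop_dfameter("bad_scene", "width and height must be at least 64 px")
  if (abs(dfa) > 90)
    stop_dfameter("bad_scene", "|dfa| must not exceed 90 degrees")
  if (is.null(macula_label_radius)) macula_label_radius <- default_macula_radius(width)
  if (macula_label_radius <= 0)
    stop_dfameter("bad_scene", "macula_label_radius must be positive")

  jit <- with_seed(seed, runif(5, -1, 1))
  if (is.null(disc_radii))
    disc_radii <- width * c(0.090, 0.082) * (1 + 0.05 * jit[1:2])
  if (any(disc_radii <= 0))
    stop_dfameter("bad_scene", "disc_radii must be positive")

  dx0 <- if (mirror) 0.70 else 0.30
  disc <- round(c(width * (dx0 + 0.02 * jit[3]),
                  height * (0.5 + 0.03 * jit[4])))
  th <- dfa * pi / 180
  sgn <- if (mirror) -1 else 1
  fovea <- round(c(disc[1] + sgn * disc_fovea_distance * cos(th),
                   disc[2] - disc_fovea_distance * sin(th)))

  margin <- 2
  in_bounds <- function(cx, cy, rx, ry)
    cx - rx >= 1 + margin && cx + rx <= width - margin &&
      cy - ry >= 1 + margin && cy + ry <= height - margin
  if (!in_bounds(disc[1], disc[2], disc_radii[1], disc_radii[2]) ||
      !in_bounds(fovea[1], fovea[2], macula_label_radius, macula_label_radius))
    stop_dfameter("placement_impossible", sprintf(
      "scene geometry exits the %d x %d image bounds (disc at %d,%d; fovea at %d,%d)",
      width, height, disc[1], disc[2], fovea[1], fovea[2]))
  if (sqrt(sum((fovea - disc)^2)) <= max(disc_radii) + macula_label_radius + margin)
    stop_dfameter("placement_impossible",
                  "disc ellipse and virtual macula circle would overlap")

  structure(list(
    width = width, height = height,
    disc_center = c(x = disc[1], y = disc[2]),
    disc_radii = c(rx = disc_radii[1], ry = disc_radii[2]),
    fovea_center = c(x = fovea[1], y = fovea[2]),
    true_dfa = compute_dfa(disc, fovea),
    macula_label_radius = macula_label_radius,
    n_vessels = as.integer(n_vessels),
    noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "fundus_scene")
}

#' @export
print.fundus_scene <- function(x, ...) {
  cat(sprintf("Synthetic fundus scene %d x %d px\n", x$width, x$height))
  cat(sprintf("  disc center (%d, %d), semi-axes (%.1f, %.1f) px\n",
              x$disc_center[1], x$disc_center[2], x$disc_radii[1], x$disc_radii[2]))
  cat(sprintf("  fovea center (%d, %d), macula label radius %.1f px\n",
              x$fovea_center[1], x$fovea_center[2], x$macula_label_radius))
  cat(sprintf("  true DFA %.4f deg; %d vessels, noise sd %.3f, seed %d\n",
              x$true_dfa, x$n_vessels, x$noise_sigma, x$seed))
  invisible(x)
}

#' Render the color image of a scene
#'
#' Deterministic for a given scene: the scene seed drives vessel geometry
#' and sensor noise. Produces a reddish background field with mild
#' vignetting, a bright ellipse at the disc, a dark radial falloff around
#' the fovea, dark quadratic-Bezier vessel arcs emanating from the disc,
#' and additive Gaussian noise.
#'
#' @param scene A `fundus_scene`.
#' @return An `height x width x 3` array with values in `[0, 1]`.
#' @export
render_image <- function(scene) {
  stopifnot(inherits(scene, "fundus_scene"))
  H <- scene$height; W <- scene$width
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)

  # background: reddish field with a soft vignette
  v <- 1 - 0.35 * (((xs - W / 2) / (W / 2))^2 + ((ys - H / 2) / (H / 2))^2)
  r <- 0.62 * v; g <- 0.30 * v; b <- 0.12 * v

  # optic disc: bright yellowish ellipse with a soft rim
  dc <- scene$disc_center; dr <- scene$disc_radii
  e <- ((xs - dc[1]) / dr[1])^2 + ((ys - dc[2]) / dr[2])^2
  rim <- clamp01((1.15 - sqrt(e)) / 0.3)
  r <- r + 0.35 * rim; g <- g + 0.45 * rim; b <- b + 0.25 * rim

  # fovea: dark radial falloff scaled to the macula label radius
  fc <- scene$fovea_center
  sig <- 0.5 * scene$macula_label_radius
  f <- exp(-((xs - fc[1])^2 + (ys - fc[2])^2) / (2 * sig^2))
  dark <- 1 - 0.45 * f
  r <- r * dark; g <- g * dark; b <- b * dark

  with_seed(scene$seed + 1L, {
    if (scene$n_vessels > 0) {
      vmask <- matrix(FALSE, H, W)
      thick <- max(1L, round(0.004 * W))
      off <- expand.grid(dy = -thick:thick, dx = -thick:thick)
      off <- off[off$dx^2 + off$dy^2 <= thick^2, ]
      for (k in seq_len(scene$n_vessels)) {
        # arcs leave the disc up/down and bend temporally
        a0 <- sample(c(-1, 1), 1) * runif(1, 0.25 * pi, 0.75 * pi)
        p0 <- dc
        p2 <- c(runif(1, 0.05, 0.95) * W, if (a0 > 0) runif(1, 0.02, 0.25) * H
                else runif(1, 0.75, 0.98) * H)
        p1 <- c(dc[1] + 0.45 * W * cos(a0) * 0.3, dc[2] - sign(a0) * 0.35 * H)
        t <- seq(0, 1, length.out = max(80L, W))
        px <- round((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1])
        py <- round((1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
        for (i in seq_along(t)) {
          rr <- py[i] + off$dy; cc <- px[i] + off$dx
          ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
          vmask[cbind(rr[ok], cc[ok])] <- TRUE
        }
      }
      r[vmask] <- r[vmask] * 0.45
      g[vmask] <- g[vmask] * 0.45
      b[vmask] <- b[vmask] * 0.45
    }
    if (scene$noise_sigma > 0) {
      n <- scene$noise_sigma
      r <- r + rnorm(H * W, 0, n)
      g <- g + rnorm(H * W, 0, n)
      b <- b + rnorm(H * W, 0, n)
    }
  })

  array(c(clamp01(r), clamp01(g), clamp01(b)), c(H, W, 3))
}

#' Render the ground-truth label mask of a scene
#'
#' A pixel belongs to a region iff its integer-coordinate center does:
#' class 1 inside the disc ellipse, class 2 within `macula_label_radius` of
#' the fovea center, 0 elsewhere. Valid scenes keep the two regions
#' disjoint; an overlap raises an error rather than silently resolving it.
#'
#' @param scene A `fundus_scene`.
#' @return An integer `height x width` matrix with values in `{0, 1, 2}`.
#' @export
render_labels <- function(scene) {
  stopifnot(inherits(scene, "fundus_scene"))
  H <- scene$height; W <- scene$width
  dc <- scene$disc_center; dr <- scene$disc_radii; fc <- scene$fovea_center
  dx2e <- ((seq_len(W) - dc[1]) / dr[1])^2
  dy2e <- ((seq_len(H) - dc[2]) / dr[2])^2
  disc <- outer(dy2e, dx2e, "+") <= 1
  dx2 <- (seq_len(W) - fc[1])^2
  dy2 <- (seq_len(H) - fc[2])^2
  mac <- outer(dy2, dx2, "+") <= scene$macula_label_radius^2
  if (any(disc & mac))
    stop_dfameter("region_overlap",
                  "disc ellipse and virtual macula circle overlap in the raster")
  mask <- matrix(0L, H, W)
  mask[mac] <- 2L
  mask[disc] <- 1L
  mask
}

#' Generate a synthetic dataset with ground-truth manifest
#'
#' Draws `n` scenes with angles and disc-fovea distances sampled from the
#' configured ranges, and either returns them in memory or writes 8-bit PNG
#' image/mask pairs plus a `manifest.csv` with the exact ground truth per
#' record. Fully reproducible from `seed`.
#'
#' @param n Number of images (at least 1).
#' @param dir Output directory; `NULL` (default) keeps the dataset in memory.
#' @param width,height Image size in pixels.
#' @param dfa_range Range (degrees) from which true angles are drawn.
#' @param dist_frac_range Disc-fovea distance range as a fraction of width.
#' @param n_vessels,noise_sigma Nuisance-structure parameters per scene.
#' @param seed Integer seed.
#' @return Invisibly (or visibly when `dir = NULL`) a list with `manifest`
#'   (data frame: id, image_path, mask_path, disc_x, disc_y, fovea_x,
#'   fovea_y, true_dfa_deg), and, in memory mode, `images`, `masks`,
#'   `scenes`.
#' @export
make_dataset <- function(n, dir = NULL, width = 512, height = 512,
                         dfa_range = c(-10, 10),
                         dist_frac_range = c(0.29, 0.33),
                         n_vessels = 4L, noise_sigma = 0.02, seed = 1L) {
  stopifnot(n >= 1)
  draws <- with_seed(seed, list(
    dfa = runif(n, dfa_range[1], dfa_range[2]),
    frac = runif(n, dist_frac_range[1], dist_frac_range[2]),
    scene_seed = sample.int(.Machine$integer.max %/% 2L, n)
  ))
  scenes <- lapply(seq_len(n), function(i)
    make_scene(width, height, draws$dfa[i], draws$frac[i] * width,
               seed = draws$scene_seed[i],
               n_vessels = n_vessels, noise_sigma = noise_sigma))
  images <- lapply(scenes, render_image)
  masks <- lapply(scenes, render_labels)
  id <- sprintf("img%04d", seq_len(n))
  manifest <- data.frame(
    id = id,
    image_path = file.path("images", paste0(id, ".png")),
    mask_path = file.path("masks", paste0(id, ".png")),
    disc_x = vapply(scenes, function(s) s$disc_center[["x"]], 0),
    disc_y = vapply(scenes, function(s) s$disc_center[["y"]], 0),
    fovea_x = vapply(scenes, function(s) s$fovea_center[["x"]], 0),
    fovea_y = vapply(scenes, function(s) s$fovea_center[["y"]], 0),
    true_dfa_deg = vapply(scenes, function(s) s$true_dfa, 0)
  )
  if (is.null(dir))
    return(list(manifest = manifest, images = images, masks = masks,
                scenes = scenes))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    write_image_png(images[[i]], file.path(dir, manifest$image_path[i]))
    write_mask_png(masks[[i]], file.path(dir, manifest$mask_path[i]))
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, dir = dir))
}

#' Read a dataset written by [make_dataset()] back into memory
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return A list with `manifest`, `images`, `masks`.
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path))
    stop_dfameter("io", sprintf("no manifest found at %s", path))
  manifest <- read.csv(path)
  list(manifest = manifest,
       images = lapply(file.path(dir, manifest$image_path), read_image_png),
       masks = lapply(file.path(dir, manifest$mask_path), read_mask_png))
}
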
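#' Imaging configuration for synthetic code rendering
#'
#' Collects the geometry and imperfection parameters used to render
#' synthetic fluorescence rasters of matrix codes. The `"full"` profile
#' reproduces the reference imaging geometry: a 692 x 648 pixel canvas
#' (width x height, i.e. 648 rows by 692 columns) holding a 7 x 7 grid of
#' square units whose library crops are 101 x 101 pixels. The `"desk"`
#' profile is a reduced 96 x 96 geometry suitable for CPU-bound training
#' runs; the generative model is identical, only the resolution differs.
#'
#' @param profile `"full"` or `"desk"` preset; individual arguments
#'   override preset values.
#' @param noise `"default"` (moderate fabrication noise), `"easy"`
#'   (mild), or `"none"` (exact noiseless rendering, used by the
#'   generator/decoder consistency oracle).
#' @param canvas `(rows, cols)` canvas size in pixels.
#' @param n grid side (cells per row/column).
#' @param margin_px margin between canvas border and the cell grid.
#' @param unit_active_side side (px) of the active patch placed per cell.
#' @param patch_side side (px) of unit patches in the library.
#' @param jitter_px maximum absolute placement offset per axis.
#' @param fill_intensity_range `[lo, hi]` of the fluorescence signal of a
#'   filled unit, above background, on the [0,1] intensity scale.
#' @param background_level mean background intensity.
#' @param background_noise_sd additive Gaussian background noise sd.
#' @param blur_sigma Gaussian blur sigma (px) applied to unit patches
#'   (models optical point spread).
#' @param edge_roughness relative amplitude of the random boundary
#'   displacement of a filled unit (0 = perfect squares).
#' @param intensity_fraction remaining fluorescence amplitude in [0,1];
#'   1 renders undegraded codes, smaller values emulate photobleaching or
#'   thermal loss of fluorescence.
#' @param seed default seed recorded with the config.
#' @return An `imaging_config` list.
#' @export
imaging_config <- function(profile = c("full", "desk"),
                           noise = c("default", "easy", "none"),
                           canvas = NULL, n = 7L, margin_px = NULL,
                           unit_active_side = NULL, patch_side = NULL,
                           jitter_px = NULL, fill_intensity_range = NULL,
                           background_level = 0.08,
                           background_noise_sd = NULL, blur_sigma = NULL,
                           edge_roughness = NULL, intensity_fraction = 1.0,
                           seed = NULL) {
  profile <- match.arg(profile)
  noise <- match.arg(noise)
  preset <- switch(profile,
    full = list(canvas = c(648L, 692L), margin_px = 10L,
                unit_active_side = 70L, patch_side = 101L, jitter_px = 3L),
    desk = list(canvas = c(96L, 96L), margin_px = 2L,
                unit_active_side = 9L, patch_side = 9L, jitter_px = 1L))
  nz <- switch(noise,
    default = list(background_noise_sd = 0.02, edge_roughness = 0.15,
                   fill_intensity_range = c(0.65, 0.85),
                   blur_sigma = if (profile == "full") 2.0 else 0.5),
    easy    = list(background_noise_sd = 0.01, edge_roughness = 0.08,
                   fill_intensity_range = c(0.72, 0.85),
                   blur_sigma = if (profile == "full") 1.5 else 0.4),
    none    = list(background_noise_sd = 0, edge_roughness = 0,
                   fill_intensity_range = c(0.8, 0.8), blur_sigma = 0))
  cfg <- list(
    profile = profile, noise = noise,
    canvas = as.integer(canvas %||% preset$canvas),
    n = as.integer(n),
    margin_px = as.integer(margin_px %||% preset$margin_px),
    unit_active_side = as.integer(unit_active_side %||% preset$unit_active_side),
    patch_side = as.integer(patch_side %||% preset$patch_side),
    jitter_px = as.integer(jitter_px %||% preset$jitter_px),
    fill_intensity_range = fill_intensity_range %||% nz$fill_intensity_range,
    background_level = background_level,
    background_noise_sd = background_noise_sd %||% nz$background_noise_sd,
    blur_sigma = blur_sigma %||% nz$blur_sigma,
    edge_roughness = edge_roughness %||% nz$edge_roughness,
    intensity_fraction = intensity_fraction,
    seed = seed)
  if (cfg$intensity_fraction < 0 || cfg$intensity_fraction > 1)
    stop("intensity_fraction must be in [0, 1]")
  if (cfg$fill_intensity_range[1] <= 0)
    stop("fill_intensity_range lower bound must be positive: a filled unit ",
         "must sit above background, otherwise patches are undetectable ",
         "by construction")
  geom <- grid_geometry(cfg)   # errors early on impossible layouts
  cfg$pitch <- geom$pitch
  structure(cfg, class = "imaging_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grid geometry implied by an imaging config
#'
#' @param config an `imaging_config`.
#' @return List with per-axis cell pitch, cell centers, and the active
#'   box bounds; errors with a geometry report when the grid (including
#'   jitter) cannot fit the canvas.
#' @keywords internal
grid_geometry <- function(config) {
  rows <- config$canvas[1]; cols <- config$canvas[2]
  n <- config$n; m <- config$margin_px
  pitch <- c((rows - 2 * m) / n, (cols - 2 * m) / n)
  need <- config$unit_active_side + 2 * config$jitter_px
  if (any(pitch < need))
    stop("grid overflows canvas: cell pitch (", round(pitch[1], 1), ", ",
         round(pitch[2], 1), ") px cannot hold active side ",
         config$unit_active_side, " px + jitter ", config$jitter_px,
         " px on a ", rows, " x ", cols, " canvas with ", m, " px margins")
  centers_r <- m + (seq_len(n) - 0.5) * pitch[1]
  centers_c <- m + (seq_len(n) - 0.5) * pitch[2]
  list(pitch = pitch, centers_r = centers_r, centers_c = centers_c)
}

# smooth periodic boundary perturbation, max amplitude 1
.rough_profile <- function(theta) {
  g <- 0
  for (k in 1:4) g <- g + stats::rnorm(1, 0, 1 / k) * sin(k * theta +
                                                          stats::runif(1, 0, 2 * pi))
  mx <- max(abs(g), 1e-9)
  g / mx
}

#' Generate one synthetic unit patch
#'
#' A filled patch is a centred rounded square whose boundary is displaced
#' by a smooth random profile (fabrication edge roughness), filled with a
#' smoothly varying fluorescence intensity drawn from
#' `fill_intensity_range`, blurred by a Gaussian point spread, and summed
#' with the mean background plus additive Gaussian noise. An empty patch
#' is background plus noise only. Deterministic given the RNG state (set
#' `seed`).
#'
#' @param filled logical; render a fluorescent (filled) or empty unit.
#' @param config an `imaging_config`.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A `unit_patch`: list with `pixels` (patch_side x patch_side
#'   matrix in [0,1]), `filled`, and `provenance`.
#' @export
make_unit_patch <- function(filled, config = imaging_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- config$patch_side
  bg <- config$background_level
  fr <- config$fill_intensity_range
  if (fr[1] <= 0)
    stop("fill intensity must exceed zero signal above background")
  px <- matrix(bg, s, s)
  if (filled) {
    # coordinates in [-1, 1] across the patch
    u <- (seq_len(s) - (s + 1) / 2) / (s / 2)
    X <- matrix(u, s, s, byrow = TRUE)   # column coordinate
    Y <- matrix(u, s, s)                 # row coordinate
    h0 <- 0.80                            # nominal half-side, patch units
    theta <- atan2(Y, X)
    if (config$edge_roughness > 0) {
      a <- stats::rnorm(4, 0, 1 / (1:4)); phi <- stats::runif(4, 0, 2 * pi)
      g <- matrix(0, s, s)
      for (k in 1:4) g <- g + a[k] * sin(k * theta + phi[k])
      g <- g / max(abs(g), 1e-9)
      h <- h0 * (1 + config$edge_roughness * g)
    } else h <- h0
    mask <- pmax(abs(X), abs(Y)) <= h
    base <- stats::runif(1, fr[1], fr[2])
    amp <- 0.5 * min(base - fr[1], fr[2] - base)
    if (amp > 0) {
      uu <- stats::runif(2, -1.5, 1.5); ph <- stats::runif(1, 0, 2 * pi)
      field <- base + amp * sin(pi * (uu[1] * X + uu[2] * Y) + ph)
    } else field <- base
    sig <- ifelse(mask, field, 0)
    if (config$blur_sigma > 0)
      sig <- as.matrix(EBImage::gblur(sig, sigma = config$blur_sigma,
                                      boundary = "replicate"))
    px <- px + sig
  }
  if (config$background_noise_sd > 0)
    px <- px + matrix(stats::rnorm(s * s, 0, config$background_noise_sd), s, s)
  px <- pmin(pmax(px, 0), 1)
  structure(list(pixels = px, filled = filled,
                 provenance = list(patch_side = s, background = bg,
                                   fill_range = fr, seed = seed)),
            class = "unit_patch")
}

#' Build a library of filled and empty unit patches
#'
#' Emulates the pool of cropped real square units from which synthetic
#' codes are composed (200 crops of 101 x 101 pixels in the reference
#' recipe): `n_patches` filled and `n_patches` empty patches, all drawn
#' from the imperfection model under one seed.
#'
#' @param n_patches number of filled (and of empty) patches.
#' @param config an `imaging_config`.
#' @param seed integer seed.
#' @return A `patch_library`: list with `filled`, `empty` (lists of
#'   `unit_patch`), `patch_side`, `config`, `seed`.
#' @export
build_patch_library <- function(n_patches = 200L, config = imaging_config(),
                                seed = 1L) {
  stopifnot(n_patches >= 1)
  set.seed(seed)
  filled <- replicate(n_patches, make_unit_patch(TRUE, config), simplify = FALSE)
  empty <- replicate(n_patches, make_unit_patch(FALSE, config), simplify = FALSE)
  structure(list(filled = filled, empty = empty,
                 patch_side = config$patch_side, config = config, seed = seed),
            class = "patch_library")
}

#' Resize a patch library to a new unit side
#'
#' Used to map 101 x 101 library crops onto the active cell area of the
#' composed canvas (about 70 px for the full-scale 7 x 7 geometry).
#' Bilinear resampling via EBImage.
#'
#' @param library a `patch_library`.
#' @param side target side in pixels.
#' @return The resized `patch_library`.
#' @export
resize_patch_library <- function(library, side) {
  if (library$patch_side == side) return(library)
  rs <- function(p) {
    p$pixels <- pmin(pmax(as.matrix(
      EBImage::resize(p$pixels, w = side, h = side)), 0), 1)
    p
  }
  library$filled <- lapply(library$filled, rs)
  library$empty <- lapply(library$empty, rs)
  library$patch_side <- as.integer(side)
  library
}

#' Render one fluorescence channel of a matrix code
#'
#' Produces the grayscale raster a camera would record through one
#' excitation/emission filter set: cells whose symbol matches `channel`
#' receive a randomly drawn filled patch at their grid position (with
#' placement jitter), all other cells an empty patch; the rest of the
#' canvas is background plus noise. Degradation multiplies the
#' foreground-above-background amplitude of filled patches by
#' `config$intensity_fraction`.
#'
#' @param code a `matrix_code`.
#' @param channel `"ECFP"`, `"EGFP"` or `"MKATE2"` (not `"NONE"`).
#' @param library a `patch_library` whose `patch_side` equals
#'   `config$unit_active_side` (see [resize_patch_library()]).
#' @param config an `imaging_config` with `config$n == code$n`.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return Numeric matrix `canvas[1] x canvas[2]` in [0,1], with
#'   attributes `background_level` and `channel`.
#' @export
compose_channel_image <- function(code, channel, library,
                                  config = imaging_config(), seed = NULL) {
  stopifnot(inherits(code, "matrix_code"), inherits(library, "patch_library"))
  channel <- match.arg(channel, channel_order)
  if (config$n != code$n)
    stop("config grid side (", config$n, ") != code side (", code$n, ")")
  if (library$patch_side != config$unit_active_side)
    stop("library patch side ", library$patch_side, " != configured active ",
         "side ", config$unit_active_side,
         "; use resize_patch_library() or rebuild the library")
  if (!is.null(seed)) set.seed(seed)
  geom <- grid_geometry(config)
  rows <- config$canvas[1]; cols <- config$canvas[2]
  bg <- config$background_level
  canvas <- matrix(bg, rows, cols)
  if (config$background_noise_sd > 0)
    canvas <- canvas + matrix(stats::rnorm(rows * cols, 0,
                                           config$background_noise_sd),
                              rows, cols)
  a <- config$unit_active_side
  j <- config$jitter_px
  target <- code_symbols[[channel]]
  nf <- length(library$filled); ne <- length(library$empty)
  for (r in seq_len(code$n)) {
    for (cc in seq_len(code$n)) {
      hit <- code$cells[r, cc] == target
      patch <- if (hit) library$filled[[sample.int(nf, 1)]]
               else library$empty[[sample.int(ne, 1)]]
      pix <- patch$pixels
      if (hit && config$intensity_fraction < 1)
        pix <- bg + (pix - bg) * config$intensity_fraction
      jr <- if (j > 0) sample.int(2L * j + 1L, 1L) - j - 1L else 0L
      jc <- if (j > 0) sample.int(2L * j + 1L, 1L) - j - 1L else 0L
      tl_r <- round(geom$centers_r[r] - a / 2) + jr
      tl_c <- round(geom$centers_c[cc] - a / 2) + jc
      canvas[tl_r:(tl_r + a - 1L), tl_c:(tl_c + a - 1L)] <- pix
    }
  }
  canvas <- pmin(pmax(canvas, 0), 1)
  attr(canvas, "background_level") <- bg
  attr(canvas, "channel") <- channel
  canvas
}

#' Render all three channel images of a matrix code
#'
#' @inheritParams compose_channel_image
#' @return A `code_image_set`: list with `channels` (named list of three
#'   rasters), `truth` (the `matrix_code`), and `config`.
#' @export
render_code <- function(code, library, config = imaging_config(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chans <- lapply(channel_order, function(ch)
    compose_channel_image(code, ch, library, config))
  names(chans) <- channel_order
  structure(list(channels = chans, truth = code, config = config),
            class = "code_image_set")
}

config_hash <- function(config) {
  paste(unclass(as.character(openssl::md5(charToRaw(
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))))))
}

#' Generate a labelled synthetic data set
#'
#' Draws `n_images` random codes and renders them. In `"channel"` mode
#' each item is one single-channel raster paired with its ground-truth
#' binary channel key (the decoder's training unit); channels are
#' assigned round-robin. In `"code"` mode each item is a full
#' three-channel `code_image_set` paired with its digitized key.
#'
#' @param n_images number of labelled items.
#' @param library a `patch_library`.
#' @param config an `imaging_config` (carries the grid side `n`).
#' @param seed integer seed governing codes, patch draws and noise.
#' @param mode `"channel"` or `"code"`.
#' @return A `labeled_set`: list with `items`, `mode`, `n`, and
#'   `manifest` (seed, counts, config hash).
#' @export
generate_dataset <- function(n_images, library, config = imaging_config(),
                             seed = 1L, mode = c("channel", "code")) {
  stopifnot(n_images >= 1)
  mode <- match.arg(mode)
  set.seed(seed)
  n <- config$n
  items <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    code <- random_code(n, seed = NULL, allow_other_n = TRUE)
    if (mode == "channel") {
      ch <- channel_order[(i - 1L) %% 3L + 1L]
      raster <- compose_channel_image(code, ch, library, config)
      items[[i]] <- list(raster = raster,
                         key = encode_channels(code)[[ch]],
                         channel = ch)
    } else {
      set <- render_code(code, library, config)
      items[[i]] <- list(images = set, key = concat_key(encode_channels(code)))
    }
  }
  structure(list(items = items, mode = mode, n = n,
                 manifest = list(seed = seed, n_images = n_images,
                                 mode = mode, config_hash = config_hash(config))),
            class = "labeled_set")
}

#' Degrade the fluorescence intensity of a rendered raster
#'
#' Scales the foreground-above-background amplitude by `fraction` while
#' leaving background statistics unchanged: pixels above
#' `background_level + 3 * background_noise_sd` are pulled towards the
#' background linearly, the rest untouched. `fraction = 1` is the
#' identity; `fraction = 0` flattens every foreground pixel to
#' background. Degradation of whole scenes at render time uses
#' `config$intensity_fraction` instead, which scales the signal exactly.
#'
#' @param raster matrix from [compose_channel_image()].
#' @param fraction remaining intensity fraction in [0,1].
#' @param background_level background mean; defaults to the raster's
#'   `background_level` attribute.
#' @param background_noise_sd noise sd used for the foreground mask.
#' @return Degraded raster (attributes preserved).
#' @export
degrade_intensity <- function(raster, fraction,
                              background_level = attr(raster, "background_level"),
                              background_noise_sd = 0) {
  if (is.null(background_level))
    stop("background_level is required (raster has no background attribute)")
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]")
  out <- raster
  mask <- raster > background_level + 3 * background_noise_sd
  out[mask] <- background_level + (raster[mask] - background_level) * fraction
  attributes(out) <- attributes(raster)
  out
}

#' Write a grayscale raster to an image file
#'
#' TIFF output is 16-bit; PNG output is 8-bit (the PNG writer's
#' precision). Intensities map linearly from [0,1].
#'
#' @param raster numeric matrix in [0,1] (rows x cols).
#' @param path output path; format from the extension (.png/.tif/.tiff).
#' @export
write_raster <- function(raster, path) {
  EBImage::writeImage(EBImage::Image(t(raster)), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale raster written by [write_raster()]
#'
#' @param path image file.
#' @return Numeric matrix in [0,1] (rows x cols).
#' @export
read_raster <- function(path) {
  img <- EBImage::readImage(path)
  m <- as.matrix(img)
  if (length(dim(EBImage::imageData(img))) > 2)
    m <- EBImage::imageData(img)[, , 1]
  t(m)
}
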
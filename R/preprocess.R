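# Conversion of raw clips to the network input representation, plus the
# training-time augmentation cascade and frame-sampling policies.

#' Preprocessing configuration
#'
#' @param target_size Side length in pixels of the square network input
#'   (>= 32). Frames are resized to this height with preserved aspect
#'   ratio, then centre-cropped (or zero-padded) to a square.
#' @param crop_region Optional rectangle `c(y0, y1, x0, x1)` (1-based,
#'   inclusive pixel coordinates) cropped from the raw frames first; a
#'   generic stand-in for metadata-driven removal of vendor overlays.
#' @param train_frames_per_clip Frames sampled per clip during training.
#' @param augment Master toggle for the augmentation cascade.
#' @param rotation_range Rotation angle range in degrees.
#' @param gamma_range Gamma-correction exponent range.
#' @param crop_scale_range Scale range of the random resized crop.
#' @param elastic_alpha Elastic-distortion intensity in pixels (x and y).
#' @param elastic_sigma Smoothing bandwidth (pixels) of the elastic
#'   displacement field.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param p_transform Probability that each cascade stage is applied.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 224L, crop_region = NULL,
                              train_frames_per_clip = 8L, augment = TRUE,
                              rotation_range = c(-25, 25),
                              gamma_range = c(0.5, 2),
                              crop_scale_range = c(0.2, 2),
                              elastic_alpha = 2, elastic_sigma = 8,
                              noise_sd = 0.01, p_transform = 0.5) {
  if (target_size < 32) stop("target_size must be >= 32")
  structure(list(target_size = as.integer(target_size),
                 crop_region = crop_region,
                 train_frames_per_clip = as.integer(train_frames_per_clip),
                 augment = isTRUE(augment),
                 rotation_range = rotation_range, gamma_range = gamma_range,
                 crop_scale_range = crop_scale_range,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 noise_sd = noise_sd, p_transform = p_transform),
            class = "preprocess_config")
}

#' Convert RGB (or grayscale) frames to single-channel `[0, 1]`
#'
#' Three-channel pixel data in `[0, 255]` are reduced by the unweighted
#' channel mean and divided by 255. The unweighted mean (rather than luma
#' weights) corresponds to averaging a pretrained input layer's RGB
#' weights into one channel. Already single-channel input is passed
#' through after rescaling; input already in `[0, 1]` with no channel
#' axis is returned unchanged, making the operation idempotent.
#'
#' @param frames `T x H x W x 3` (or `T x H x W x 1` or `T x H x W`)
#'   numeric array.
#' @return `T x H x W` array of reals in `[0, 1]`.
#' @export
to_grayscale <- function(frames) {
  d <- dim(frames)
  if (any(frames < 0) || any(frames > 255))
    stop("pixel values must lie in [0, 255]")
  if (length(d) == 3) {
    if (max(frames) <= 1) return(frames)
    return(frames / 255)
  }
  if (length(d) != 4 || !(d[4] %in% c(1L, 3L)))
    stop("expected a T x H x W x {1,3} array")
  out <- frames[, , , 1, drop = TRUE]
  if (d[4] == 3L)
    out <- (frames[, , , 1] + frames[, , , 2] + frames[, , , 3]) / 3
  dim(out) <- d[1:3]
  if (max(out) > 1) out <- out / 255
  out
}

resize_bilinear <- function(img, h, w) {
  EBImage::resize(img, w = h, h = w) # EBImage's first dim is our row axis
}

#' Crop, aspect-preserving resize and centre square crop
#'
#' Optionally crops `cfg$crop_region` first, then resizes every frame to
#' `cfg$target_size` pixels in height with maintained aspect ratio
#' (bilinear), then centre-crops the width to a square. If the
#' post-resize width falls short of the target, the frame is
#' symmetrically zero-padded instead of stretched.
#'
#' @param frames `T x H x W` array.
#' @param cfg A [preprocess_config()].
#' @return `T x S x S` array with `S = cfg$target_size`.
#' @export
crop_resize_center <- function(frames, cfg = preprocess_config()) {
  d <- dim(frames)
  stopifnot(length(d) == 3)
  if (!is.null(cfg$crop_region)) {
    cr <- cfg$crop_region
    if (cr[1] < 1 || cr[3] < 1 || cr[2] > d[2] || cr[4] > d[3] ||
        cr[1] > cr[2] || cr[3] > cr[4])
      stop("crop_region outside frame bounds")
    frames <- frames[, cr[1]:cr[2], cr[3]:cr[4], drop = FALSE]
    d <- dim(frames)
  }
  S <- cfg$target_size
  new_w <- max(1L, as.integer(round(d[3] * S / d[2])))
  out <- array(0, dim = c(d[1], S, S))
  if (new_w >= S) {
    x0 <- (new_w - S) %/% 2
    cols <- (x0 + 1):(x0 + S)
  } else {
    pad <- (S - new_w) %/% 2
    cols <- (pad + 1):(pad + new_w)
  }
  for (t in seq_len(d[1])) {
    r <- resize_bilinear(frames[t, , ], S, new_w)
    if (new_w >= S) out[t, , ] <- r[, cols] else out[t, , cols] <- r
  }
  out
}

# Gaussian blur of a matrix by separable convolution (used to smooth the
# elastic displacement field).
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_apply <- function(x) {
    n <- nrow(x)
    xp <- rbind(x[rep(1, r), , drop = FALSE], x, x[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + n - 1), , drop = FALSE]
    out
  }
  t(pad_apply(t(pad_apply(m))))
}

# Compose the geometric stages (rotation, resized crop, elastic) into one
# coordinate map and resample each frame once; all frames of the clip
# share the same parameter draw, preserving temporal consistency.
augment_maps <- function(S, do, params, cfg) {
  ctr <- (S + 1) / 2
  grid_y <- matrix(seq_len(S), S, S)
  grid_x <- matrix(seq_len(S), S, S, byrow = TRUE)
  map_y <- grid_y
  map_x <- grid_x
  if (do["crop"]) {
    s <- params$crop_scale
    map_y <- (map_y - ctr) / s + ctr
    map_x <- (map_x - ctr) / s + ctr
  }
  if (do["rotation"]) {
    th <- params$angle * pi / 180
    dy <- map_y - ctr
    dx <- map_x - ctr
    map_y <- ctr + cos(th) * dy - sin(th) * dx
    map_x <- ctr + sin(th) * dy + cos(th) * dx
  }
  if (do["elastic"]) {
    map_y <- map_y + gaussian_smooth(params$elastic_dy, cfg$elastic_sigma) *
      cfg$elastic_alpha
    map_x <- map_x + gaussian_smooth(params$elastic_dx, cfg$elastic_sigma) *
      cfg$elastic_alpha
  }
  list(map_y = map_y - 1, map_x = map_x - 1) # 0-based for the resampler
}

#' Stochastic augmentation cascade
#'
#' Applies, in order and each gated by an independent coin with
#' probability `cfg$p_transform`: rotation, gamma correction, resized
#' crop (zoom), elastic distortion and additive Gaussian noise. One
#' parameter draw is shared by all frames of the clip so that temporal
#' structure survives augmentation. Geometric stages use bilinear
#' resampling with zero (background) fill; the output is clipped to
#' `[0, 1]` and shape-preserving.
#'
#' @param frames `T x S x S` array in `[0, 1]`.
#' @param cfg A [preprocess_config()].
#' @param seed Integer seed; identical input and seed give identical
#'   output.
#' @return Augmented `T x S x S` array in `[0, 1]`.
#' @export
augment <- function(frames, cfg = preprocess_config(), seed = 1L) {
  d <- dim(frames)
  stopifnot(length(d) == 3, d[2] == d[3])
  if (!cfg$augment) return(frames)
  S <- d[2]
  drawn <- with_seed(seed, {
    do <- stats::runif(5) < cfg$p_transform
    names(do) <- c("rotation", "gamma", "crop", "elastic", "noise")
    params <- list(
      angle = stats::runif(1, cfg$rotation_range[1], cfg$rotation_range[2]),
      gamma = stats::runif(1, cfg$gamma_range[1], cfg$gamma_range[2]),
      crop_scale = stats::runif(1, cfg$crop_scale_range[1],
                                cfg$crop_scale_range[2]),
      elastic_dy = matrix(stats::runif(S * S, -1, 1), S, S),
      elastic_dx = matrix(stats::runif(S * S, -1, 1), S, S),
      noise = array(stats::rnorm(prod(d), sd = cfg$noise_sd), dim = d))
    list(do = do, params = params)
  })
  do <- drawn$do
  params <- drawn$params
  out <- frames
  if (do["rotation"] || do["crop"] || do["elastic"]) {
    maps <- augment_maps(S, do, params, cfg)
    stack <- aperm(out, c(2, 3, 1)) # (H, W, T) for the resampler
    warped <- warp_bilinear_cpp(stack, S, S, d[1], maps$map_y, maps$map_x, 0)
    dim(warped) <- c(S, S, d[1])
    out <- aperm(warped, c(3, 1, 2))
  }
  if (do["gamma"]) out <- out^params$gamma
  if (do["noise"]) out <- out + params$noise
  clamp01(out)
}

#' Sample frames from a clip
#'
#' Training mode draws `n` frame indices uniformly without replacement
#' (with replacement only when the clip is shorter than `n`) and returns
#' them in ascending temporal order; test mode returns the full sequence
#' in order.
#'
#' @param clip A `video_clip` or a `T x H x W` array.
#' @param mode `"train"` or `"test"`.
#' @param n Number of frames to sample in train mode.
#' @param seed Integer seed for the draw.
#' @return A `T' x H x W` array of sampled frames.
#' @export
sample_frames <- function(clip, mode = c("train", "test"), n = 8L, seed = 1L) {
  mode <- match.arg(mode)
  frames <- if (inherits(clip, "video_clip")) clip$frames else clip
  T_ <- dim(frames)[1]
  if (is.null(T_) || T_ < 1) stop("empty clip")
  if (mode == "test") return(frames)
  if (n < 1) stop("n must be >= 1 in train mode")
  idx <- with_seed(seed, {
    if (T_ >= n) sort(sample.int(T_, n))
    else sort(sample.int(T_, n, replace = TRUE))
  })
  frames[idx, , , drop = FALSE]
}

#' Preprocess a clip to network input
#'
#' Convenience composition of [to_grayscale()] and [crop_resize_center()]
#' applied to a clip's frames in place.
#'
#' @param clip A `video_clip`.
#' @param cfg A [preprocess_config()].
#' @return The clip with `frames` replaced by the preprocessed
#'   `T x S x S` array.
#' @export
preprocess_clip <- function(clip, cfg = preprocess_config()) {
  stopifnot(inherits(clip, "video_clip"))
  clip$frames <- crop_resize_center(to_grayscale(clip$frames), cfg)
  clip
}
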
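# Synthetic sector-fan phantom videos.
#
# The generator emulates the geometry of B-mode cardiac ultrasound well
# enough to exercise view classification, unknown-view recognition and
# quality regression: a dark background inside a sector-fan mask (apex at
# top-centre, 75 degree aperture), bright-walled dark "chambers" laid out
# differently per view class, periodic wall motion over a cardiac cycle,
# multiplicative log-normal speckle, and graded degradations (visibility,
# centering, gain, depth) that define a known ground-truth quality score.

SECTOR_APEX <- c(x = 0.5, y = 0.05)
SECTOR_HALF_ANGLE <- 75 / 2 * pi / 180
SECTOR_DEPTH <- 0.88

#' Quality-degradation parameters for a phantom video
#'
#' The four degradation axes mirror the components of questionnaire-based
#' view-quality rating (anatomy visibility, centering in the field of
#' view, gain, imaging depth), each normalised to `[0, 1]`.
#'
#' @param visibility Structure-to-background contrast multiplier in
#'   `[0, 1]`; 1 = fully visible walls and chambers, 0 = no structure.
#' @param centering_offset Normalised displacement of the layout from the
#'   sector centre in `[0, 1]`.
#' @param gain_deviation Distance of global brightness from nominal in
#'   `[0, 1]`.
#' @param depth_error Mismatch of the layout scale to the sector in
#'   `[0, 1]`.
#' @param speckle_strength Log-standard-deviation of the multiplicative
#'   speckle (positive).
#' @return An object of class `quality_params`.
#' @export
quality_params <- function(visibility = 1, centering_offset = 0,
                           gain_deviation = 0, depth_error = 0,
                           speckle_strength = 0.3) {
  vals <- c(visibility = visibility, centering_offset = centering_offset,
            gain_deviation = gain_deviation, depth_error = depth_error)
  if (any(vals < 0 | vals > 1) || any(!is.finite(vals)))
    stop("visibility, centering_offset, gain_deviation and depth_error must lie in [0, 1]")
  if (!is.finite(speckle_strength) || speckle_strength < 0)
    stop("speckle_strength must be a non-negative real")
  structure(list(visibility = visibility,
                 centering_offset = centering_offset,
                 gain_deviation = gain_deviation,
                 depth_error = depth_error,
                 speckle_strength = speckle_strength),
            class = "quality_params")
}

#' Ground-truth quality of a phantom video
#'
#' Fixed convex combination of the degradation axes:
#' `0.4 * visibility + 0.2 * (1 - centering_offset) +
#'  0.2 * (1 - gain_deviation) + 0.2 * (1 - depth_error)`.
#' Monotone increasing in visibility and decreasing in every degradation;
#' always in `[0, 1]`.
#'
#' @param q A [quality_params()] object.
#' @return Scalar quality in `[0, 1]`.
#' @export
true_quality <- function(q) {
  stopifnot(inherits(q, "quality_params"))
  0.4 * q$visibility + 0.2 * (1 - q$centering_offset) +
    0.2 * (1 - q$gain_deviation) + 0.2 * (1 - q$depth_error)
}

# Pull a point inside the sector fan (with a small safety margin) by
# shrinking it towards the sector centroid.
project_into_sector <- function(cx, cy, margin = 0.03) {
  target <- c(0.5, 0.45)
  for (i in 1:50) {
    if (point_in_sector(cx, cy, margin)) break
    cx <- cx + 0.12 * (target[1] - cx)
    cy <- cy + 0.12 * (target[2] - cy)
  }
  c(cx, cy)
}

point_in_sector <- function(x, y, margin = 0) {
  dx <- x - SECTOR_APEX["x"]
  dy <- y - SECTOR_APEX["y"]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy) # angle from the downward axis
  unname(dy > 0 & abs(ang) <= SECTOR_HALF_ANGLE - margin &
           r <= SECTOR_DEPTH - margin & r >= 0.08)
}

#' Deterministic chamber layout for a view class
#'
#' Each class is a distinct arrangement of bright-walled elliptical
#' chambers inside the sector fan. Classes are organised so that layouts
#' of distinct classes differ either in chamber count or in the primary
#' chamber centre by at least 0.1 of the frame (a separability guarantee
#' that makes the classification task solvable). By default 10 layouts
#' are assignable as known view classes and the remaining ones are
#' reserved for the "novel category" unknown subcategory.
#'
#' @param class_id Integer in `[0, n_total)`.
#' @param seed Integer seed; only adds a sub-pixel deterministic jitter,
#'   well below the separability margin.
#' @param n_total Total number of available layouts (known + reserved).
#' @return An object of class `layout_spec` with fields `class_id`,
#'   `ellipses` (list of `center`, `axes`, `theta`, `wall_brightness`),
#'   `motion_amplitude` and `cycle_length`.
#' @export
make_view_layout <- function(class_id, seed = 1L, n_total = 12L) {
  if (length(class_id) != 1 || class_id < 0 || class_id >= n_total)
    stop("class_id must lie in [0, ", n_total, ")")
  class_id <- as.integer(class_id)
  n_ell <- 2L + class_id %/% 4L
  j <- class_id %% 4L
  px <- c(0.38, 0.62, 0.38, 0.62)[j + 1]
  py <- c(0.40, 0.40, 0.62, 0.62)[j + 1]
  jit <- with_seed(derive_seed(seed, 7001, class_id),
                   stats::runif(2 * n_ell + 2, -0.01, 0.01))
  ellipses <- vector("list", n_ell)
  ellipses[[1]] <- list(center = c(px + jit[1], py + jit[2]),
                        axes = c(0.15, 0.105),
                        theta = pi * class_id / n_total,
                        wall_brightness = 0.85)
  for (m in seq_len(n_ell - 1L)) {
    psi <- 2 * pi * (0.618 * class_id + m / n_ell)
    cx <- px + 0.14 * cos(psi) + jit[2 * m + 1]
    cy <- py + 0.14 * sin(psi) + jit[2 * m + 2]
    ctr <- project_into_sector(cx, cy)
    ellipses[[m + 1L]] <- list(center = ctr,
                               axes = c(0.085, 0.06),
                               theta = pi * (class_id / n_total + m / n_ell),
                               wall_brightness = 0.8)
  }
  structure(list(class_id = class_id,
                 ellipses = ellipses,
                 motion_amplitude = 0.03 + 0.01 * (class_id %% 2L),
                 cycle_length = 16L),
            class = "layout_spec")
}

# Separability predicate used by the generator's invariant tests: layouts
# must differ in chamber count or primary-centre position by >= 0.1.
layouts_separable <- function(a, b, min_dist = 0.1) {
  if (length(a$ellipses) != length(b$ellipses)) return(TRUE)
  ca <- a$ellipses[[1]]$center
  cb <- b$ellipses[[1]]$center
  sqrt(sum((ca - cb)^2)) >= min_dist
}

sector_mask_cache <- new.env(parent = emptyenv())

sector_mask <- function(H, W) {
  key <- paste(H, W, sep = "x")
  if (!is.null(sector_mask_cache[[key]])) return(sector_mask_cache[[key]])
  ys <- matrix((seq_len(H) - 0.5) / H, H, W)
  xs <- matrix((seq_len(W) - 0.5) / W, H, W, byrow = TRUE)
  dx <- xs - SECTOR_APEX["x"]
  dy <- ys - SECTOR_APEX["y"]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy)
  mask <- dy > 0 & abs(ang) <= SECTOR_HALF_ANGLE & r <= SECTOR_DEPTH
  out <- list(mask = mask, xs = xs, ys = ys)
  sector_mask_cache[[key]] <- out
  out
}

#' Render one phantom frame
#'
#' Draws the layout's chambers at a given cardiac phase, applies the
#' quality degradations and multiplicative log-normal speckle, masks
#' everything outside the sector fan to exactly zero, and clips to
#' `[0, 1]`. Bit-identical for identical arguments and seed.
#'
#' @param layout A [make_view_layout()] layout.
#' @param phase Cardiac phase in `[0, 1)`.
#' @param q A [quality_params()] object.
#' @param seed Integer seed for the speckle draw.
#' @param H,W Frame size in pixels (>= 64).
#' @return An `H x W` matrix of intensities in `[0, 1]`.
#' @export
render_frame <- function(layout, phase, q, seed = 1L, H = 256L, W = 256L) {
  stopifnot(inherits(layout, "layout_spec"), inherits(q, "quality_params"))
  if (H < 64 || W < 64) stop("frame size must be at least 64 x 64")
  g <- sector_mask(H, W)
  base <- 0.25
  img <- matrix(base, H, W)
  vis <- q$visibility
  scale <- 1 - 0.35 * q$depth_error
  shift <- q$centering_offset * 0.18 * c(0.93, 0.37) # fixed drift direction
  n_ell <- length(layout$ellipses)
  for (m in seq_len(n_ell)) {
    e <- layout$ellipses[[m]]
    pulse <- 1 + layout$motion_amplitude * sin(2 * pi * (phase + m / n_ell))
    bob <- 0.5 * layout$motion_amplitude * sin(2 * pi * phase + m)
    cx <- (e$center[1] - 0.5) * scale + 0.5 + shift[1]
    cy <- (e$center[2] - 0.45) * scale + 0.45 + shift[2] + bob
    a <- e$axes[1] * scale * pulse
    b <- e$axes[2] * scale * (2 - pulse)
    rb <- 1.2 * max(a, b) # ellipse bounding radius (d <= 1.3 support)
    rows <- which(abs((seq_len(H) - 0.5) / H - cy) <= rb)
    cols <- which(abs((seq_len(W) - 0.5) / W - cx) <= rb)
    if (length(rows) == 0 || length(cols) == 0) next
    dx <- g$xs[rows, cols, drop = FALSE] - cx
    dy <- g$ys[rows, cols, drop = FALSE] - cy
    u <- (dx * cos(e$theta) + dy * sin(e$theta)) / a
    v <- (-dx * sin(e$theta) + dy * cos(e$theta)) / b
    d <- u^2 + v^2
    wall <- d > 0.72 & d <= 1.3
    interior <- d <= 0.72
    sub <- img[rows, cols, drop = FALSE]
    sub[wall] <- pmax(sub[wall], base + 0.7 * vis * e$wall_brightness)
    sub[interior] <- pmin(sub[interior], base * (1 - 0.85 * vis))
    img[rows, cols] <- sub
  }
  img <- img * (1 + 0.6 * q$gain_deviation)
  if (q$speckle_strength > 0) {
    s <- q$speckle_strength
    z <- with_seed(derive_seed(seed, 3307),
                   matrix(stats::rnorm(H * W), H, W))
    img <- img * exp(s * z - s^2 / 2)
  }
  img[!g$mask] <- 0
  clamp01(img)
}

#' Generate one labelled phantom video
#'
#' @param kind Either a known class id (integer in `[0, n_known)`) or one
#'   of `"novel_category"`, `"poor_quality"`, `"multiple_views"`.
#' @param n_frames Number of frames T (>= 1; >= 2 for `multiple_views`).
#' @param q A [quality_params()] object. For `poor_quality` the
#'   visibility is forced to at most `poor_visibility_floor` so that the
#'   structures become unidentifiable; the reported `true_quality` always
#'   reflects the parameters actually rendered.
#' @param seed Integer seed; identical arguments and seed give an
#'   identical clip.
#' @param H,W Frame size in pixels.
#' @param n_known Number of known view classes configured.
#' @param n_total Total layouts (known + reserved novel).
#' @param layout_seed Seed of the layout family (class identity is shared
#'   across clips generated with the same `layout_seed`).
#' @param poor_visibility_floor Maximum visibility of a `poor_quality`
#'   clip.
#' @param frame_rate Frame rate in Hz, stored as metadata only.
#' @return An object of class `video_clip` with fields `frames`
#'   (`T x H x W` array in `[0, 1]`), `label` (known class id as integer,
#'   or the unknown subcategory), `true_quality`, `frame_rate` and
#'   bookkeeping metadata.
#' @export
generate_video <- function(kind, n_frames = 16L, q = quality_params(),
                           seed = 1L, H = 256L, W = 256L, n_known = 10L,
                           n_total = 12L, layout_seed = 1L,
                           poor_visibility_floor = 0.1, frame_rate = 30) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  is_known <- !is.character(kind)
  label <- kind
  switch_at <- NA_integer_
  if (is_known) {
    if (kind < 0 || kind >= n_known) stop("known class id out of range")
    layouts <- list(make_view_layout(kind, layout_seed, n_total))
  } else {
    kind <- match.arg(kind, unknown_labels)
    label <- kind
    if (kind == "novel_category") {
      reserved <- seq.int(n_known, n_total - 1L)
      pick <- with_seed(derive_seed(seed, 11), sample(reserved, 1L))
      layouts <- list(make_view_layout(pick, layout_seed, n_total))
    } else if (kind == "poor_quality") {
      visf <- with_seed(derive_seed(seed, 13),
                        stats::runif(1, 0, poor_visibility_floor))
      q <- quality_params(visibility = visf,
                          centering_offset = q$centering_offset,
                          gain_deviation = q$gain_deviation,
                          depth_error = q$depth_error,
                          speckle_strength = q$speckle_strength)
      pick <- with_seed(derive_seed(seed, 17), sample.int(n_known, 1L) - 1L)
      layouts <- list(make_view_layout(pick, layout_seed, n_total))
    } else { # multiple_views
      if (n_frames < 2) stop("multiple_views requires n_frames >= 2")
      if (n_known < 2) stop("multiple_views requires at least 2 known classes")
      picks <- with_seed(derive_seed(seed, 19), sample.int(n_known, 2L) - 1L)
      layouts <- lapply(picks, make_view_layout, seed = layout_seed,
                        n_total = n_total)
      lo <- max(1L, ceiling(n_frames / 4))
      hi <- min(n_frames - 1L, floor(3 * n_frames / 4))
      switch_at <- with_seed(derive_seed(seed, 23),
                             if (hi > lo) sample(seq.int(lo, hi), 1L) else lo)
    }
  }
  frames <- array(0, dim = c(n_frames, H, W))
  cyc <- layouts[[1]]$cycle_length
  for (t in seq_len(n_frames)) {
    lay <- if (!is.na(switch_at) && t > switch_at) layouts[[2]] else layouts[[1]]
    frames[t, , ] <- render_frame(lay, ((t - 1) %% cyc) / cyc, q,
                                  seed = derive_seed(seed, 29, t), H = H, W = W)
  }
  structure(list(frames = frames,
                 label = if (is_known) as.integer(kind) else label,
                 subcategory = if (is_known) NA_character_ else label,
                 true_quality = true_quality(q),
                 quality = q,
                 frame_rate = frame_rate,
                 switch_at = switch_at,
                 seed = as.integer(seed)),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_clip> %d frames of %dx%d, label: %s, quality: %.3f\n",
              d[1], d[2], d[3], as.character(x$label), x$true_quality))
  invisible(x)
}

draw_quality <- function(spread) {
  if (spread == "default")
    quality_params(visibility = stats::runif(1, 0.7, 1),
                   centering_offset = stats::runif(1, 0, 0.2),
                   gain_deviation = stats::runif(1, 0, 0.2),
                   depth_error = stats::runif(1, 0, 0.2))
  else # "wide": full quality range, for quality-regression training
    quality_params(visibility = stats::runif(1, 0.15, 1),
                   centering_offset = stats::runif(1, 0, 0.7),
                   gain_deviation = stats::runif(1, 0, 0.7),
                   depth_error = stats::runif(1, 0, 0.7))
}

#' Configuration of a synthetic dataset
#'
#' @param n_known Number of known view classes.
#' @param clips_per_class Named integer vector with entries `train`,
#'   `val`, `test`: known clips per class in each split.
#' @param unknown_fraction Named numeric vector (`train`, `val`, `test`):
#'   unknown clips as a fraction of the known clips of the split, divided
#'   equally over the three unknown subcategories. Must be 0 for `train`
#'   unless `outlier_exposure` is set.
#' @param n_frames Frames per clip.
#' @param height,width Frame size in pixels.
#' @param quality_spread `"default"` (routine acquisitions: high
#'   visibility, mild degradations) or `"wide"` (full quality range, for
#'   quality-regression training).
#' @param outlier_exposure If `TRUE`, the training split may contain
#'   unknown clips; their labels are collapsed to a single `"outlier"`
#'   class without fine-grained subcategory.
#' @param n_total Total layouts (known + reserved novel).
#' @param frame_rate Frame rate metadata in Hz.
#' @return An object of class `dataset_config`.
#' @export
dataset_config <- function(n_known = 10L,
                           clips_per_class = c(train = 50L, val = 4L, test = 8L),
                           unknown_fraction = c(train = 0, val = 0.3, test = 0.3),
                           n_frames = 16L, height = 256L, width = 256L,
                           quality_spread = c("default", "wide"),
                           outlier_exposure = FALSE,
                           n_total = 12L, frame_rate = 30) {
  quality_spread <- match.arg(quality_spread)
  clips_per_class <- unlist(clips_per_class) # accept YAML-style lists
  unknown_fraction <- unlist(unknown_fraction)
  stopifnot(all(c("train", "val", "test") %in% names(clips_per_class)),
            all(c("train", "val", "test") %in% names(unknown_fraction)))
  if (any(clips_per_class < 1)) stop("clips_per_class entries must be >= 1")
  if (unknown_fraction[["train"]] > 0 && !outlier_exposure)
    stop("unknown clips in the training split require outlier_exposure = TRUE")
  if (outlier_exposure && unknown_fraction[["train"]] == 0)
    unknown_fraction[["train"]] <- 0.1
  structure(list(n_known = as.integer(n_known),
                 clips_per_class = clips_per_class,
                 unknown_fraction = unknown_fraction,
                 n_frames = as.integer(n_frames),
                 height = as.integer(height), width = as.integer(width),
                 quality_spread = quality_spread,
                 outlier_exposure = isTRUE(outlier_exposure),
                 n_total = as.integer(n_total),
                 frame_rate = frame_rate),
            class = "dataset_config")
}

split_offsets <- c(train = 101L, val = 202L, test = 303L)

generate_split <- function(config, split, seed, transform) {
  split_seed <- seed + split_offsets[[split]]
  n_per_class <- config$clips_per_class[[split]]
  n_known_clips <- config$n_known * n_per_class
  n_unknown <- round(config$unknown_fraction[[split]] * n_known_clips)
  per_subcat <- diff(round(seq(0, n_unknown, length.out = 4)))
  clips <- vector("list", n_known_clips + n_unknown)
  idx <- 1L
  mk <- function(kind, clip_seed) {
    qp <- with_seed(derive_seed(clip_seed, 41), draw_quality(config$quality_spread))
    clip <- generate_video(kind, n_frames = config$n_frames, q = qp,
                           seed = clip_seed, H = config$height, W = config$width,
                           n_known = config$n_known, n_total = config$n_total,
                           layout_seed = 1L, frame_rate = config$frame_rate)
    clip$split <- split
    if (!is.null(transform)) clip <- transform(clip)
    clip
  }
  for (k in seq_len(config$n_known) - 1L) {
    for (r in seq_len(n_per_class)) {
      clips[[idx]] <- mk(k, derive_seed(split_seed, k, r))
      idx <- idx + 1L
    }
  }
  for (s in seq_along(unknown_labels)) {
    for (r in seq_len(per_subcat[s])) {
      clip <- mk(unknown_labels[s], derive_seed(split_seed, 900 + s, r))
      if (split == "train" && config$outlier_exposure) {
        clip$label <- "outlier"
        clip$subcategory <- NA_character_ # collapsed, no fine-grained label
      }
      clips[[idx]] <- clip
      idx <- idx + 1L
    }
  }
  clips
}

#' Generate a full train/validation/test phantom dataset
#'
#' The training split contains only known views (unless
#' `outlier_exposure` is configured, in which case unknown clips enter
#' the training split under a single collapsed `"outlier"` label);
#' validation and test contain all three unknown subcategories at the
#' configured fractions. Splits use disjoint seed streams derived as
#' `seed + fixed per-split offset`, so the whole dataset is a pure
#' function of `(config, seed)`.
#'
#' @param config A [dataset_config()].
#' @param seed Integer master seed.
#' @param transform Optional function applied to every clip right after
#'   generation (e.g. a preprocessing closure, to avoid holding raw
#'   high-resolution frames for large datasets).
#' @return An object of class `clip_dataset`: list with elements `train`,
#'   `val`, `test` (lists of `video_clip`), `config` and `seed`.
#' @export
generate_dataset <- function(config, seed = 1L, transform = NULL) {
  stopifnot(inherits(config, "dataset_config"))
  out <- list(train = generate_split(config, "train", seed, transform),
              val = generate_split(config, "val", seed, transform),
              test = generate_split(config, "test", seed, transform),
              config = config, seed = as.integer(seed))
  structure(out, class = "clip_dataset")
}

#' @export
print.clip_dataset <- function(x, ...) {
  for (s in c("train", "val", "test")) {
    labs <- vapply(x[[s]], function(cl) as.character(cl$label), character(1))
    cat(sprintf("%-5s: %d clips (%d unknown)\n", s, length(labs),
                sum(labs %in% c(unknown_labels, "outlier"))))
  }
  invisible(x)
}

## ---- dataset persistence ----------------------------------------------

#' Write a dataset to a directory
#'
#' One compressed array container (`.rds`) per clip under per-split
#' subdirectories, plus a `metadata.csv` sidecar with columns `clip_id`,
#' `label`, `subcategory`, `true_quality`, `frame_rate`, `split`, `path`.
#'
#' @param dataset A `clip_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the metadata data frame.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "clip_dataset"))
  meta <- list()
  for (split in c("train", "val", "test")) {
    sdir <- file.path(dir, split)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(dataset[[split]])) {
      clip <- dataset[[split]][[i]]
      clip_id <- sprintf("%s_%04d", split, i)
      path <- file.path(split, paste0(clip_id, ".rds"))
      saveRDS(clip, file.path(dir, path), compress = "gzip")
      meta[[length(meta) + 1L]] <-
        data.frame(clip_id = clip_id, label = as.character(clip$label),
                   subcategory = clip$subcategory %||% NA_character_,
                   true_quality = clip$true_quality,
                   frame_rate = clip$frame_rate, split = split, path = path,
                   stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `metadata.csv`.
#' @return A `clip_dataset`.
#' @export
read_dataset <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  out <- list(train = list(), val = list(), test = list(),
              config = NULL, seed = NA_integer_)
  for (i in seq_len(nrow(meta))) {
    clip <- readRDS(file.path(dir, meta$path[i]))
    out[[meta$split[i]]] <- c(out[[meta$split[i]]], list(clip))
  }
  structure(out, class = "clip_dataset")
}

#' Export a clip as a directory of PNG frames
#'
#' For visual inspection of generated phantoms.
#'
#' @param clip A `video_clip`.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
export_clip_png <- function(clip, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(dim(clip$frames)[1])
  for (t in seq_along(paths)) {
    paths[t] <- file.path(dir, sprintf("frame_%03d.png", t))
    png::writePNG(clip$frames[t, , ], paths[t])
  }
  invisible(paths)
}

#' Read a clip from a directory of PNG frames
#'
#' Frames are read in lexicographic filename order; RGB PNGs are reduced
#' to grayscale by the unweighted channel mean.
#'
#' @param dir Directory containing `.png` frames.
#' @param label Optional label to attach (known class id or unknown
#'   subcategory).
#' @param frame_rate Frame rate metadata in Hz.
#' @return A `video_clip` with frames in `[0, 1]`.
#' @export
read_clip_png <- function(dir, label = NA_integer_, frame_rate = 30) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG import")
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no .png frames found in ", dir)
  imgs <- lapply(files, function(f) {
    im <- png::readPNG(f)
    if (length(dim(im)) == 3) im <- rowMeans(im[, , 1:3, drop = FALSE], dims = 2)
    im
  })
  frames <- array(0, dim = c(length(imgs), nrow(imgs[[1]]), ncol(imgs[[1]])))
  for (t in seq_along(imgs)) frames[t, , ] <- imgs[[t]]
  structure(list(frames = frames, label = label,
                 subcategory = if (is.character(label)) label else NA_character_,
                 true_quality = NA_real_, quality = NULL,
                 frame_rate = frame_rate, switch_at = NA_integer_,
                 seed = NA_integer_),
            class = "video_clip")
}
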
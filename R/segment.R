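# Configuration-free classical nucleus segmenter: group classification,
# grayscale pre-processing, threshold/distance-transform/watershed primary
# identification, and seeded-watershed refinement with size priors.

#' Per-group segmentation preset
#'
#' Fixed parameters of the classical pipeline for one image group. All five
#' presets are decided at build time; `segment_nuclei()` takes only the
#' image, mirroring the no-human-interaction contract of a reference
#' segmenter.
#'
#' @param group group label.
#' @param foreground_transform one of `"identity"` (nuclei already bright),
#'   `"invert_luminance"`, `"stain_contrast"` (per-channel normalization
#'   then luminance inversion, for stained tissue).
#' @param smoothing_sigma Gaussian pre-smoothing sigma in pixels.
#' @param threshold_method `"otsu_global"` or `"otsu_two_class_adaptive"`
#'   (background flattening by large-scale Gaussian subtraction before a
#'   global Otsu; for low-contrast grayscale tissue).
#' @param min_diameter,max_diameter nuclear size prior in pixels; objects
#'   with equivalent diameter outside the range are removed.
#' @param declump logical; split touching nuclei via distance-transform
#'   seeds and watershed.
#' @param seed_min_distance minimum distance between declumping seeds
#'   (default `min_diameter / 2`).
#' @param fill_holes logical; fill holes in the thresholded foreground.
#' @param border_policy `"keep"` (default; the evaluation counts border
#'   nuclei as targets) or `"discard"`.
#' @return List of class `pipeline_preset`.
#' @export
pipeline_preset <- function(group,
                            foreground_transform = "identity",
                            smoothing_sigma = 1,
                            threshold_method = "otsu_global",
                            min_diameter = 5, max_diameter = 30,
                            declump = TRUE,
                            seed_min_distance = min_diameter / 2,
                            fill_holes = TRUE,
                            border_policy = "keep") {
  stopifnot(min_diameter > 0, min_diameter < max_diameter, seed_min_distance >= 1)
  foreground_transform <- match.arg(foreground_transform,
                                    c("identity", "invert_luminance", "stain_contrast"))
  threshold_method <- match.arg(threshold_method,
                                c("otsu_global", "otsu_two_class_adaptive"))
  border_policy <- match.arg(border_policy, c("keep", "discard"))
  structure(list(group = group, foreground_transform = foreground_transform,
                 smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 min_diameter = min_diameter, max_diameter = max_diameter,
                 declump = declump, seed_min_distance = seed_min_distance,
                 fill_holes = fill_holes, border_policy = border_policy),
            class = "pipeline_preset")
}

#' Built-in preset for an image group
#'
#' @param group one of [group_names()].
#' @return A [pipeline_preset()].
#' @export
group_preset <- function(group) {
  switch(group,
    small_fluorescent = pipeline_preset(group, "identity", smoothing_sigma = 1,
                                        min_diameter = 5, max_diameter = 30,
                                        seed_min_distance = 6),
    large_fluorescent = pipeline_preset(group, "identity", smoothing_sigma = 2,
                                        min_diameter = 15, max_diameter = 90,
                                        seed_min_distance = 18),
    purple_tissue = pipeline_preset(group, "stain_contrast", smoothing_sigma = 1,
                                    min_diameter = 5, max_diameter = 32,
                                    seed_min_distance = 6),
    pink_purple_tissue = pipeline_preset(group, "stain_contrast", smoothing_sigma = 1,
                                         min_diameter = 6, max_diameter = 38,
                                         seed_min_distance = 7),
    grayscale_tissue = pipeline_preset(group, "invert_luminance", smoothing_sigma = 1,
                                       threshold_method = "otsu_two_class_adaptive",
                                       min_diameter = 5, max_diameter = 30,
                                       seed_min_distance = 6),
    stopf("unknown group '%s'", group)
  )
}

luminance <- function(px) {
  if (is.matrix(px)) px else (px[, , 1] + px[, , 2] + px[, , 3]) / 3
}

#' Classify an image into one of the five visual groups
#'
#' A deterministic decision tree over the cues the five groups were defined
#' by — nucleus/background colors and object sizes: (1) color versus
#' grayscale by inter-channel variance; (2) fluorescent versus tissue by
#' background-luminance polarity (dark background means fluorescent);
#' (3) fluorescent split small/large by the median rough-object diameter
#' against a fixed 24-pixel cut; (4) bright-background images split into
#' grayscale tissue (colorless), purple tissue (near-white background) or
#' pink-and-purple tissue (saturated pink background) by background
#' saturation. A degenerate constant image falls back to small fluorescent
#' at the lowest confidence.
#'
#' @param img an [image_record()].
#' @return List of class `group_call`: `group`, `confidence` (`"high"`,
#'   `"medium"` or `"low"`) and `features` (is_color, background_luminance,
#'   background_saturation, median_diameter).
#' @export
classify_group <- function(img) {
  stopifnot(inherits(img, "image_record"))
  px <- img$pixels
  lum <- luminance(px)
  is_color <- FALSE
  if (!is.matrix(px)) {
    chvar <- mean((px[, , 1] - lum)^2 + (px[, , 2] - lum)^2 + (px[, , 3] - lum)^2)
    is_color <- chvar > 1e-4
  }
  rng <- max(lum) - min(lum)
  bg_lum <- stats::median(lum)
  if (rng < 0.02) {
    return(structure(list(group = "small_fluorescent", confidence = "low",
                          features = c(is_color = is_color,
                                       background_luminance = bg_lum,
                                       background_saturation = 0,
                                       median_diameter = NA)),
                     class = "group_call"))
  }
  feats <- c(is_color = is_color, background_luminance = bg_lum,
             background_saturation = 0, median_diameter = NA)
  if (bg_lum < 0.5) {
    d <- rough_median_diameter(lum, dark_background = TRUE)
    feats["median_diameter"] <- d
    group <- if (!is.na(d) && d > 24) "large_fluorescent" else "small_fluorescent"
    conf <- if (is.na(d)) "low" else "high"
  } else if (!is_color) {
    group <- "grayscale_tissue"; conf <- "high"
  } else {
    bright <- lum >= stats::quantile(lum, 0.6)
    mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
    mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
    sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
    bg_sat <- stats::median(sat[bright])
    feats["background_saturation"] <- bg_sat
    group <- if (bg_sat > 0.08) "pink_purple_tissue" else "purple_tissue"
    conf <- "high"
  }
  structure(list(group = group, confidence = conf, features = feats),
            class = "group_call")
}

# Median equivalent diameter of rough Otsu objects on a luminance image.
rough_median_diameter <- function(lum, dark_background = TRUE) {
  g <- if (dark_background) lum else 1 - lum
  th <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  lab <- EBImage::bwlabel(g > th)
  areas <- tabulate(as.integer(EBImage::imageData(lab)))
  areas <- areas[areas >= 9]
  if (length(areas) == 0L) return(NA_real_)
  stats::median(equivalent_diameter(areas))
}

#' Transform an image to a nuclei-bright grayscale matrix
#'
#' Step 1 of the pipeline: whatever the input polarity or stain, the output
#' is a smoothed grayscale matrix in `[0, 1]` with nuclei brighter than the
#' background. `identity` keeps the luminance; `invert_luminance` flips it;
#' `stain_contrast` normalizes each channel to full range before inverting
#' the luminance, boosting stain contrast without an explicit stain matrix.
#'
#' @param img an [image_record()].
#' @param preset a [pipeline_preset()].
#' @return Numeric matrix in `[0, 1]`.
#' @export
to_foreground_grayscale <- function(img, preset) {
  stopifnot(inherits(img, "image_record"), inherits(preset, "pipeline_preset"))
  px <- img$pixels
  g <- switch(preset$foreground_transform,
    identity = luminance(px),
    invert_luminance = 1 - luminance(px),
    stain_contrast = {
      if (is.matrix(px)) 1 - normalize01(px)
      else {
        ch <- lapply(1:3, function(i) normalize01(px[, , i]))
        1 - (ch[[1]] + ch[[2]] + ch[[3]]) / 3
      }
    })
  if (preset$smoothing_sigma > 0) {
    g <- EBImage::imageData(EBImage::gblur(EBImage::Image(g),
                                           sigma = preset$smoothing_sigma))
  }
  normalize01(g)
}

# Rescale to [0,1]; a constant matrix is returned unchanged (clipped).
normalize01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < 1e-12) return(pmin(pmax(x, 0), 1))
  (x - r[1]) / (r[2] - r[1])
}

threshold_foreground <- function(gray, preset) {
  if (max(gray) - min(gray) < 1e-12) return(matrix(FALSE, nrow(gray), ncol(gray)))
  g <- gray
  if (preset$threshold_method == "otsu_two_class_adaptive") {
    bgs <- EBImage::imageData(EBImage::gblur(EBImage::Image(gray),
                                             sigma = max(4 * preset$max_diameter / 3, 8)))
    g <- normalize01(gray - bgs)
  }
  th <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  g > th
}

#' Identify primary objects by threshold, distance transform and watershed
#'
#' Step 2: the grayscale image is thresholded (global Otsu, or the adaptive
#' variant), holes optionally filled, and — when declumping is on — touching
#' nuclei are split by a watershed over the Euclidean distance transform:
#' seeds are local maxima of the distance map within a neighborhood set by
#' `seed_min_distance`, maxima separated by a saddle shallower than 0.5
#' distance-map pixels count as one seed, and foreground pixels flood to the
#' seeds. Objects with equivalent diameter outside
#' `[min_diameter, max_diameter]` are removed and labels canonicalized.
#'
#' @param gray nuclei-bright grayscale matrix in `[0, 1]`.
#' @param preset a [pipeline_preset()].
#' @param image_id identifier for the result.
#' @return A [label_mask()] (possibly with zero objects).
#' @export
identify_primary <- function(gray, preset, image_id = "image") {
  stopifnot(is.matrix(gray))
  fgm <- threshold_foreground(gray, preset)
  if (!any(fgm)) return(label_mask(matrix(0L, nrow(gray), ncol(gray)), image_id))
  fg <- EBImage::Image(fgm * 1)
  if (preset$fill_holes) fg <- EBImage::fillHull(fg)
  if (preset$declump) {
    lab <- declump_watershed(fg, preset$seed_min_distance)
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(fg))
  }
  if (preset$border_policy == "discard") lab <- drop_border_objects(lab)
  lab <- filter_by_diameter(lab, preset$min_diameter, preset$max_diameter)
  label_mask(lab, image_id = image_id)
}

# Watershed over the Euclidean distance transform. Seeds are the local
# maxima of the distance map within a neighborhood tied to the seed-distance
# prior; maxima whose separating saddle is shallower than DECLUMP_TOLERANCE
# (in distance-map pixels) are treated as one seed, so boundary wobble on a
# single nucleus does not split it while a genuine neck between touching
# nuclei does.
DECLUMP_TOLERANCE <- 0.5

declump_watershed <- function(fg, seed_min_distance) {
  dist <- EBImage::distmap(fg)
  out <- EBImage::imageData(
    EBImage::watershed(dist, tolerance = DECLUMP_TOLERANCE,
                       ext = max(1L, floor(seed_min_distance / 2))))
  matrix(as.integer(round(out)), nrow(out), ncol(out))
}

drop_border_objects <- function(lab) {
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  lab[lab %in% border[border > 0]] <- 0L
  lab
}

filter_by_diameter <- function(lab, min_d, max_d) {
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  n <- max(lab, 0L)
  if (n == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  bad <- which(equivalent_diameter(areas) < min_d | equivalent_diameter(areas) > max_d)
  if (length(bad) > 0L) lab[lab %in% bad] <- 0L
  canonicalize_labels(lab)
}

#' Refine a segmentation by seeded watershed with size priors
#'
#' Step 3: the grayscale image is re-thresholded, the foreground is the
#' union of that threshold mask and the primary objects, and each foreground
#' pixel is reassigned by seeded region growing (seeds = primary objects)
#' over the intensity landscape. Every seed maps to at most one output
#' object, so the object count is preserved or reduced (size-prior filtering
#' may remove objects, never split them), and boundaries move only within
#' the foreground.
#'
#' @param gray nuclei-bright grayscale matrix in `[0, 1]`.
#' @param primary [label_mask()] from [identify_primary()].
#' @param preset a [pipeline_preset()].
#' @return A [label_mask()].
#' @export
refine_secondary <- function(gray, primary, preset) {
  stopifnot(is.matrix(gray), inherits(primary, "label_mask"))
  if (!identical(dim(gray), dim(primary$labels))) stopf("gray and primary shapes differ")
  if (primary$n_objects == 0L) return(primary)
  fgm <- threshold_foreground(gray, preset) | primary$labels > 0L
  out <- EBImage::imageData(
    EBImage::propagate(x = 1 - gray, seeds = EBImage::Image(primary$labels),
                       mask = EBImage::Image(fgm * 1), lambda = 0.05))
  lab <- filter_by_diameter(out, preset$min_diameter, preset$max_diameter)
  label_mask(lab, image_id = primary$image_id)
}

#' Segment nuclei in one image with no manual configuration
#'
#' The full three-step reference pipeline: classify the image group (unless
#' a preset is supplied), transform to a nuclei-bright grayscale, identify
#' primary objects by threshold/distance-transform/watershed, then refine by
#' seeded watershed under the group's nuclear size prior. Fully
#' deterministic; takes no per-image parameters.
#'
#' @param img an [image_record()].
#' @param preset optional [pipeline_preset()] override; default is the
#'   preset of the automatically classified group.
#' @return List with `mask` ([label_mask()]), `group_call` and `preset`.
#' @examples
#' gen <- generate_image(synthetic_spec("small_fluorescent", n_objects = 5, seed = 3))
#' res <- segment_nuclei(gen$image)
#' res$mask$n_objects
#' @export
segment_nuclei <- function(img, preset = NULL) {
  stopifnot(inherits(img, "image_record"))
  call <- classify_group(img)
  if (is.null(preset)) preset <- group_preset(call$group)
  gray <- to_foreground_grayscale(img, preset)
  primary <- identify_primary(gray, preset, image_id = img$image_id)
  mask <- refine_secondary(gray, primary, preset)
  list(mask = mask, group_call = call, preset = preset)
}
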
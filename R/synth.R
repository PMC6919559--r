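# Seeded synthetic microscopy images with ground-truth label masks.

#' Names of the five visual image groups
#'
#' The dataset's images fall into five visually similar groups defined by
#' nucleus/background colors and object sizes: small and large fluorescent
#' (bright nuclei on a dark background), purple tissue (purple nuclei on a
#' white background), pink-and-purple tissue (purple nuclei on a pink
#' background) and grayscale tissue (dark nuclei on a bright colorless
#' background).
#'
#' @return Character vector of the five group names.
#' @export
group_names <- function() {
  c("small_fluorescent", "large_fluorescent", "purple_tissue",
    "pink_purple_tissue", "grayscale_tissue")
}

#' Default group mixture proportions
#'
#' The training data were heavily imbalanced: the largest group (small
#' fluorescent) held 80% of the examples and the smallest 0.6%. The extremes
#' are fixed at those values; the three middle proportions are package
#' defaults.
#'
#' @return Named numeric vector over [group_names()] summing to 1.
#' @export
default_group_mixture <- function() {
  c(small_fluorescent = 0.800, large_fluorescent = 0.006,
    purple_tissue = 0.090, pink_purple_tissue = 0.064,
    grayscale_tissue = 0.040)
}

# Fixed reference colors for the tissue stain model (linear RGB in [0,1]).
# A nucleus pixel multiplies the background color by the nucleus tint.
stain_colors <- function(group) {
  switch(group,
    purple_tissue = list(background = c(0.97, 0.96, 0.97),
                         tint = c(0.45, 0.28, 0.68)),
    pink_purple_tissue = list(background = c(0.95, 0.76, 0.84),
                              tint = c(0.48, 0.30, 0.70)),
    grayscale_tissue = list(background = c(0.85, 0.85, 0.85),
                            tint = c(0.38, 0.38, 0.38)),
    NULL
  )
}

#' Synthetic image specification
#'
#' Parameters for generating one synthetic microscopy image of a given
#' visual group. Defaults differ per group and emulate the qualitative
#' appearance of that group (sizes in pixels): small fluorescent nuclei have
#' mean diameter 12, large fluorescent 40; tissue nuclei are 12-16 px,
#' irregular and frequently touching (`touching_prob` 0.4).
#'
#' @param group one of [group_names()].
#' @param height,width image size in pixels.
#' @param n_objects number of nuclei to place (default per group).
#' @param diameter_mean,diameter_sd nucleus equivalent-diameter distribution
#'   in pixels; diameters are drawn from a normal truncated at 2.5 sd.
#' @param irregularity radial-perturbation amplitude in `[0, 1]` (0 =
#'   smooth ellipse).
#' @param touching_prob probability that a nucleus is placed adjacent to an
#'   existing one; with probability `1 - touching_prob` a gap of at least 2
#'   pixels to all other nuclei is enforced.
#' @param noise_sd additive Gaussian noise sigma on the `[0, 1]` intensity
#'   scale.
#' @param shot_noise logical; add intensity-scaled (Poisson-like) noise.
#' @param illumination_gradient amplitude in `[0, 1]` of a linear
#'   illumination ramp across the field.
#' @param seed integer RNG seed; the generated image and mask are pure
#'   functions of the spec including this seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(group = "small_fluorescent",
                           height = 256, width = 256,
                           n_objects = NULL,
                           diameter_mean = NULL, diameter_sd = NULL,
                           irregularity = NULL, touching_prob = NULL,
                           noise_sd = NULL, shot_noise = NULL,
                           illumination_gradient = NULL,
                           seed = 1L) {
  if (!group %in% group_names()) stopf("unknown group '%s'", group)
  def <- switch(group,
    small_fluorescent = list(n_objects = 30L, diameter_mean = 12, diameter_sd = 2,
                             irregularity = 0.15, touching_prob = 0.10,
                             noise_sd = 0.02, shot_noise = TRUE,
                             illumination_gradient = 0.15),
    large_fluorescent = list(n_objects = 8L, diameter_mean = 40, diameter_sd = 6,
                             irregularity = 0.20, touching_prob = 0.10,
                             noise_sd = 0.02, shot_noise = TRUE,
                             illumination_gradient = 0.15),
    purple_tissue = list(n_objects = 45L, diameter_mean = 13, diameter_sd = 2.5,
                         irregularity = 0.30, touching_prob = 0.40,
                         noise_sd = 0.03, shot_noise = FALSE,
                         illumination_gradient = 0.10),
    pink_purple_tissue = list(n_objects = 35L, diameter_mean = 16, diameter_sd = 3,
                              irregularity = 0.30, touching_prob = 0.40,
                              noise_sd = 0.03, shot_noise = FALSE,
                              illumination_gradient = 0.10),
    grayscale_tissue = list(n_objects = 35L, diameter_mean = 12, diameter_sd = 2.5,
                            irregularity = 0.25, touching_prob = 0.40,
                            noise_sd = 0.03, shot_noise = FALSE,
                            illumination_gradient = 0.10)
  )
  spec <- list(
    group = group, height = as.integer(height), width = as.integer(width),
    n_objects = as.integer(n_objects %||% def$n_objects),
    diameter_mean = diameter_mean %||% def$diameter_mean,
    diameter_sd = diameter_sd %||% def$diameter_sd,
    irregularity = irregularity %||% def$irregularity,
    touching_prob = touching_prob %||% def$touching_prob,
    noise_sd = noise_sd %||% def$noise_sd,
    shot_noise = shot_noise %||% def$shot_noise,
    illumination_gradient = illumination_gradient %||% def$illumination_gradient,
    seed = as.integer(seed)
  )
  stopifnot(spec$n_objects >= 0L, spec$diameter_mean > 2,
            spec$diameter_sd >= 0, spec$height > 0L, spec$width > 0L)
  for (f in c("irregularity", "touching_prob", "noise_sd", "illumination_gradient")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) stopf("%s must be in [0, 1]", f)
  }
  structure(spec, class = "synthetic_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rasterize one radially perturbed ellipse; returns linear pixel indices
# (column-major) inside the full image, or NULL if it falls off the grid.
rasterize_nucleus <- function(cy, cx, diameter, aspect, angle, irregularity,
                              height, width) {
  a <- diameter / 2
  b <- a * aspect
  # low-order harmonic boundary perturbation, total amplitude <= irregularity
  nh <- 3L
  amp <- runif(nh); amp <- amp / max(sum(amp), 1e-9) * irregularity
  ph <- runif(nh, 0, 2 * pi)
  rmax <- a * (1 + irregularity) + 1
  r0 <- max(1L, floor(cy - rmax)); r1 <- min(height, ceiling(cy + rmax))
  c0 <- max(1L, floor(cx - rmax)); c1 <- min(width, ceiling(cx + rmax))
  if (r0 > r1 || c0 > c1) return(NULL)
  yy <- r0:r1; xx <- c0:c1
  dy <- matrix(yy - cy, length(yy), length(xx))
  dx <- matrix(xx - cx, length(yy), length(xx), byrow = TRUE)
  # rotate into the ellipse frame
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  rad <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  re <- (a * b) / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  mod <- 1
  for (j in seq_len(nh)) mod <- mod + amp[j] * cos((j + 1) * theta + ph[j])
  inside <- rad <= re * pmax(mod, 0.2)
  if (!any(inside)) return(NULL)
  ri <- row(inside)[inside] + r0 - 1L
  ci <- col(inside)[inside] + c0 - 1L
  (ci - 1L) * height + ri
}

# Chebyshev-dilate a set of linear pixel indices by `by` pixels, clipped.
dilate_indices <- function(idx, height, width, by = 2L) {
  ri <- ((idx - 1L) %% height) + 1L
  ci <- ((idx - 1L) %/% height) + 1L
  off <- expand.grid(dr = -by:by, dc = -by:by)
  rr <- outer(ri, off$dr, `+`); cc <- outer(ci, off$dc, `+`)
  ok <- rr >= 1L & rr <= height & cc >= 1L & cc <= width
  unique((cc[ok] - 1L) * height + rr[ok])
}

#' Generate one synthetic image with its ground-truth mask
#'
#' Nuclei are radially perturbed ellipses placed sequentially; a later
#' placement is carved to disjointness against earlier ones (touching is
#' allowed only for placements drawn as "touching", otherwise a 2-pixel gap
#' is enforced). Fluorescent groups render bright nuclei on a dark
#' background in one channel; tissue groups render stained nuclei on a
#' bright background in 3 channels by multiplying a fixed background color
#' with a nucleus tint. The returned mask is exactly the set of rendered
#' nucleus supports before noise is added, and the whole output is a pure
#' function of the spec (same seed, bit-identical result).
#'
#' @param spec a [synthetic_spec()].
#' @param image_id identifier for the outputs.
#' @return List with elements `image` ([image_record()]) and `mask`
#'   ([label_mask()] with exactly `spec$n_objects` objects).
#' @export
generate_image <- function(spec, image_id = sprintf("%s_seed%d", spec$group, spec$seed)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_image_impl(spec, image_id))
}

generate_image_impl <- function(spec, image_id) {
  h <- spec$height; w <- spec$width
  labels <- matrix(0L, h, w)
  budget <- 200L
  for (k in seq_len(spec$n_objects)) {
    placed <- FALSE
    for (att in seq_len(budget)) {
      d0 <- spec$diameter_mean
      d <- d0 + pmin(pmax(rnorm(1, 0, spec$diameter_sd), -2.5 * spec$diameter_sd),
                     2.5 * spec$diameter_sd)
      d <- max(d, 3)
      touching <- k > 1L && runif(1) < spec$touching_prob
      if (touching) {
        # adjacent placement: center one radius-sum away from the anchor's
        # centroid (slight overlap, carved to disjointness below)
        anchor_id <- sample.int(k - 1L, 1L)
        aidx <- which(labels == anchor_id)
        if (length(aidx) == 0L) next
        ari <- ((aidx - 1L) %% h) + 1L
        aci <- ((aidx - 1L) %/% h) + 1L
        ay <- mean(ari); ax <- mean(aci)
        dir <- runif(1, 0, 2 * pi)
        # anchor boundary extent in the placement direction (the centroid
        # distance alone under-estimates it for elongated shapes)
        pang <- atan2(aci - ax, ari - ay)
        dang <- abs(((pang - dir + pi) %% (2 * pi)) - pi)
        sect <- dang < pi / 6
        r_anchor <- if (any(sect)) {
          max(sqrt((ari[sect] - ay)^2 + (aci[sect] - ax)^2))
        } else sqrt(length(aidx) / pi)
        gap <- (r_anchor + d / 2) * runif(1, 0.92, 1.02)
        cy <- ay + cos(dir) * gap
        cx <- ax + sin(dir) * gap
      } else {
        m <- d / 2 + 1
        if (h - m <= m || w - m <= m) { cy <- h / 2; cx <- w / 2 }
        else { cy <- runif(1, m, h - m); cx <- runif(1, m, w - m) }
      }
      idx <- rasterize_nucleus(cy, cx, d, runif(1, 0.7, 1), runif(1, 0, pi),
                               spec$irregularity, h, w)
      if (is.null(idx)) next
      full <- length(idx)
      idx <- idx[labels[idx] == 0L]                 # carve to disjointness
      if (length(idx) < max(4L, 0.6 * full)) next   # too much carved away
      if (!touching) {
        halo <- dilate_indices(idx, h, w, by = 2L)
        if (any(labels[halo] > 0L)) next            # enforce separation gap
      }
      labels[idx] <- k
      placed <- TRUE
      break
    }
    if (!placed) {
      stopf(paste0("could not place object %d of %d after %d attempts: ",
                   "grid %dx%d too crowded for diameter_mean %.1f"),
            k, spec$n_objects, budget, h, w, spec$diameter_mean)
    }
  }
  fg <- labels > 0L

  if (spec$group %in% c("small_fluorescent", "large_fluorescent")) {
    img <- matrix(0.06, h, w)
    if (spec$n_objects > 0L) {
      bright <- runif(spec$n_objects, 0.60, 0.95)
      img[fg] <- bright[labels[fg]]
    }
    img <- apply_illumination(img, spec$illumination_gradient)
    img <- add_noise(img, spec)
  } else {
    col <- stain_colors(spec$group)
    tint_jit <- if (spec$n_objects > 0L) runif(spec$n_objects, 0.85, 1.1) else numeric(0)
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(col$background[ch], h, w)
      if (spec$n_objects > 0L) {
        tint <- pmin(col$tint[ch] * tint_jit[labels[fg]], 1)
        plane[fg] <- plane[fg] * tint
      }
      img[, , ch] <- plane
    }
    grad <- illumination_field(h, w, spec$illumination_gradient)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * grad
    if (spec$group == "grayscale_tissue") {
      # a grayscale camera: one noise realization shared by all channels
      plane <- add_noise(img[, , 1], spec)
      for (ch in 1:3) img[, , ch] <- plane
    } else {
      img <- add_noise(img, spec)
    }
  }
  list(image = image_record(img, image_id = image_id, group = spec$group),
       mask = label_mask(labels, image_id = image_id))
}

illumination_field <- function(h, w, amplitude) {
  if (amplitude <= 0) return(matrix(1, h, w))
  dir <- runif(1, 0, 2 * pi)
  ramp <- outer(seq(0, 1, length.out = h) * cos(dir),
                rep(1, w)) + outer(rep(1, h), seq(0, 1, length.out = w) * sin(dir))
  ramp <- (ramp - min(ramp)) / max(max(ramp) - min(ramp), 1e-12)
  1 - amplitude / 2 + amplitude * ramp / 2   # in [1 - a/2, 1]
}

apply_illumination <- function(img, amplitude) {
  img * illumination_field(nrow(img), ncol(img), amplitude)
}

add_noise <- function(img, spec) {
  if (spec$noise_sd > 0) {
    sd_field <- spec$noise_sd * if (spec$shot_noise) (0.5 + sqrt(pmax(img, 0))) else 1
    img <- img + rnorm(length(img), 0, 1) * sd_field
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Generate a mixed-group dataset on disk
#'
#' Per-group image counts are the largest-remainder rounding of
#' `proportions * n_images` (ties broken by group name order); per-image
#' seeds are derived deterministically from the master seed, so the same
#' master seed yields byte-identical files. Writes `<id>.png` images,
#' `<id>_mask.png` 16-bit label masks, a `groups.csv` (columns `image_id`,
#' `group`) and a `manifest.json` recording every spec.
#'
#' @param n_images total number of images (>= 1).
#' @param proportions named vector of group fractions summing to 1; default
#'   [default_group_mixture()].
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   everything in memory only.
#' @param seed master seed.
#' @param base_specs optional named list of [synthetic_spec()]s overriding
#'   the per-group defaults (the spec's own seed field is ignored).
#' @return List of class `dataset_index` with `entries` (data frame:
#'   `image_id`, `group`, `image_path`, `mask_path`, `seed`) and `data`
#'   (list of `list(image, mask)` per entry).
#' @export
generate_dataset <- function(n_images, proportions = default_group_mixture(),
                             out_dir = NULL, seed = 1L, base_specs = NULL) {
  stopifnot(n_images >= 1)
  if (abs(sum(proportions) - 1) > 1e-9 || any(proportions < 0)) {
    stopf("proportions must be non-negative and sum to 1")
  }
  counts <- largest_remainder(proportions, n_images)
  groups <- rep(names(counts), counts)
  entries <- NULL
  data <- vector("list", length(groups))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    base <- if (!is.null(base_specs) && !is.null(base_specs[[g]])) {
      base_specs[[g]]
    } else synthetic_spec(group = g)
    base$seed <- derive_seed(seed, i)
    id <- sprintf("synth_%03d_%s", i, g)
    gen <- generate_image(base, image_id = id)
    data[[i]] <- gen
    specs[[i]] <- unclass(base)
    img_path <- mask_path <- NA_character_
    if (!is.null(out_dir)) {
      img_path <- file.path(out_dir, paste0(id, ".png"))
      mask_path <- file.path(out_dir, paste0(id, "_mask.png"))
      write_image(gen$image, img_path)
      write_label_mask(gen$mask, mask_path)
    }
    entries <- rbind(entries, data.frame(
      image_id = id, group = g, image_path = img_path,
      mask_path = mask_path, seed = base$seed))
  }
  if (!is.null(out_dir)) {
    utils::write.csv(entries[, c("image_id", "group")],
                     file.path(out_dir, "groups.csv"), row.names = FALSE)
    jsonlite::write_json(specs, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(entries = entries, data = data), class = "dataset_index")
}

# Largest-remainder apportionment of n among named proportions;
# remainder ties broken by name order.
largest_remainder <- function(proportions, n) {
  p <- proportions[order(names(proportions))]
  exact <- p * n
  base <- floor(exact)
  left <- as.integer(round(n - sum(base)))
  if (left > 0L) {
    ord <- order(-(exact - base), names(p))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(p)
  counts
}

#' Perturb an annotation to emulate inter-observer boundary noise
#'
#' Each object's boundary is displaced by a smooth random radial offset of
#' amplitude at most `boundary_jitter` pixels (a low-order harmonic field of
#' the polar angle around the object centroid, applied to the object's
#' signed Euclidean distance field), and each object is independently
#' dropped with probability `drop_prob`. Disjointness is preserved: a pixel
#' claimed by several jittered objects stays with the lowest original label.
#'
#' @param mask canonical [label_mask()].
#' @param boundary_jitter maximum boundary displacement in pixels (>= 0).
#' @param drop_prob per-object drop probability in `[0, 1]`.
#' @param seed RNG seed; output is deterministic given mask and seed.
#' @return A [label_mask()].
#' @export
perturb_annotation <- function(mask, boundary_jitter = 1, drop_prob = 0, seed = 1L) {
  stopifnot(inherits(mask, "label_mask"), boundary_jitter >= 0,
            drop_prob >= 0, drop_prob <= 1)
  with_seed(seed, perturb_annotation_impl(mask, boundary_jitter, drop_prob))
}

perturb_annotation_impl <- function(mask, jitter, drop_prob) {
  h <- nrow(mask$labels); w <- ncol(mask$labels)
  out <- matrix(0L, h, w)
  keep <- runif(max(mask$n_objects, 0L)) >= drop_prob
  pad <- ceiling(jitter) + 1L
  for (k in seq_len(mask$n_objects)) {
    if (!keep[k]) next
    idx <- which(mask$labels == k)
    if (jitter == 0) { sel <- idx[out[idx] == 0L]; out[sel] <- k; next }
    ri <- ((idx - 1L) %% h) + 1L
    ci <- ((idx - 1L) %/% h) + 1L
    r0 <- max(1L, min(ri) - pad); r1 <- min(h, max(ri) + pad)
    c0 <- max(1L, min(ci) - pad); c1 <- min(w, max(ci) + pad)
    win <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    win[cbind(ri - r0 + 1L, ci - c0 + 1L)] <- 1
    din <- EBImage::imageData(EBImage::distmap(win))        # >0 inside
    dout <- EBImage::imageData(EBImage::distmap(1 - win))   # >0 outside
    signed <- dout - din                                    # <=0 inside, >0 outside
    cy <- mean(ri); cx <- mean(ci)
    th <- atan2(col(win) + c0 - 1 - cx, row(win) + r0 - 1 - cy)
    nh <- 3L
    amp <- runif(nh); amp <- amp / max(sum(amp), 1e-9) * jitter
    ph <- runif(nh, 0, 2 * pi)
    off <- matrix(0, nrow(win), ncol(win))
    for (j in seq_len(nh)) off <- off + amp[j] * cos(j * th + ph[j])
    newwin <- signed <= off
    wi <- which(newwin)
    gr <- ((wi - 1L) %% nrow(win)) + r0
    gc <- ((wi - 1L) %/% nrow(win)) + c0
    gi <- (gc - 1L) * h + gr
    gi <- gi[out[gi] == 0L]    # first-wins keeps disjointness
    if (length(gi) > 0L) out[gi] <- k
  }
  label_mask(out, image_id = mask$image_id)
}
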
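# Agreement between two segmentations of the same image (annotator vs
# annotator, or model vs annotator).

#' Object-level agreement between two segmentations
#'
#' Objects of `a` and `b` are matched one-to-one with the greedy IoU matcher
#' at threshold 0 (any strictly positive overlap qualifies), giving the
#' per-object IoU distribution of the matched pairs; `f1_at_07` re-matches
#' at the fixed 0.7 IoU threshold treating `a` as the target. The matched
#' IoU multiset is symmetric in `a` and `b`, so `median_iou` does not depend
#' on the argument order. When no objects match, `median_iou` is 1 if both
#' masks are empty (nothing to disagree about) and 0 otherwise.
#'
#' @param a,b [label_mask()]s of one shape.
#' @param pair_label label for the comparison (e.g. "annot1 vs annot2").
#' @return List of class `agreement_report`: `pair_label`, `image_id`,
#'   `per_object_ious`, `median_iou`, `f1_at_07`, `n_matched`, `n_only_a`,
#'   `n_only_b`.
#' @export
pairwise_agreement <- function(a, b, pair_label = "a vs b") {
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  m <- iou_matrix(a, b)
  ov <- match_at_threshold_zero(m)
  ious <- ov$pairs$iou
  median_iou <- if (length(ious) > 0L) stats::median(ious)
                else if (a$n_objects == 0L && b$n_objects == 0L) 1 else 0
  m07 <- match_at_threshold(m, 0.7)
  f1 <- precision_recall_f1(m07)[["f1"]]
  structure(list(
    pair_label = pair_label, image_id = a$image_id,
    per_object_ious = ious, median_iou = median_iou, f1_at_07 = f1,
    n_matched = nrow(ov$pairs),
    n_only_a = a$n_objects - nrow(ov$pairs),
    n_only_b = b$n_objects - nrow(ov$pairs)
  ), class = "agreement_report")
}

# Matching over all pairs with IoU > 0 (threshold 0 is outside the (0,1)
# contract of match_at_threshold, hence this sibling); same matcher.
match_at_threshold_zero <- function(m) {
  list(pairs = matched_pairs(m$values, m$values > 0))
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement '%s' on '%s': median IoU %.3f, F1@0.7 %.3f, %d matched (+%d/+%d unmatched)>\n",
              x$pair_label, x$image_id, x$median_iou, x$f1_at_07,
              x$n_matched, x$n_only_a, x$n_only_b))
  invisible(x)
}

#' Agreement table across several mask collections
#'
#' Compares every unordered pair of named collections on their shared image
#' ids, one [pairwise_agreement()] per pair per image, plus a pooled summary
#' per pair: the pooled median is taken over the concatenated per-object IoU
#' list (object-weighted, not a mean of per-image medians) and the pooled F1
#' at 0.7 IoU is recomputed from object counts pooled over images.
#'
#' @param masksets named list (>= 2 entries); each entry a named list of
#'   [label_mask()]s keyed by image id.
#' @return List with `per_image` (list of `agreement_report`s) and `pooled`
#'   (data frame: `pair`, `n_images`, `n_objects`, `pooled_median_iou`,
#'   `pooled_f1_at_07`).
#' @export
agreement_table <- function(masksets) {
  if (length(masksets) < 2L || is.null(names(masksets))) {
    stopf("masksets must be a named list with at least two collections")
  }
  ids <- Reduce(intersect, lapply(masksets, names))
  if (length(ids) == 0L) stopf("collections share no image ids")
  nm <- names(masksets)
  per_image <- list()
  pooled <- NULL
  for (i in seq_len(length(nm) - 1L)) for (j in (i + 1L):length(nm)) {
    pair <- sprintf("%s vs %s", nm[i], nm[j])
    ious <- numeric(0); tp <- fp <- fn <- 0L; n_img <- 0L
    for (id in ids) {
      rep <- pairwise_agreement(masksets[[i]][[id]], masksets[[j]][[id]], pair)
      per_image[[length(per_image) + 1L]] <- rep
      ious <- c(ious, rep$per_object_ious)
      m07 <- match_at_threshold(iou_matrix(masksets[[i]][[id]], masksets[[j]][[id]]), 0.7)
      tp <- tp + m07$tp; fp <- fp + m07$fp; fn <- fn + m07$fn
      n_img <- n_img + 1L
    }
    f1 <- precision_recall_f1(tp, fp, fn)[["f1"]]
    pooled <- rbind(pooled, data.frame(
      pair = pair, n_images = n_img, n_objects = length(ious),
      pooled_median_iou = if (length(ious) > 0L) stats::median(ious)
                          else if (tp + fp + fn == 0L) 1 else 0,
      pooled_f1_at_07 = f1))
  }
  list(per_image = per_image, pooled = pooled)
}

#' Flatten agreement reports to a data frame
#'
#' @param reports list of `agreement_report`s (e.g.
#'   `agreement_table(...)$per_image`).
#' @return Data frame with columns `pair`, `image_id`, `median_iou`,
#'   `f1_at_0.7`, `n_matched`, `n_only_a`, `n_only_b`.
#' @export
agreement_data_frame <- function(reports) {
  do.call(rbind, lapply(reports, function(r) data.frame(
    pair = r$pair_label, image_id = r$image_id, median_iou = r$median_iou,
    `f1_at_0.7` = r$f1_at_07, n_matched = r$n_matched,
    n_only_a = r$n_only_a, n_only_b = r$n_only_b, check.names = FALSE)))
}
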
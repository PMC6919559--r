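# Object matching by IoU and all derived evaluation metrics.

#' Default IoU threshold grid
#'
#' The competition's threshold set T = {0.10, 0.15, ..., 0.95} (step 0.05,
#' 18 values), generated from integer hundredths so the grid carries no
#' floating-point drift.
#'
#' @return Numeric vector of 18 strictly increasing thresholds.
#' @export
default_thresholds <- function() seq.int(10L, 95L, by = 5L) / 100

#' Parse a threshold specification string
#'
#' `"lo:hi:step"` with values in `[0, 1]`, parsed in integer hundredths
#' (e.g. `"0.10:0.95:0.05"` reproduces [default_thresholds()] exactly).
#'
#' @param spec threshold spec string.
#' @return Strictly increasing numeric vector of thresholds in (0, 1).
#' @export
parse_thresholds <- function(spec) {
  parts <- suppressWarnings(as.numeric(strsplit(spec, ":")[[1]]))
  if (length(parts) != 3L || anyNA(parts)) stopf("bad threshold spec '%s'", spec)
  h <- round(parts * 100)
  values <- seq.int(h[1], h[2], by = h[3]) / 100
  if (any(values <= 0) || any(values >= 1) || is.unsorted(values, strictly = TRUE)) {
    stopf("thresholds must be strictly increasing within (0, 1)")
  }
  values
}

#' Intersection over union of two binary regions
#'
#' `IoU = |A intersect B| / |A union B|` between two pixel sets on a common
#' grid; defined as 0 when both regions are empty. A prediction that covers
#' its target perfectly scores exactly 1.
#'
#' @param a,b logical/0-1 matrices of the same shape.
#' @return IoU score in `[0, 1]`.
#' @examples
#' a <- matrix(FALSE, 4, 4); a[2:3, 2:3] <- TRUE
#' iou(a, a)  # 1
#' @export
iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("regions must share one grid shape")
  a <- a > 0; b <- b > 0
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(0)
  inter / uni
}

#' Pairwise IoU matrix between all target and predicted objects
#'
#' Computes the full `n_targets x n_preds` IoU matrix. Intersections are
#' found sparsely by tabulating co-occurring label pairs in one pass over the
#' pixels, which is identical to the dense all-pairs computation: a pair
#' that shares no pixel has IoU exactly 0.
#'
#' @param targets,preds [label_mask()]s of the same shape.
#' @return List of class `iou_matrix` with `n_targets`, `n_preds` and
#'   `values` (dense numeric matrix).
#' @export
iou_matrix <- function(targets, preds) {
  stopifnot(inherits(targets, "label_mask"), inherits(preds, "label_mask"))
  if (!identical(dim(targets$labels), dim(preds$labels))) {
    stopf("target and prediction masks must share one shape")
  }
  nt <- targets$n_objects; np <- preds$n_objects
  tv <- as.vector(targets$labels); pv <- as.vector(preds$labels)
  area_t <- tabulate(tv, nbins = max(nt, 1L))
  area_p <- tabulate(pv, nbins = max(np, 1L))
  values <- matrix(0, nt, np)
  both <- tv > 0L & pv > 0L
  if (any(both)) {
    key <- (as.double(tv[both]) - 1) * np + as.double(pv[both])
    inter <- tabulate(key, nbins = nt * np)
    hit <- which(inter > 0L)
    ti <- ((hit - 1L) %/% np) + 1L
    pj <- ((hit - 1L) %% np) + 1L
    values[cbind(ti, pj)] <- inter[hit] / (area_t[ti] + area_p[pj] - inter[hit])
  }
  structure(list(n_targets = nt, n_preds = np, values = values),
            class = "iou_matrix")
}

#' Match predicted to target objects at one IoU threshold
#'
#' A predicted object counts as a correct detection of a target when their
#' IoU strictly exceeds `t` (set `inclusive = TRUE` for `>=` sensitivity
#' checks). Matching is one-to-one: pairs are first taken greedily in
#' descending-IoU order (ties broken by lower target label, then lower
#' predicted label), then completed by augmenting paths so the number of
#' matches always equals the maximum one-to-one matching over the
#' admissible pairs. For `t >= 0.5` each object can exceed the threshold
#' with at most one partner, so the greedy pass alone is already the unique
#' maximal matching; the full matcher is checked against an exhaustive
#' oracle in the test suite.
#'
#' @param m an [iou_matrix()].
#' @param t IoU threshold in (0, 1).
#' @param inclusive logical; treat IoU exactly equal to `t` as a hit.
#' @return List of class `match_result`: `threshold`, `pairs` (data frame
#'   with `target`, `pred`, `iou`), `unmatched_targets`, `unmatched_preds`,
#'   and the confusion counts `tp`, `fp`, `fn` (`tn` is identically 0:
#'   object-level true negatives are undefined).
#' @export
match_at_threshold <- function(m, t, inclusive = FALSE) {
  stopifnot(inherits(m, "iou_matrix"), is_scalar_number(t), t > 0, t < 1)
  admissible <- if (inclusive) m$values >= t else m$values > t
  res <- matched_pairs(m$values, admissible)
  tp <- nrow(res)
  structure(list(
    threshold = t,
    pairs = res,
    unmatched_targets = setdiff(seq_len(m$n_targets), res$target),
    unmatched_preds = setdiff(seq_len(m$n_preds), res$pred),
    tp = tp, fp = m$n_preds - tp, fn = m$n_targets - tp, tn = 0L
  ), class = "match_result")
}

# One-to-one matching over admissible (target, pred) pairs: greedy in
# descending-IoU order (ties: lower target, then lower pred label), then
# augmenting paths so the cardinality always equals the maximum one-to-one
# matching (greedy alone can fall short below 0.5 where an object may exceed
# the threshold with several partners). Fully deterministic.
matched_pairs <- function(values, admissible) {
  nt <- nrow(values); np <- ncol(values)
  hits <- which(admissible)
  if (length(hits) == 0L || nt == 0L || np == 0L) {
    return(data.frame(target = integer(0), pred = integer(0), iou = numeric(0)))
  }
  ti <- ((hits - 1L) %% nt) + 1L
  pj <- ((hits - 1L) %/% nt) + 1L
  sc <- values[hits]
  ord <- order(-sc, ti, pj)
  match_of_pred <- integer(np)    # 0 = free
  match_of_target <- integer(nt)
  for (k in ord) {
    if (match_of_target[ti[k]] == 0L && match_of_pred[pj[k]] == 0L) {
      match_of_target[ti[k]] <- pj[k]
      match_of_pred[pj[k]] <- ti[k]
    }
  }
  # Kuhn augmentation from each still-unmatched target, in label order;
  # each target's candidate preds are kept in descending-IoU order so the
  # result is deterministic
  nbr <- vector("list", nt)
  for (k in ord) nbr[[ti[k]]] <- c(nbr[[ti[k]]], pj[k])
  seen <- logical(np)
  try_augment <- function(i) {
    for (j in nbr[[i]]) {
      if (seen[j]) next
      seen[j] <<- TRUE
      if (match_of_pred[j] == 0L || try_augment(match_of_pred[j])) {
        match_of_target[i] <<- j
        match_of_pred[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(nt)) {
    if (match_of_target[i] == 0L && length(nbr[[i]]) > 0L) {
      seen[] <- FALSE
      try_augment(i)
    }
  }
  sel <- which(match_of_target > 0L)
  data.frame(target = sel, pred = match_of_target[sel],
             iou = values[cbind(sel, match_of_target[sel])])
}

#' Precision, recall and F1 from a confusion at one threshold
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2TP/(2TP+FP+FN)`. A quotient
#' with zero denominator is defined as 0, except in the all-empty case
#' `TP = FP = FN = 0` (an image with nothing to find and nothing predicted),
#' where all three are defined as 1.
#'
#' @param tp,fp,fn non-negative confusion counts, or a `match_result` as
#'   `tp` with `fp`/`fn` missing.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (inherits(tp, "match_result")) { fp <- tp$fp; fn <- tp$fn; tp <- tp$tp }
  if (tp == 0 && fp == 0 && fn == 0) {
    return(c(precision = 1, recall = 1, f1 = 1))
  }
  q <- function(num, den) if (den == 0) 0 else num / den
  c(precision = q(tp, tp + fp), recall = q(tp, tp + fn),
    f1 = q(2 * tp, 2 * tp + fp + fn))
}

#' Score one image against its target mask
#'
#' Sweeps the threshold set, matches objects at each threshold and computes
#' the per-threshold confusion, precision/recall/F1 and the competition
#' score term `TP/(TP+FP+FN)` (defined as 1 when all three counts are 0).
#' The official score `S` is the unweighted mean of the terms over the
#' threshold set.
#'
#' @param targets,preds [label_mask()]s of one shape.
#' @param thresholds numeric threshold vector; defaults to the competition
#'   grid [default_thresholds()].
#' @param inclusive passed to [match_at_threshold()].
#' @return List of class `image_report`: `image_id`, `score` (S), and
#'   `by_threshold`, a data frame with columns `t`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `term`.
#' @examples
#' m <- label_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' image_score(m, m)$score  # 1
#' @export
image_score <- function(targets, preds, thresholds = default_thresholds(),
                        inclusive = FALSE) {
  m <- iou_matrix(targets, preds)
  rows <- lapply(thresholds, function(t) {
    mr <- match_at_threshold(m, t, inclusive = inclusive)
    prf <- precision_recall_f1(mr)
    term <- if (mr$tp + mr$fp + mr$fn == 0L) 1 else mr$tp / (mr$tp + mr$fp + mr$fn)
    data.frame(t = t, tp = mr$tp, fp = mr$fp, fn = mr$fn,
               precision = prf[["precision"]], recall = prf[["recall"]],
               f1 = prf[["f1"]], term = term)
  })
  by_t <- do.call(rbind, rows)
  structure(list(image_id = targets$image_id, score = mean(by_t$term),
                 by_threshold = by_t),
            class = "image_report")
}

#' @export
print.image_report <- function(x, ...) {
  cat(sprintf("<image_report '%s': S = %.4f over %d thresholds>\n",
              x$image_id, x$score, nrow(x$by_threshold)))
  invisible(x)
}

# Pooled percentages at a fixed threshold with the all-empty convention:
# no targets -> recall 100 / missed 0; no predictions -> extra 0.
pooled_at <- function(tp, fp, fn) {
  recall <- if (tp + fn == 0) 100 else 100 * tp / (tp + fn)
  extra <- if (tp + fp == 0) 0 else 100 * fp / (tp + fp)
  c(recall_at_07 = recall, missed_at_07 = 100 - recall, extra_at_07 = extra)
}

#' Evaluate a dataset of (target, prediction) mask pairs
#'
#' Produces the dataset-level metrics of the challenge analysis:
#' * `mean_score` — unweighted mean over images of the per-image score S
#'   (the challenge ranked per image);
#' * `average_f1` — mean over thresholds of the mean-over-images F1(t);
#' * `recall_at_07`, `missed_at_07`, `extra_at_07` — percentages from
#'   object counts pooled over all images at IoU threshold 0.7
#'   (recall + missed = 100 by construction; extra is normalized by the
#'   pooled predicted-object count, so it need not sum with recall);
#' * the same quantities per image group.
#'
#' @param pairs list; each element a list with elements `target` and `pred`
#'   ([label_mask()]s of one shape) and optionally `group`.
#' @param thresholds threshold vector, default [default_thresholds()].
#' @param inclusive passed to [match_at_threshold()].
#' @param pool_score if `TRUE`, additionally report `pooled_score` and
#'   `pooled_average_f1` computed from confusion counts pooled over images
#'   before forming ratios.
#' @return List of class `dataset_report` with the fields above, plus
#'   `images` (per-image data frame), `f1_curve` (per-threshold mean F1) and
#'   `by_group` (data frame, one row per group).
#' @export
evaluate_dataset <- function(pairs, thresholds = default_thresholds(),
                             inclusive = FALSE, pool_score = FALSE) {
  if (length(pairs) == 0L) stopf("evaluate_dataset needs at least one mask pair")
  reports <- vector("list", length(pairs))
  conf07 <- matrix(0, length(pairs), 3, dimnames = list(NULL, c("tp", "fp", "fn")))
  groups <- character(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    reports[[i]] <- image_score(p$target, p$pred, thresholds, inclusive = inclusive)
    m07 <- match_at_threshold(iou_matrix(p$target, p$pred), 0.7, inclusive = inclusive)
    conf07[i, ] <- c(m07$tp, m07$fp, m07$fn)
    groups[i] <- if (!is.null(p$group)) p$group else "unknown"
  }
  f1_by_image <- t(vapply(reports, function(r) r$by_threshold$f1,
                          numeric(length(thresholds))))
  scores <- vapply(reports, function(r) r$score, 0)
  summarize <- function(sel) {
    f1c <- colMeans(f1_by_image[sel, , drop = FALSE])
    out <- list(
      n_images = sum(sel),
      mean_score = mean(scores[sel]),
      average_f1 = mean(f1c),
      f1_curve = data.frame(t = thresholds, mean_f1 = f1c)
    )
    c(out, as.list(pooled_at(sum(conf07[sel, "tp"]), sum(conf07[sel, "fp"]),
                             sum(conf07[sel, "fn"]))))
  }
  overall <- summarize(rep(TRUE, length(pairs)))
  by_group <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    s <- summarize(groups == g)
    data.frame(group = g, n_images = s$n_images, mean_score = s$mean_score,
               average_f1 = s$average_f1, recall_at_07 = s$recall_at_07,
               missed_at_07 = s$missed_at_07, extra_at_07 = s$extra_at_07)
  }))
  images <- data.frame(
    image_id = vapply(reports, function(r) r$image_id, ""),
    group = groups, score = scores,
    tp_07 = conf07[, "tp"], fp_07 = conf07[, "fp"], fn_07 = conf07[, "fn"]
  )
  out <- list(
    n_images = length(pairs),
    mean_score = overall$mean_score,
    average_f1 = overall$average_f1,
    recall_at_07 = overall$recall_at_07,
    missed_at_07 = overall$missed_at_07,
    extra_at_07 = overall$extra_at_07,
    f1_curve = overall$f1_curve,
    by_group = by_group,
    images = images,
    reports = reports
  )
  if (pool_score) {
    tpm <- sapply(reports, function(r) r$by_threshold$tp)
    fpm <- sapply(reports, function(r) r$by_threshold$fp)
    fnm <- sapply(reports, function(r) r$by_threshold$fn)
    tp <- rowSums(tpm); fp <- rowSums(fpm); fn <- rowSums(fnm)
    term <- ifelse(tp + fp + fn == 0, 1, tp / (tp + fp + fn))
    f1 <- ifelse(tp + fp + fn == 0, 1, 2 * tp / (2 * tp + fp + fn))
    out$pooled_score <- mean(term)
    out$pooled_average_f1 <- mean(f1)
  }
  structure(out, class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<dataset_report: %d images>\n",
    "  mean score S     %.4f\n  average F1       %.4f\n",
    "  recall @0.7 IoU  %.2f%%\n  missed @0.7 IoU  %.2f%%\n",
    "  extra  @0.7 IoU  %.2f%%\n"),
    x$n_images, x$mean_score, x$average_f1,
    x$recall_at_07, x$missed_at_07, x$extra_at_07))
  invisible(x)
}

#' Mean F1 as a function of IoU threshold
#'
#' The per-threshold series behind accuracy-versus-coverage curves: the mean
#' over images of F1(t), non-increasing in `t` for fixed inputs.
#'
#' @inheritParams evaluate_dataset
#' @return Data frame with columns `t` and `mean_f1`.
#' @export
f1_curve <- function(pairs, thresholds = default_thresholds(), inclusive = FALSE) {
  evaluate_dataset(pairs, thresholds, inclusive = inclusive)$f1_curve
}
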
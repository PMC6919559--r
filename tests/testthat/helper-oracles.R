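# Shared fixtures and independent oracles used across test files.
# Everything here is deliberately naive: dense loops and exhaustive search,
# so package results can be checked against implementations that share no
# code path with them.

# Random canonical label mask: k disjoint blobs on an h x w grid.
random_mask <- function(h, w, k, seed, blob = 3L) {
  set.seed(seed)
  lab <- matrix(0L, h, w)
  placed <- 0L
  guard <- 0L
  while (placed < k && guard < 500L) {
    guard <- guard + 1L
    r <- sample.int(h - blob, 1L)
    c <- sample.int(w - blob, 1L)
    win <- lab[r:(r + blob - 1L), c:(c + blob - 1L)]
    if (any(win != 0L)) next
    placed <- placed + 1L
    sel <- matrix(runif(blob * blob) < 0.8, blob, blob)
    sel[1 + blob %/% 2, 1 + blob %/% 2] <- TRUE   # guarantee >= 1 pixel
    win[sel] <- placed
    lab[r:(r + blob - 1L), c:(c + blob - 1L)] <- win
  }
  label_mask(lab)
}

# A prediction mask correlated with `mask`: each object shifted by up to
# `shift` pixels (overlaps resolved first-wins), some objects dropped, some
# spurious blobs added, so IoU matrices carry genuine matching conflicts.
jittered_prediction <- function(mask, seed, shift = 2L, drop = 0.1, add = 1L) {
  set.seed(seed)
  h <- nrow(mask$labels); w <- ncol(mask$labels)
  out <- matrix(0L, h, w)
  nxt <- 0L
  for (k in seq_len(mask$n_objects)) {
    if (runif(1) < drop) next
    dy <- sample(-shift:shift, 1L); dx <- sample(-shift:shift, 1L)
    idx <- which(mask$labels == k)
    ri <- ((idx - 1L) %% h) + 1L + dy
    ci <- ((idx - 1L) %/% h) + 1L + dx
    ok <- ri >= 1L & ri <= h & ci >= 1L & ci <= w
    gi <- (ci[ok] - 1L) * h + ri[ok]
    gi <- gi[out[gi] == 0L]
    if (length(gi) == 0L) next
    nxt <- nxt + 1L
    out[gi] <- nxt
  }
  for (a in seq_len(add)) {
    r <- sample.int(h - 2L, 1L); c <- sample.int(w - 2L, 1L)
    win <- out[r:(r + 2L), c:(c + 2L)]
    if (all(win == 0L)) {
      nxt <- nxt + 1L
      out[r:(r + 2L), c:(c + 2L)] <- nxt
    }
  }
  label_mask(out)
}

# Dense all-pairs IoU oracle: one iou() call per object pair.
dense_iou_oracle <- function(targets, preds) {
  values <- matrix(0, targets$n_objects, preds$n_objects)
  for (i in seq_len(targets$n_objects)) {
    for (j in seq_len(preds$n_objects)) {
      values[i, j] <- iou(targets$labels == i, preds$labels == j)
    }
  }
  values
}

# Exhaustive maximum one-to-one matching cardinality over an adjacency
# matrix (targets x preds). Recursion; fine for <= 6 x 6.
max_matching_cardinality <- function(adj) {
  nt <- nrow(adj); np <- ncol(adj)
  if (nt == 0L || np == 0L) return(0L)
  rec <- function(i, used) {
    if (i > nt) return(0L)
    best <- rec(i + 1L, used)
    for (j in which(adj[i, ] & !used)) {
      used[j] <- TRUE
      best <- max(best, 1L + rec(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  rec(1L, logical(np))
}

# Exhaustive best one-to-one matching maximizing cardinality then total IoU;
# returns the matched-IoU multiset (sorted).
best_matching_ious <- function(values, threshold = 0) {
  nt <- nrow(values); np <- ncol(values)
  best <- list(card = -1L, total = -Inf, ious = numeric(0))
  rec <- function(i, used, ious) {
    if (i > nt) {
      card <- length(ious); total <- sum(ious)
      if (card > best$card || (card == best$card && total > best$total + 1e-12)) {
        best <<- list(card = card, total = total, ious = ious)
      }
      return(invisible())
    }
    rec(i + 1L, used, ious)
    for (j in which(!used)) {
      if (values[i, j] > threshold) {
        used[j] <- TRUE
        rec(i + 1L, used, c(ious, values[i, j]))
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(np), numeric(0))
  sort(best$ious)
}

# Construct an iou_matrix object directly from a value matrix (for matcher
# contract tests that need exact scores).
manual_iou_matrix <- function(values) {
  structure(list(n_targets = nrow(values), n_preds = ncol(values),
                 values = values),
            class = "iou_matrix")
}

# Binary disk on an h x w grid.
disk_mask <- function(h, w, cy, cx, r) {
  d <- outer(seq_len(h), seq_len(w), function(y, x) sqrt((y - cy)^2 + (x - cx)^2))
  d <= r
}
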
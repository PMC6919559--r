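# Group classifier and the three-step classical segmentation pipeline.

test_that("the classifier recovers the generating group of synthetic images", {
  for (g in group_names()) {
    for (s in 1:3) {
      gen <- generate_image(synthetic_spec(g, seed = 200 + s))
      expect_equal(classify_group(gen$image)$group, g,
                   label = sprintf("group call for %s seed %d", g, s))
    }
  }
})

test_that("degenerate and constructed images get the documented calls", {
  flat <- image_record(matrix(0.5, 32, 32))
  call <- classify_group(flat)
  expect_equal(call$group, "small_fluorescent")
  expect_equal(call$confidence, "low")

  # bright background, dark blobs, no color: grayscale tissue
  px <- matrix(0.9, 64, 64)
  px[disk_mask(64, 64, 20, 20, 6)] <- 0.25
  px[disk_mask(64, 64, 44, 40, 7)] <- 0.30
  gray3 <- array(rep(px, 3), dim = c(64, 64, 3))
  expect_equal(classify_group(image_record(gray3))$group, "grayscale_tissue")
})

test_that("foreground transform makes nuclei bright regardless of input polarity", {
  flu <- generate_image(synthetic_spec("small_fluorescent", seed = 5))
  g1 <- to_foreground_grayscale(flu$image, group_preset("small_fluorescent"))
  fg <- flu$mask$labels > 0
  expect_gt(mean(g1[fg]), mean(g1[!fg]))
  expect_true(min(g1) >= 0 && max(g1) <= 1)

  tis <- generate_image(synthetic_spec("purple_tissue", seed = 5))
  g2 <- to_foreground_grayscale(tis$image, group_preset("purple_tissue"))
  fg2 <- tis$mask$labels > 0
  expect_gt(mean(g2[fg2]), mean(g2[!fg2]))

  flat <- image_record(matrix(0.4, 16, 16))
  g3 <- to_foreground_grayscale(flat, group_preset("small_fluorescent"))
  expect_equal(length(unique(as.vector(round(g3, 10)))), 1)
})

test_that("identify_primary finds separated nuclei and splits touching pairs", {
  preset <- group_preset("small_fluorescent")
  expect_equal(identify_primary(matrix(0, 32, 32), preset)$n_objects, 0)

  clean <- generate_image(synthetic_spec("small_fluorescent", n_objects = 20,
                                         noise_sd = 0, touching_prob = 0, seed = 17))
  gray <- to_foreground_grayscale(clean$image, preset)
  expect_equal(identify_primary(gray, preset)$n_objects, 20)

  # two equal disks fused into one blob: declumping must yield two objects
  blob <- (disk_mask(40, 40, 20, 14, 6) | disk_mask(40, 40, 20, 26, 6)) * 0.8
  two <- identify_primary(blob, preset)
  expect_equal(two$n_objects, 2)
  areas <- tabulate(two$labels[two$labels > 0])
  expect_lt(abs(areas[1] - areas[2]) / sum(areas), 0.2)  # roughly equal split
})

test_that("refine_secondary preserves good objects and recovers eroded ones", {
  clean <- generate_image(synthetic_spec("small_fluorescent", n_objects = 12,
                                         noise_sd = 0, touching_prob = 0,
                                         illumination_gradient = 0, seed = 19))
  preset <- group_preset("small_fluorescent")
  gray <- to_foreground_grayscale(clean$image, preset)

  # a primary with nothing left to fix passes through (almost) unchanged
  primary <- identify_primary(gray, preset)
  refined <- refine_secondary(gray, primary, preset)
  expect_equal(refined$n_objects, primary$n_objects)
  agr <- pairwise_agreement(primary, refined)
  expect_true(all(agr$per_object_ious >= 0.99))

  # a primary eroded 2 px inside the true support recovers most of its IoU
  erbin <- EBImage::imageData(EBImage::erode(
    EBImage::Image((clean$mask$labels > 0) * 1), EBImage::makeBrush(5, "disc")))
  eroded <- label_mask(clean$mask$labels * (erbin > 0))
  expect_equal(eroded$n_objects, clean$mask$n_objects)
  rec <- refine_secondary(gray, eroded, preset)
  ious_in <- pairwise_agreement(clean$mask, eroded)$per_object_ious
  ious_out <- pairwise_agreement(clean$mask, rec)$per_object_ious
  expect_gt(median(ious_out), median(ious_in))
  expect_gt(median(ious_out), 0.9)

  empty <- label_mask(matrix(0L, nrow(gray), ncol(gray)))
  expect_equal(refine_secondary(gray, empty, preset)$n_objects, 0)
})

test_that("refinement never splits and respects the size prior", {
  for (s in 1:4) {
    gen <- generate_image(synthetic_spec("purple_tissue", seed = 300 + s))
    preset <- group_preset("purple_tissue")
    gray <- to_foreground_grayscale(gen$image, preset)
    prim <- identify_primary(gray, preset)
    sec <- refine_secondary(gray, prim, preset)
    expect_lte(sec$n_objects, prim$n_objects)
    if (sec$n_objects > 0) {
      d <- 2 * sqrt(tabulate(sec$labels[sec$labels > 0]) / pi)
      expect_true(all(d >= preset$min_diameter & d <= preset$max_diameter))
    }
  }
})

test_that("segmentation is deterministic and needs no configuration", {
  gen <- generate_image(synthetic_spec("pink_purple_tissue", seed = 23))
  r1 <- segment_nuclei(gen$image)
  r2 <- segment_nuclei(gen$image)
  expect_identical(r1$mask$labels, r2$mask$labels)
  expect_equal(r1$group_call$group, "pink_purple_tissue")
})

test_that("a clean fluorescent image is segmented perfectly at 0.5 IoU", {
  gen <- generate_image(synthetic_spec("small_fluorescent", n_objects = 20,
                                       noise_sd = 0, touching_prob = 0, seed = 29))
  res <- segment_nuclei(gen$image)
  rep <- image_score(gen$mask, res$mask, thresholds = 0.5)
  expect_equal(rep$by_threshold$f1[1], 1)
  expect_equal(segment_nuclei(image_record(matrix(0.1, 64, 64)))$mask$n_objects, 0)
})
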
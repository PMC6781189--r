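test_that("lesion parameters are validated", {
  expect_error(lesion_params(base_radius_fraction = 0.6),
               class = "lesioncam_parameter_error")
  expect_error(lesion_params(boundary_irregularity = -1),
               class = "lesioncam_parameter_error")
  expect_error(lesion_params(texture_contrast = 1.5),
               class = "lesioncam_parameter_error")
})

test_that("mask generation is deterministic and respects the ellipse limit", {
  m1 <- withr::with_seed(11, generate_lesion_mask(48))
  m2 <- withr::with_seed(11, generate_lesion_mask(48))
  expect_identical(m1, m2)

  # zero irregularity: foreground is exactly the pixels inside the ellipse
  p0 <- lesion_params(boundary_irregularity = 0)
  m <- withr::with_seed(5, generate_lesion_mask(64, p0))
  geo <- attr(m, "geometry")
  jj <- matrix(rep(1:64, each = 64), 64)
  ii <- matrix(rep(1:64, times = 64), 64)
  dx <- jj - geo$centre["x"]; dy <- ii - geo$centre["y"]
  u <- dx * cos(geo$rotation) + dy * sin(geo$rotation)
  v <- -dx * sin(geo$rotation) + dy * cos(geo$rotation)
  inside <- (u / geo$semi_axes["a"])^2 + (v / geo$semi_axes["b"])^2 <= 1
  expect_identical(unname(m[TRUE]), unname(inside[TRUE]))

  expect_error(generate_lesion_mask(8), class = "lesioncam_parameter_error")
})

test_that("mask areas stay within 1-40% of the frame", {
  p <- lesion_params(base_radius_fraction = 0.15)
  areas <- withr::with_seed(99, {
    vapply(seq_len(1000), function(i) mean(generate_lesion_mask(48, p)),
           numeric(1))
  })
  expect_true(all(areas >= 0.01))
  expect_true(all(areas <= 0.40))
})

test_that("masks are single connected blobs", {
  masks <- withr::with_seed(7, {
    lapply(1:50, function(i) generate_lesion_mask(48))
  })
  n_comp <- vapply(masks, function(m) {
    max(lesioncam:::.label_components8(m))
  }, integer(1))
  expect_true(all(n_comp == 1L))
})

test_that("rendering couples masks to lesion classes", {
  m <- withr::with_seed(1, generate_lesion_mask(32))
  expect_error(render_image("nonEGC", mask = m),
               class = "lesioncam_consistency_error")
  expect_error(render_image("T1a"), class = "lesioncam_consistency_error")
  img <- withr::with_seed(2, render_image("nonEGC", image_side = 32))
  expect_null(img$lesion_mask)
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
})

test_that("zero-amplitude lesions are invisible", {
  p0 <- lesion_params(texture_contrast = 0, rim_strength = 0, color_shift = 0)
  diffs <- withr::with_seed(21, {
    vapply(1:50, function(i) {
      m <- generate_lesion_mask(48, p0)
      img <- render_image("T1a", mask = m, params = p0,
                          shortcut_artifact = FALSE, vignetting = FALSE)
      lum <- luminance_of(img)
      mean(lum[m]) - mean(lum[!m])
    }, numeric(1))
  })
  expect_lt(abs(mean(diffs)), 0.02)

  # with all appearance amplitudes at zero, the two depth classes render
  # identical pixels from the same random state
  m <- withr::with_seed(3, generate_lesion_mask(48, p0))
  ia <- withr::with_seed(4, render_image("T1a", mask = m, params = p0))
  ib <- withr::with_seed(4, render_image("T1b", mask = m, params = p0))
  expect_identical(ia$pixels, ib$pixels)
})

test_that("submucosal rim brightens the lesion margin", {
  p <- lesion_params(rim_strength = 0.5, texture_contrast = 0,
                     color_shift = 0)
  withr::with_seed(8, {
    m <- generate_lesion_mask(64, p)
    img <- render_image("T1b", mask = m, params = p,
                        shortcut_artifact = FALSE, vignetting = FALSE)
    lum <- luminance_of(img)
    ring <- lesioncam:::dilate1(m) & !m
    interior <- lesioncam:::erode1(m)
    expect_gt(mean(lum[ring]), mean(lum[interior]))
  })
})

test_that("cohorts are reproducible, patient-grouped and mask-consistent", {
  co1 <- tiny_cohort(seed = 13)
  co2 <- tiny_cohort(seed = 13)
  expect_identical(co1$labels, co2$labels)
  expect_identical(co1$images[[1]]$pixels, co2$images[[1]]$pixels)

  co <- generate_cohort(10, images_per_patient = c(2L, 2L), image_side = 32,
                        seed = 1)
  expect_equal(nrow(co$labels), 20L)
  expect_equal(length(unique(co$labels$patient_id)), 10L)
  # every image belongs to exactly one patient
  expect_equal(anyDuplicated(co$labels$image_id), 0L)

  # mask/class coupling across the whole cohort
  for (im in co$images) {
    expect_identical(!is.null(im$lesion_mask), im$class_label != "nonEGC")
    if (!is.null(im$lesion_mask)) expect_gte(sum(im$lesion_mask), 1)
  }

  pure <- generate_cohort(6, class_mix = c(1, 0, 0), image_side = 32,
                          seed = 2)
  expect_true(all(pure$labels$class == "nonEGC"))

  expect_error(generate_cohort(3, image_side = 32),
               class = "lesioncam_parameter_error")
  expect_error(generate_cohort(6, class_mix = c(0.5, 0.2, 0.2),
                               image_side = 32),
               class = "lesioncam_parameter_error")
})

test_that("in-mask texture contrast grows with the texture amplitude", {
  stats <- vapply(c(0.1, 0.3, 0.5), function(tc) {
    p <- lesion_params(texture_contrast = tc)
    withr::with_seed(31, {
      mean(vapply(1:100, function(i) {
        m <- generate_lesion_mask(48, p)
        img <- render_image("T1a", mask = m, params = p,
                            shortcut_artifact = FALSE)
        texture_contrast_stat(img)
      }, numeric(1)))
    })
  }, numeric(1))
  expect_true(all(diff(stats) > 0))
})

test_that("cohorts roundtrip through PNG + CSV byte-identically", {
  co <- tiny_cohort(n_patients = 6, seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(tiny_cohort(n_patients = 6, seed = 3), d2)
  expect_identical(readLines(file.path(d1, "labels.csv")),
                   readLines(file.path(d2, "labels.csv")))
  expect_identical(unname(tools::md5sum(sort(list.files(file.path(d1, "images"),
                                                        full.names = TRUE)))),
                   unname(tools::md5sum(sort(list.files(file.path(d2, "images"),
                                                        full.names = TRUE)))))
  back <- read_cohort(d1)
  expect_identical(back$labels$image_id, co$labels$image_id)
  expect_identical(back$labels$class, co$labels$class)
  iid <- co$labels$image_id[co$labels$class != "nonEGC"][1]
  expect_identical(unname(back$images[[iid]]$lesion_mask[TRUE]),
                   unname(co$images[[iid]]$lesion_mask[TRUE]))
})
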
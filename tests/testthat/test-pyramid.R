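test_that("scale interpolation is geometric with exact endpoints", {
  spec <- scale_pyramid_spec()
  s <- compute_scales(spec, c(200, 200, 200))
  # closed form: s0 = 0.8*200/32 = 5, ratio (1/5)^(1/3)
  expect_equal(s, 5 * (1 / 5)^((0:3) / 3), tolerance = 1e-12)
  expect_equal(round(s, 3), c(5.000, 2.924, 1.710, 1.000))
  expect_equal(s[1], 0.8 * 200 / 32)
  expect_equal(s[4], 1.0)
  r <- s[-length(s)] / s[-1]
  expect_lt(diff(range(r)), 1e-12)                 # constant ratio
  # degenerate cases
  expect_equal(compute_scales(scale_pyramid_spec(depth = 1), 200), 1.0)
  expect_error(compute_scales(spec, 40), "degenerate")
})

test_that("finest-level extraction equals a plain crop when aligned", {
  set.seed(3)
  v <- volume(array(round(rnorm(40^3, 0, 300)), c(40, 40, 40)), spacing = 1)
  ctr <- c(19.5, 19.5, 19.5)       # even matrix: aligned at half-integers
  st <- extract_stack(v, ctr, scales = 1, matrix = 8)
  expect_equal(st$levels[[1]]$data, v$data[17:24, 17:24, 17:24])
})

test_that("patch stacks nest strictly and respect the shared centre", {
  v <- volume(array(0, c(60, 60, 60)), spacing = 1)
  sc <- compute_scales(scale_pyramid_spec(matrix = 8), c(60, 60, 60))
  st <- extract_stack(v, c(30, 30, 30), sc, matrix = 8)
  ext <- vapply(st$levels, function(l) 8 * l$spacing, numeric(1))
  expect_true(all(diff(ext) < 0))
  expect_error(extract_stack(v, c(200, 30, 30), sc, matrix = 8), "outside")
})

test_that("coordinate round trip on the finest grid is exact", {
  sp <- 1.0
  M <- 16
  ctr <- c(31.5, 31.5, 31.5)
  j <- c(3, 10, 15)
  pos <- ctr + (j - (M - 1) / 2) * sp
  back <- (pos - ctr) / sp + (M - 1) / 2
  expect_identical(back, as.numeric(j))
})

test_that("image and label stacks share one augmentation transform", {
  # a bright 3^3 marker block carried by both image and labels: wherever the
  # label patch sees the marker, the image patch must see elevated HU, for
  # any sampled transform -- this fails if the two stacks used different
  # transforms
  v <- volume(array(-1024, c(40, 40, 40)), spacing = 1)
  lab <- label_map(array(0L, c(40, 40, 40)), n_labels = 1, spacing = 1)
  v$data[20:22, 22:24, 17:19] <- 3000
  lab$data[20:22, 22:24, 17:19] <- 1L
  found <- 0L
  for (seed in 40:49) {
    st <- extract_stack(v, c(19.5, 19.5, 19.5), scales = c(2, 1), matrix = 8,
                        augment = augment_spec(), seed = seed)
    ls <- extract_label_stack(lab, c(19.5, 19.5, 19.5), scales = c(2, 1),
                              matrix = 8, transform = st$transform)
    hit <- ls$levels[[2]]$data == 1L
    if (any(hit)) {
      found <- found + 1L
      expect_gt(min(st$levels[[2]]$data[hit]), -500)
    }
    expect_gt(max(st$levels[[2]]$data[!hit]), -1024) # marker fringe visible
    # seeded determinism
    st2 <- extract_stack(v, c(19.5, 19.5, 19.5), scales = c(2, 1), matrix = 8,
                         augment = augment_spec(), seed = seed)
    expect_identical(st$levels[[2]]$data, st2$levels[[2]]$data)
  }
  expect_gt(found, 5)
})

test_that("zero-range augmentation equals no augmentation", {
  set.seed(5)
  v <- volume(array(round(rnorm(30^3, 0, 200)), c(30, 30, 30)), spacing = 1)
  aug0 <- augment_spec(max_rotation_deg = 0, flip_axis = 0, max_scale_frac = 0)
  a <- extract_stack(v, c(14.5, 14.5, 14.5), scales = c(2, 1), matrix = 8,
                     augment = aug0, seed = 1)
  b <- extract_stack(v, c(14.5, 14.5, 14.5), scales = c(2, 1), matrix = 8)
  expect_equal(a$levels[[1]]$data, b$levels[[1]]$data)
  expect_equal(a$levels[[2]]$data, b$levels[[2]]$data)
})

test_that("all-background and all-foreground regions extract as such", {
  lab <- label_map(array(0L, c(30, 30, 30)), n_labels = 1, spacing = 1)
  ls <- extract_label_stack(lab, c(14.5, 14.5, 14.5), scales = c(2, 1), matrix = 8)
  expect_true(all(ls$levels[[1]]$data == 0L) && all(ls$levels[[2]]$data == 0L))
  lab$data[] <- 1L
  ls2 <- extract_label_stack(lab, c(14.5, 14.5, 14.5), scales = c(2, 1), matrix = 8)
  expect_true(all(ls2$levels[[1]]$data == 1L) && all(ls2$levels[[2]]$data == 1L))
})

test_that("label-biased centre sampling hits at the requested rate", {
  lab <- label_map(array(0L, c(60, 60, 60)), n_labels = 1, spacing = 1)
  lab$data[30:32, 30:32, 30:32] <- 1L              # sparse blob
  hit_rate <- function(ctrs) {
    mean(vapply(seq_len(nrow(ctrs)), function(i) {
      lp <- extract_label_stack(lab, ctrs[i, ], scales = 1, matrix = 16)
      any(lp$levels[[1]]$data > 0)
    }, logical(1)))
  }
  ctrs <- sample_training_centers(lab, 1000, patch_mm = 16,
                                  label_hit_fraction = 0.8, seed = 9)
  expect_gt(hit_rate(ctrs), 0.75)                  # 3 sigma binomial band at
  expect_lt(hit_rate(ctrs), 0.85)                  # n = 1000 around 0.8
  # fraction 1: every patch hits
  c1 <- sample_training_centers(lab, 100, 16, 1.0, seed = 2)
  expect_equal(hit_rate(c1), 1.0)
  # fraction 0: uniform; hit rate equals the dilated-foreground coverage
  c0 <- sample_training_centers(lab, 800, 16, 0.0, seed = 3)
  cover <- ((3 + 15)^3) / 60^3                     # blob side + (M-1) reach
  expect_lt(abs(hit_rate(c0) - cover), 3 * sqrt(cover * (1 - cover) / 800) + 0.01)
  expect_error(sample_training_centers(
    label_map(array(0L, c(10, 10, 10)), n_labels = 1), 10, 8, 0.5), "foreground")
})
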
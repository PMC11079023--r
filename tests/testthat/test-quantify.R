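# hand-built stack: Gaussian nuclei at given positions with set peak
# intensities, on a constant background
blob_stack <- function(centers, sensor_peak, reference_peak, dims = c(40, 40, 20),
                       sigma = 1.5, bg = 0) {
  sen <- array(bg, dims); ref <- array(bg, dims)
  xs <- seq_len(dims[1]) - 1; ys <- seq_len(dims[2]) - 1
  zs <- seq_len(dims[3]) - 1
  for (i in seq_len(nrow(centers))) {
    gx <- exp(-(xs - centers[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - centers[i, 2])^2 / (2 * sigma^2))
    gz <- exp(-(zs - centers[i, 3])^2 / (2 * sigma^2))
    blob <- outer(outer(gx, gy), gz)
    sen <- sen + sensor_peak[i] * blob
    ref <- ref + reference_peak[i] * blob
  }
  image_stack(list(sensor = sen, reference = ref), spacing = c(1, 1, 1))
}

test_that("nucleus detection finds every synthetic nucleus one-to-one", {
  g <- small_sam()
  nuc <- detect_nuclei(g$stack)
  tr <- g$truth$nuclei
  expect_equal(nrow(nuc), nrow(tr))
  d <- as.matrix(dist(rbind(cbind(nuc$x, nuc$y, nuc$z),
                            cbind(tr$x, tr$y, tr$z))))
  d <- d[seq_len(nrow(nuc)), nrow(nuc) + seq_len(nrow(tr)), drop = FALSE]
  nn <- unname(apply(d, 1, which.min))
  # one-to-one and within one nucleus sigma of the true centre
  expect_equal(sort(nn), seq_len(nrow(tr)))
  expect_true(all(d[cbind(seq_len(nrow(nuc)), nn)] <= 1.5))
  # detections sorted by z, y, x
  expect_true(!is.unsorted(nuc$z))
})

test_that("flat images yield zero detections, not an error", {
  z <- image_stack(list(reference = array(0, c(20, 20, 10))),
                   spacing = c(1, 1, 1))
  expect_equal(nrow(detect_nuclei(z)), 0)
  c5 <- image_stack(list(reference = array(5, c(20, 20, 10))),
                    spacing = c(1, 1, 1))
  expect_equal(nrow(detect_nuclei(c5)), 0)
})

test_that("blobs closer than min_blob_distance merge into one detection", {
  st <- blob_stack(rbind(c(19, 20, 10), c(21.2, 20, 10)), c(100, 100),
                   c(100, 100))
  cfg <- quant_config(min_blob_distance = 4)
  expect_equal(nrow(detect_nuclei(st, cfg)), 1)
  far <- blob_stack(rbind(c(12, 20, 10), c(28, 20, 10)), c(100, 100),
                    c(100, 100))
  expect_equal(nrow(detect_nuclei(far, cfg)), 2)
})

test_that("detection is translation-equivariant", {
  st <- blob_stack(rbind(c(15, 18, 8), c(25, 22, 12)), c(80, 120), c(100, 90))
  n0 <- detect_nuclei(st)
  sh <- list(reference = gasigmap:::shift3d(st$channels$reference,
                                            c(3, -2, 1), 0))
  n1 <- detect_nuclei(image_stack(sh, spacing = c(1, 1, 1)))
  expect_equal(nrow(n1), nrow(n0))
  expect_equal(n1$x, n0$x + 3)
  expect_equal(n1$y, n0$y - 2)
  expect_equal(n1$z, n0$z + 1)
})

test_that("intensity ratios are recovered and background cancels", {
  st <- blob_stack(matrix(c(20, 20, 10), 1), 120, 60)
  nuc <- detect_nuclei(st)
  rec <- measure_intensities(st, nuc)
  expect_equal(rec$ratio, 2.0, tolerance = 1e-6)
  # uniform background on both channels is removed by subtraction
  stb <- blob_stack(matrix(c(20, 20, 10), 1), 120, 60, bg = 10)
  recb <- measure_intensities(stb, detect_nuclei(stb))
  expect_equal(recb$ratio, 2.0, tolerance = 0.02)
})

test_that("records out of the image or below the reference floor are dropped", {
  st <- blob_stack(matrix(c(20, 20, 10), 1), 120, 60)
  nuc <- data.frame(id = 1:2, x = c(20, 200), y = c(20, 200), z = c(10, 50))
  rec <- measure_intensities(st, nuc)
  expect_equal(nrow(rec), 1)
  qc <- attr(rec, "qc")
  expect_equal(qc$n_dropped_outside, 1)
  # dim nucleus: reference below min_reference (positions given, since a
  # reference-dark nucleus is undetectable by design)
  st2 <- blob_stack(rbind(c(12, 12, 10), c(28, 28, 10)), c(100, 100),
                    c(100, 0.001))
  nuc2 <- data.frame(id = 1:2, x = c(12, 28), y = c(12, 28), z = c(10, 10))
  rec2 <- measure_intensities(st2, nuc2, quant_config(min_reference = 5))
  expect_equal(nrow(rec2), 1)
  expect_equal(attr(rec2, "qc")$n_dropped_dim, 1)
})

test_that("signaling transform is 3 minus ratio, flagged out of range", {
  expect_equal(as.numeric(compute_signaling(1.0)), 2.0)
  expect_equal(as.numeric(compute_signaling(0)), 3.0)  # sensor fully degraded
  expect_warning(s <- compute_signaling(3.5), "flagged")
  expect_equal(as.numeric(s), -0.5)
  expect_true(attr(s, "out_of_range"))
  expect_error(compute_signaling(Inf), "finite")
  expect_error(compute_signaling(NA_real_), "finite")
  expect_error(compute_signaling(-0.1), "non-negative")
  # monotonicity: increasing ratio strictly decreases signaling
  r <- seq(0, 3, by = 0.1)
  expect_true(all(diff(as.numeric(compute_signaling(r))) < 0))
})

test_that("per-image ratio standardization centres distributions on 1", {
  rec <- data.frame(ratio = c(2, 4))
  out <- standardize_ratios(rec)
  expect_equal(out$ratio, c(2 / 3, 4 / 3))
  expect_equal(mean(out$ratio), 1)
  recc <- data.frame(ratio = rep(0.7, 5))
  expect_equal(standardize_ratios(recc)$ratio, rep(1, 5))
  expect_error(standardize_ratios(data.frame(ratio = numeric(0))),
               "at least one")
  expect_error(standardize_ratios(data.frame(ratio = c(0, 0))), "positive")
  # any synthetic image: mean standardized ratio exactly 1
  g <- small_sam()
  rec2 <- measure_intensities(g$stack, detect_nuclei(g$stack))
  expect_equal(mean(standardize_ratios(rec2)$ratio), 1, tolerance = 1e-12)
})

test_that("noiseless round trip recovers the signaling field within 1%", {
  g <- small_sam()
  rec <- measure_intensities(g$stack, detect_nuclei(g$stack))
  rec$region <- truth_region_of(rec, g$truth)
  mr <- tapply(rec$signaling, rec$region, mean)
  target <- small_spec()$signaling_field
  for (r in names(target))
    expect_equal(unname(mr[r]), unname(target[r]), tolerance = 0.01)
})

test_that("anisotropic stacks are resampled before detection", {
  g <- small_sam()
  ch <- g$stack$channels$reference
  thick <- ch[, , seq(1, dim(ch)[3], by = 2)]
  st <- image_stack(list(reference = thick), spacing = c(1, 1, 2))
  nuc <- detect_nuclei(st)
  tr <- g$truth$nuclei
  expect_gt(nrow(nuc), 0.9 * nrow(tr))
})

test_that("nucleus records and QC report are written", {
  g <- small_sam()
  rec <- measure_intensities(g$stack, detect_nuclei(g$stack))
  dir <- tempfile()
  write_nucleus_records(rec, dir)
  expect_true(file.exists(file.path(dir, "nuclei.csv")))
  qc <- jsonlite::read_json(file.path(dir, "qc.json"), simplifyVector = TRUE)
  expect_equal(qc$n_detected, 50)
  unlink(dir, recursive = TRUE)
})
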
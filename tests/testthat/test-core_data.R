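# Data model, preprocessing, labels, regions, file dialects.

test_that("rating binarization thresholds at 5 with 5 classified high", {
  r <- data.frame(valence = c(5, 1, 4.99, 9), arousal = c(5, 9, 2, 1))
  lab <- binarize_labels(r)
  expect_equal(lab$valence_bin, c(1L, 0L, 0L, 1L))
  expect_equal(lab$arousal_bin, c(1L, 1L, 0L, 0L))
  expect_equal(as.character(lab$four_class),
               c("HVHA", "LVHA", "LVLA", "HVLA"))
  expect_error(binarize_labels(data.frame(valence = 0.5, arousal = 5)),
               "out of range")
})

test_that("reflecting a rating about the scale midpoint flips its label", {
  r <- setdiff(seq(1, 8, by = 0.5), 4.5)  # keep 9 - r in range, skip (4, 5)
  lab <- binarize_labels(data.frame(valence = r, arousal = r))
  flip <- binarize_labels(data.frame(valence = 9 - r, arousal = 9 - r))
  expect_equal(lab$valence_bin + flip$valence_bin, rep(1L, length(r)))
})

test_that("preprocessing subtracts the 3-s baseline mean and trims to 60 s", {
  fs <- 128
  n <- 63 * fs
  x <- matrix(rnorm(40 * n), 40, n)
  x[5, ] <- 2.5  # constant channel
  raw <- trial_recording(x, fs, deap_channel_names(peripheral = TRUE))
  out <- preprocess_trial(raw)
  expect_equal(dim(out$data), c(32L, 7680L))
  expect_equal(unname(out$data[5, ]), rep(0, 7680))
  expect_equal(out$channel_names, deap_channel_names())

  # zero baseline leaves the final 60 s untouched
  x2 <- cbind(matrix(0, 4, 3 * fs), matrix(rnorm(4 * 60 * fs), 4))
  out2 <- preprocess_trial(trial_recording(x2, fs))
  expect_equal(unname(out2$data), unname(x2[, -(1:(3 * fs))]))

  expect_error(preprocess_trial(trial_recording(x[, 1:1000], fs)),
               "too short")
})

test_that("the five scalp regions partition the 32 channels", {
  reg <- deap_regions()
  all_ch <- unname(unlist(reg))
  expect_setequal(all_ch, deap_channel_names())
  expect_length(all_ch, 32)
  expect_equal(anyDuplicated(all_ch), 0L)
  expect_length(intersect(reg$LT, reg$RT), 0)
  expect_equal(lengths(reg)[c("F", "LT", "RT", "C", "PO")],
               c(F = 9L, LT = 3L, RT = 3L, C = 7L, PO = 10L))
})

test_that("region selection subsets channels in recording order", {
  tr <- trial_recording(matrix(rnorm(32 * 100), 32), 128,
                        deap_channel_names())
  expect_equal(select_region(tr, region_mask("ALL"))$data, tr$data)
  lt <- select_region(tr, region_mask("LT"))
  expect_equal(lt$channel_names, c("FC5", "T7", "CP5"))  # recording order
  expect_equal(nrow(select_region(tr, region_mask("F"))$data), 9L)
  expect_error(select_region(tr, c("FC5", "Nope")), "not present")
})

test_that("subject files round-trip through both on-disk dialects", {
  st <- generate_study(
    1, 3,
    list(A = coupling_spec(4, matrix(c(1, 2), ncol = 2)),
         B = coupling_spec(4)),
    list(A = list(valence = c(6, 8), arousal = c(2, 4)),
         B = list(valence = c(2, 4), arousal = c(6, 8))),
    seed = 3, duration_s = 2)
  sd0 <- st$subjects[[1]]
  for (dialect in c("matlab", "python")) {
    path <- tempfile(fileext = if (dialect == "matlab") ".mat" else ".dat")
    write_subject(sd0, path, dialect)
    back <- load_subject(path, dialect)
    expect_length(back$trials, 3)
    for (i in 1:3)
      expect_equal(unname(back$trials[[i]]$data),
                   unname(sd0$trials[[i]]$data), tolerance = 1e-12)
    expect_equal(back$ratings$valence, sd0$ratings$valence,
                 tolerance = 1e-12)
    unlink(path)
  }
})

test_that("malformed subject files are rejected with shape errors", {
  p <- tempfile(fileext = ".mat")
  write_mat5(p, list(data = matrix(rnorm(12), 3), labels = matrix(5, 3, 4)))
  expect_error(load_subject(p), "3-dimensional")
  write_mat5(p, list(data = array(rnorm(24), c(2, 3, 4)),
                     labels = matrix(5, 3, 4)))
  expect_error(load_subject(p), "trial count mismatch")
  write_mat5(p, list(data = array(rnorm(24), c(2, 3, 4))))
  expect_error(load_subject(p), "no 'labels'")
  unlink(p)
})

test_that("the MAT reader handles zlib-compressed elements", {
  # emulate the v7 variant: wrap a written element in a compressed one
  p <- tempfile(fileext = ".mat")
  a <- matrix(rnorm(20), 4)
  write_mat5(p, list(data = a))
  r <- readBin(p, "raw", file.size(p))
  body <- r[129:length(r)]
  comp <- memCompress(body, type = "gzip")
  tag <- writeBin(c(15L, length(comp)), raw(), size = 4L, endian = "little")
  p2 <- tempfile(fileext = ".mat")
  writeBin(c(r[1:128], tag, comp), p2)
  expect_equal(read_mat5(p2)$data, a)
  unlink(c(p, p2))
})
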
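test_that("constructed coupling in the synthetic signal drives the index", {
  flat <- pac_signal(duration_s = 6, depth = 0, seed = 2)
  full <- pac_signal(duration_s = 6, depth = 1, seed = 2)
  fs <- attr(flat, "fs_hz")
  expect_lt(modulation_index(flat$x, fs)$modulation_index, 0.01)
  cm <- comodulogram(full$x, fs, phase_range = c(4, 8), amp_range = c(40, 80),
                     phase_overlap = 0.5, amp_overlap = 0.5, seed = 3)
  idx <- which(cm$mi == max(cm$mi), arr.ind = TRUE)
  expect_lt(abs(cm$phase_hz[idx[1]] - 6), 1.01)
  expect_lt(abs(cm$amp_hz[idx[2]] - 60), 10.01)
  expect_error(pac_signal(depth = 2), "depth")
})

test_that("fixture files are written, labelled and reproducible", {
  d <- withr::local_tempdir()
  fg <- generate_fixtures("slice-geometry", dir = d)
  expect_true(all(file.exists(fg)))
  geo <- read.csv(fg[1])
  expect_setequal(unique(geo$region), c("EC", "DG", "CA3", "CA1"))
  meta <- yaml::read_yaml(fg[2])
  expect_equal(meta$z_extent_um, 15000)

  f1 <- generate_fixtures("spike-toy", dir = d, seed = 7)
  sp1 <- read.csv(f1)
  f2 <- generate_fixtures("spike-toy", dir = d, seed = 7)
  expect_identical(sp1, read.csv(f2))
  expect_false(is.unsorted(sp1$time_ms))

  fp <- generate_fixtures("pac-signal", dir = d,
                          params = list(duration_s = 2), seed = 1)
  sig <- read.csv(fp)
  expect_equal(nrow(sig), 2000)
})
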
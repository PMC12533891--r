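test_that("traditional ACI reproduces the hand-worked ratio", {
  # one bin, intensities [1, 2, 3]: D = 2, sum I = 6, ACI = 1/3
  a <- aci_traditional(matrix(c(1, 2, 3), nrow = 1))
  expect_equal(a$per_frame, 1 / 3)
  expect_equal(a$aggregate, 1 / 3)
})

test_that("both indices vanish exactly on time-constant inputs", {
  const <- matrix(5, 10, 8)
  expect_identical(aci_traditional(const)$per_frame, 0)
  expect_identical(logmel_aci_frames(const)$per_frame, rep(0, 7))
})

test_that("a steady tone scores near zero Log-Mel ACI", {
  expect_lt(logmel_aci(gen_tone(2000, 1.0))$aggregate, 1e-3)
})

test_that("per-frame Log-Mel ACI reproduces the hand-worked values", {
  lm <- matrix(c(1, 2, 2, 2, 4, 1), nrow = 2)  # bands x frames [[1,2,4],[2,2,1]]
  v <- logmel_aci_frames(lm)$per_frame
  expect_equal(v, c(1 / 3, 3 / 4))
})

test_that("per-frame Log-Mel ACI equals the brute-force double loop", {
  errs <- sapply(1:25, function(i) {
    lm <- with_seed_test(100 + i, {
      nb <- sample(2:20, 1); nt <- sample(3:50, 1)
      matrix(stats::runif(nb * nt, 0, 4), nb, nt)
    })
    max(abs(logmel_aci_frames(lm)$per_frame - logmel_aci_oracle(lm)))
  })
  expect_lt(max(errs), 1e-12)
})

test_that("silent frames are guarded and counted", {
  lm <- matrix(0, 20, 6)
  s <- logmel_aci_frames(lm)
  expect_identical(s$per_frame, rep(0, 5))
  expect_equal(s$silent_frames, 5)
  expect_error(logmel_aci_frames(matrix(1, 3, 1)), "2 frames")
  expect_error(aci_traditional(matrix(1, 3, 1)), "2 frames")
})

test_that("traditional ACI is scale-invariant; Log-Mel ACI is not", {
  spec <- with_seed_test(51, matrix(stats::runif(30 * 40, 0, 2), 30, 40))
  base <- aci_traditional(spec)$per_frame
  for (c_ in c(0.1, 10)) {
    expect_equal(aci_traditional(spec * c_)$per_frame, base, tolerance = 1e-12)
  }

  lm_base <- logmel_aci_frames(log_compress(spec))$aggregate
  lm_scaled <- logmel_aci_frames(log_compress(spec * 10))$aggregate
  expect_false(isTRUE(all.equal(lm_base, lm_scaled, tolerance = 1e-3)))
})

test_that("band order does not matter for either index", {
  lm <- with_seed_test(52, matrix(stats::runif(20 * 15, 0, 3), 20, 15))
  perm <- with_seed_test(53, sample(20))
  expect_equal(logmel_aci_frames(lm)$per_frame,
               logmel_aci_frames(lm[perm, ])$per_frame, tolerance = 1e-12)
  expect_equal(aci_traditional(lm)$per_frame,
               aci_traditional(lm[perm, ])$per_frame, tolerance = 1e-12)
})

test_that("aggregations are consistent and clumping partitions frames", {
  sig <- add_noise(gen_chirp_train(syllable_train_spec(
    5, 2000, 4000, duration = 2, seed = 54, jitter_frac = 0.5))$signal,
    "white", 20, seed = 55)
  m <- logmel_aci(sig, aggregation = "mean")
  s <- logmel_aci(sig, aggregation = "sum")
  expect_equal(m$aggregate * length(m$per_frame), s$aggregate, tolerance = 1e-12)

  spec <- with_seed_test(56, matrix(stats::runif(12 * 40), 12, 40))
  clumped <- aci_traditional(spec, clump_frames = 10)
  expect_length(clumped$per_frame, 4)
  whole <- aci_traditional(spec)
  expect_length(whole$per_frame, 1)
})

test_that("the literal product form differs from the ratio and scales", {
  spec <- with_seed_test(57, matrix(stats::runif(8 * 20), 8, 20))
  ratio <- aci_traditional(spec)$aggregate
  lit <- aci_traditional(spec, literal_eq9 = TRUE)$aggregate
  expect_false(isTRUE(all.equal(ratio, lit)))
  expect_equal(aci_traditional(spec * 2, literal_eq9 = TRUE)$aggregate, 4 * lit,
               tolerance = 1e-10)
})

test_that("Log-Mel ACI increases with syllable rate at fixed RMS", {
  vals <- sapply(c(2, 5, 10), function(r) {
    g <- gen_chirp_train(syllable_train_spec(r, 2000, 4000, syllable_dur = 0.06,
                                             duration = 3, seed = 42,
                                             jitter_frac = 0.5))
    s <- add_noise(scale_to_rms(g$signal, 0.1), "white", 20, seed = 542)
    logmel_aci(s)$aggregate
  })
  expect_true(all(diff(vals) > 0))
})

test_that("diel comparison recovers the constructed dawn > night > noon regime", {
  dd <- gen_diel_dataset(diel_dataset_spec(n_species = 2, n_per_group = 3, seed = 7))
  cmp <- compare_periods(dd$recordings, "logmel")
  for (sp in names(cmp$orderings)) {
    expect_identical(cmp$orderings[[sp]], c("dawn", "night", "noon"))
  }
  expect_equal(nrow(cmp$per_group), 6)
  expect_true(all(cmp$per_group$n == 3))

  # single recording per group: means equal the individual aggregates
  one <- gen_diel_dataset(diel_dataset_spec(n_species = 1, n_per_group = 1, seed = 9))
  c1 <- compare_periods(one$recordings, "logmel")
  expect_equal(sort(c1$per_group$mean_index), sort(c1$per_recording$aggregate))
})

test_that("Log-Mel ACI separates periods more than the traditional index", {
  dd <- gen_diel_dataset(diel_dataset_spec(n_species = 2, n_per_group = 4, seed = 7))
  s_lm <- diel_spread(compare_periods(dd$recordings, "logmel"))
  s_tr <- diel_spread(compare_periods(dd$recordings, "traditional"))
  expect_true(all(s_lm$spread >= s_tr$spread))
})

test_that("tidy/glance/autoplot views of results are well formed", {
  a <- logmel_aci_frames(with_seed_test(58, matrix(stats::runif(40), 4, 10)))
  td <- tidy(a)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 9)
  gl <- glance(a)
  expect_equal(gl$aggregate, a$aggregate)

  dd <- gen_diel_dataset(diel_dataset_spec(n_species = 1, n_per_group = 2, seed = 3))
  cmp <- compare_periods(dd$recordings, "logmel")
  expect_s3_class(tidy(cmp), "tbl_df")
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_spectrogram(stft_magnitude(gen_tone(2000, 0.2))), "ggplot")
  expect_s3_class(plot_aci_series(a), "ggplot")
})
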
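test_that("pooled features have the documented layout and stability", {
  g <- gen_chirp_train(syllable_train_spec(5, 2000, 4000, duration = 4,
                                           seed = 1, jitter_frac = 0.5))
  s <- add_noise(g$signal, "white", 20, seed = 2)
  v <- pool_features(second_order_mfcc(s))
  expect_length(v, 13 * 3 * 2)
  expect_true(all(c("c0_mean", "c12_sd", "dd0_mean") %in% names(v)))

  # constant coefficients: sd entries 0, delta means ~0
  msil <- second_order_mfcc(audio_signal(numeric(8192), 22050))
  vs <- pool_features(msil)
  expect_lt(max(abs(vs[grepl("_sd$", names(vs))])), 1e-9)
  expect_lt(max(abs(vs[grepl("^d{1,2}\\d+_mean$", names(vs))])), 1e-9)

  # shifting the vocalization against a continuing background moves the
  # pooled vector by well under 1% in norm
  s2 <- add_noise(time_shift(g$signal, 1000 * 512 / 22050), "white", 20, seed = 2)
  v2 <- pool_features(second_order_mfcc(s2))
  expect_lt(sqrt(sum((v - v2)^2)) / sqrt(sum(v^2)), 0.01)
})

test_that("stratified splits are seeded, disjoint and exhaustive", {
  dd <- gen_diel_dataset(diel_dataset_spec(n_species = 2, n_per_group = 10, seed = 3))
  ds <- build_feature_dataset(dd$recordings)
  sp <- split_train_val(ds, 0.8, seed = 11)

  # 8:2 within every (species, period) cell
  tr_cells <- table(paste(sp$train$species, sp$train$period))
  va_cells <- table(paste(sp$val$species, sp$val$period))
  expect_true(all(tr_cells == 8))
  expect_true(all(va_cells == 2))

  # partition: union is the dataset, intersection empty
  key <- function(d) paste(d$species, d$period,
                           vapply(d$features, function(f) f[["c0_mean"]], 0))
  expect_setequal(c(key(sp$train), key(sp$val)), key(ds))
  expect_length(intersect(key(sp$train), key(sp$val)), 0)

  sp2 <- split_train_val(ds, 0.8, seed = 11)
  expect_identical(key(sp2$train), key(sp$train))

  tiny <- ds[c(1, 2, 11), ]  # the cell in row 11 has a single sample
  expect_error(split_train_val(tiny, 0.8, seed = 1), "single sample")
})

test_that("the two-layer model memorizes separable data and routes properly", {
  dd <- gen_diel_dataset(diel_dataset_spec(n_species = 3, n_per_group = 3, seed = 5))
  ds <- build_feature_dataset(dd$recordings)
  m <- train_two_layer(ds, "nn")
  expect_length(m$layer2, 3)
  expect_setequal(names(m$layer2), unique(ds$species))

  # training samples under 1-NN return their own labels
  pred <- predict_two_layer(m, ds)
  expect_identical(pred$species, ds$species)
  expect_identical(pred$period, ds$period)
  # returned metadata records which layer-2 model ran
  expect_identical(pred$layer2_model, pred$species)

  # row order of the training set does not change 1-NN predictions
  perm <- with_seed_test(61, sample(nrow(ds)))
  m2 <- train_two_layer(ds[perm, ], "nn")
  pred2 <- predict_two_layer(m2, ds)
  expect_identical(pred2$species, pred$species)
  expect_identical(pred2$period, pred$period)

  expect_error(predict_two_layer(m, matrix(0, 1, 5)), "match")
  expect_error(train_two_layer(ds[ds$period != "noon" | ds$species != "species1", ]),
               "species1")
})

test_that("end-to-end validation accuracy is high on the default diel corpus", {
  dd <- gen_diel_dataset(diel_dataset_spec(seed = 7))
  ds <- build_feature_dataset(dd$recordings)
  sp <- split_train_val(ds, 0.8, seed = 7)
  m <- train_two_layer(sp$train, "nn")
  ev <- evaluate_two_layer(m, sp$val)
  expect_gte(ev$layer1_accuracy, 0.9)
  expect_gte(ev$layer2_accuracy, 0.9)
  # strict scoring can only be harder
  strict <- evaluate_two_layer(m, sp$val, "strict")
  expect_lte(strict$layer2_accuracy, ev$layer1_accuracy)
})

test_that("confusion counts match enumeration and always partition", {
  cc <- confusion_counts(c("A", "B", "A", "B"), c("A", "A", "B", "B"))
  a <- cc$counts[cc$counts$class == "A", ]
  expect_equal(c(a$tp, a$fn, a$fp, a$tn), c(1, 1, 1, 1))
  expect_true(all(cc$counts$tp + cc$counts$fp + cc$counts$fn + cc$counts$tn == 4))

  perfect <- confusion_counts(c("x", "y", "z"), c("x", "y", "z"))
  expect_true(all(perfect$counts$fp == 0))
  expect_true(all(perfect$counts$fn == 0))

  expect_error(confusion_counts(c("a"), c("a", "b")), "labels")
})

test_that("metrics reproduce closed forms and hand evaluation", {
  one <- manual_confusion_counts(9, 1, 1, 9)
  m <- classification_metrics(one, "macro")
  expect_equal(unlist(m[, c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 0.9, precision = 0.9, recall = 0.9, f1 = 0.9))

  # perfect 3-class predictions: all four metrics 1 in both averagings
  p <- confusion_counts(c("a", "b", "c", "a"), c("a", "b", "c", "a"))
  for (avg in c("macro", "micro")) {
    mm <- classification_metrics(p, avg)
    expect_equal(as.numeric(mm[, 1:4]), rep(1, 4))
  }

  # random 3-class confusion vs independent hand evaluation
  truth <- with_seed_test(62, sample(c("a", "b", "c"), 60, TRUE))
  pred <- with_seed_test(63, sample(c("a", "b", "c"), 60, TRUE))
  cc <- confusion_counts(pred, truth)
  by_class <- sapply(c("a", "b", "c"), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    c(prec = tp / (tp + fp), rec = tp / (tp + fn))
  })
  mac <- classification_metrics(cc, "macro")
  expect_equal(mac$precision, mean(by_class["prec", ]))
  expect_equal(mac$recall, mean(by_class["rec", ]))
  expect_equal(mac$f1, 2 * mac$precision * mac$recall / (mac$precision + mac$recall))

  # micro accuracy is the fraction of exactly correct predictions
  mic <- classification_metrics(cc, "micro")
  expect_equal(mic$accuracy, mean(pred == truth))

  # binary symmetric confusion: precision = recall = F1
  sym <- manual_confusion_counts(c(7, 5), c(3, 5), c(5, 3), c(5, 7),
                                 class = c("pos", "neg"))
  ms <- classification_metrics(sym, "micro")
  expect_equal(ms$precision, ms$recall)
  expect_equal(ms$f1, ms$precision)
})

test_that("the linear classifier kind and custom classifiers plug in", {
  dd <- gen_diel_dataset(diel_dataset_spec(n_species = 2, n_per_group = 3, seed = 13))
  ds <- build_feature_dataset(dd$recordings)
  ml <- train_two_layer(ds, "linear")
  pl <- predict_two_layer(ml, ds)
  expect_gte(mean(pl$species == ds$species), 0.9)

  # a trivial majority-vote classifier via the custom interface
  maj <- list(
    fit = function(X, y) names(which.max(table(y))),
    predict = function(model, X) rep(model, nrow(X))
  )
  mc <- train_two_layer(ds, maj)
  pc <- predict_two_layer(mc, ds)
  expect_length(pc$species, nrow(ds))
})
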
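# Compact U-Net stage: loss weighting, Dice, oracle path, training.

test_that("background loss weight defaults to half the foreground weight", {
  w <- lossWeights(trainConfig(foregroundWeight = 1),
                   c("background", "a", "b"))
  expect_equal(unname(w["background"]), 0.5)
  expect_equal(unname(w[c("a", "b")]), c(1, 1))
  w2 <- lossWeights(trainConfig(foregroundWeight = 2), c("background", "a"))
  expect_equal(unname(w2["background"]), 1)
  ## explicit background weight wins
  w3 <- lossWeights(trainConfig(backgroundWeight = 0.25),
                    c("background", "a"))
  expect_equal(unname(w3["background"]), 0.25)
  expect_error(trainConfig(learningRate = 0), "> 0")
})

test_that("dice follows its definition and conventions", {
  base <- coarsePhantom(1)$mask
  empty <- base
  lab <- voxelData(base); lab[] <- 0L; empty@data <- lab
  ## identical masks
  expect_equal(dice(base, base, "MT"), 1)
  ## both empty for a label
  expect_equal(dice(empty, empty, "MT"), 1)
  ## disjoint
  a <- empty; la <- voxelData(a); la[1:5, 1, 1] <- 1L; a@data <- la
  b <- empty; lb <- voxelData(b); lb[1:5, 2, 1] <- 1L; b@data <- lb
  expect_equal(dice(a, b, "MT"), 0)
  ## A = half of B, A subset of B -> 2/3
  hb <- empty; lh <- voxelData(hb); lh[1:10, 1, 1] <- 1L; hb@data <- lh
  ha <- empty; lha <- voxelData(ha); lha[1:5, 1, 1] <- 1L; ha@data <- lha
  expect_equal(dice(ha, hb, "MT"), 2 / 3)
  ## symmetry
  expect_equal(dice(ha, hb, "MT"), dice(hb, ha, "MT"))
  ## geometry mismatch
  other <- new("LabelMask", data = array(0L, c(4, 4, 4)),
               spacing = c(1, 1, 1), origin = c(0, 0, 0))
  expect_error(dice(base, other, "MT"), "geometry")
})

test_that("zero-epoch training still yields a usable model", {
  ph <- memo("unetPh",
             makePhantom(phantomSpec(spacing = c(0.6, 0.7, 0.6), seed = 1)))
  slices <- phantomSlices(ph, "cartilage", step = 4)
  model <- trainUnet(slices[1], trainConfig(epochs = 0, seed = 2))
  pred <- predictMask(model, ph$volume)
  expect_true(all(voxelData(pred) %in% cartLabels()))
  expect_identical(dim(voxelData(pred)), dim(voxelData(ph$volume)))
})

test_that("training inputs are validated", {
  expect_error(trainUnet(list()), "empty training set")
  bad <- list(list(image = matrix(0, 8, 8),
                   labels = matrix(99L, 8, 8)))
  expect_error(trainUnet(bad), "outside dictionary")
})

test_that("the oracle model returns the phantom's mask and checks protocol", {
  ph <- coarsePhantom(1)
  model <- oracleSegModel(ph$mask, "cartilage")
  pred <- predictMask(model, ph$volume)
  expect_identical(voxelData(pred), voxelData(ph$mask))
  wrong <- ph$volume
  wrong@protocol <- "coronal-FLASH"
  expect_error(predictMask(model, wrong), "protocol mismatch")
})

test_that("training reduces the loss and reaches Dice > 0.8 held out", {
  phs <- lapply(1:2, function(s)
    memo(paste0("unetTrain", s),
         makePhantom(phantomSpec(spacing = c(0.6, 0.7, 0.6), seed = s))))
  slices <- do.call(c, lapply(phs, phantomSlices, target = "cartilage",
                              step = 2))
  slices <- slices[seq_len(min(40, length(slices)))]
  cfg <- trainConfig(epochs = 14, seed = 1)
  model <- memo("unetModel", trainUnet(slices, cfg))
  h <- model@params$history
  expect_equal(length(h), 14)
  ## smoothed-window non-increase: late window below early window
  expect_lt(mean(tail(h, 3)), mean(head(h, 3)))
  ## reproducibility of parameters under the seed
  model2 <- trainUnet(slices[1:4], trainConfig(epochs = 1, seed = 1))
  model3 <- trainUnet(slices[1:4], trainConfig(epochs = 1, seed = 1))
  expect_identical(model2@params$W1, model3@params$W1)
  ## held-out phantom
  hold99 <- makePhantom(phantomSpec(spacing = c(0.6, 0.7, 0.6), seed = 99))
  pred <- predictMask(model, hold99$volume)
  for (p in platesAll())
    expect_gt(dice(pred, hold99$mask, p), 0.8)
})
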
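# Architecture contracts: shapes, parameter counts, weight sharing and
# forward-pass properties. Width knobs are kept small here; the
# architectures' topologies are identical at any width.

small_spec <- function(name, C) {
  model_spec(name, in_channels = C, width = 8L, lstm_hidden = 8L,
             encoder_filters = c(4L, 8L, 16L), encoder_kernels = c(8L, 8L, 8L))
}

test_that("all models map every signal combination to 3 logits", {
  for (C in c(1L, 3L, 5L)) {
    segs <- random_segments(2, C, seed = C)
    for (name in c("stressnext", "lrcn")) {
      m <- build_model(small_spec(name, C), seed = 1)
      lg <- predict(m, segs, type = "logits")
      expect_equal(dim(lg), c(2, 3))
      expect_true(all(is.finite(lg)))
    }
    b <- build_sscnn(small_spec("sscnn", C), seed = 1)
    expect_equal(dim(predict(b$classifier, segs, type = "logits")), c(2, 3))
    expect_equal(dim(predict(b$pretext, segs, type = "logits")), c(2, 6))
  }
})

test_that("model_spec validates channel and class counts", {
  expect_error(model_spec("lrcn", in_channels = 0), "in_channels")
  expect_error(model_spec("lrcn", n_classes = 4), "n_classes")
  expect_error(model_spec("sscnn", encoder_filters = c(64, 32, 128)),
               "increasing")
})

test_that("multi-kernel addition is cheaper than concatenation would be", {
  # combining branch outputs by addition keeps the block width W; the
  # parameter count oracle distinguishes this from concatenation, which
  # would multiply the next block's input width by the branch count.
  W <- 8L
  m <- build_stressnext(model_spec("stressnext", in_channels = 1, width = W),
                        seed = 1)
  count_conv_params <- function(Cin, Cout, k) k * Cin * Cout + Cout
  expected <- count_conv_params(1, W, 1) + 2 * W +       # 1x1 projection + BN
    4 * (sum(vapply(c(1, 3, 5, 7), function(k)
      count_conv_params(W, W, k), 0)) + 2 * W) +         # 4 additive blocks + BN
    (W * 3 + 3)                                          # dense head
  expect_equal(n_params(m), expected)
  # under concatenation block 2+ would see 4W input channels instead
  concat_expected <- count_conv_params(1, W, 1) + 2 * W +
    (sum(vapply(c(1, 3, 5, 7), function(k) count_conv_params(W, W, k), 0)) + 2 * W) +
    3 * (sum(vapply(c(1, 3, 5, 7), function(k) count_conv_params(4 * W, W, k), 0)) + 2 * W) +
    (W * 3 + 3)
  expect_true(n_params(m) < concat_expected)
})

test_that("parallel multi-kernel branches share one output shape before addition", {
  ns <- asNamespace("stresswear")
  mk <- ns$nn_multikernel(4L)
  convs <- mk$children[1:4]
  t <- ns$segments_to_tensor(random_segments(2, 4, len = 64, seed = 2))
  outs <- lapply(convs, function(cv) cv$fwd(t))
  dims <- vapply(outs, function(o) c(o$L, ncol(o$x)), numeric(2))
  expect_true(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]))
})

test_that("a residual block with zeroed convolutions is the identity (after ReLU)", {
  ns <- asNamespace("stresswear")
  rb <- ns$nn_residual(3L, 3L)
  for (ly in ns$flatten_layers(list(rb))) {
    for (nm in names(ly$params)) ly$params[[nm]] <- 0 * ly$params[[nm]]
  }
  x <- abs(random_segments(1, 3, len = 128, seed = 4))  # non-negative input
  t <- ns$segments_to_tensor(x)
  out <- rb$fwd(t)
  expect_equal(out$x, t$x, tolerance = 1e-12)
})

test_that("LSTM input width is set by conv width, not input channel count", {
  m1 <- build_lrcn(small_spec("lrcn", 1), seed = 1)
  m5 <- build_lrcn(small_spec("lrcn", 5), seed = 1)
  lstm_in <- function(m) {
    ly <- Filter(function(l) grepl("^lstm", l$type), m$layers)[[1]]
    nrow(ly$params$Wx)
  }
  expect_equal(lstm_in(m1), lstm_in(m5))
})

test_that("encoder feature shapes follow the conv/pool arithmetic", {
  enc <- build_sscnn_encoder(model_spec("sscnn", in_channels = 1), seed = 1)
  shapes <- attr(enc, "shapes")
  # oracle: valid conv L - k + 1 twice, then pool (L - 8) %/% 2 + 1
  L <- 2560
  expected <- list(c(L, 1))
  ks <- c(32, 16, 8); fl <- c(32, 64, 128); pads <- c("valid", "valid", "same")
  for (b in 1:3) {
    if (pads[b] == "valid") L <- L - 2 * (ks[b] - 1)
    L <- (L - 8) %/% 2 + 1
    expected <- c(expected, list(c(L, fl[b])))
  }
  expect_equal(shapes, expected)
  # the published intermediate width appears after block 2 under this
  # arithmetic: 605 time steps
  expect_equal(shapes[[3]][1], 605)
  # real forward pass agrees with the recorded arithmetic
  ns <- asNamespace("stresswear")
  t <- ns$net_forward(unclass(enc), ns$segments_to_tensor(
    random_segments(1, 1, seed = 6)))
  expect_equal(c(t$L, ncol(t$x)), shapes[[4]])
})

test_that("the embedding after global max pooling has 128 features", {
  enc <- build_sscnn_encoder(model_spec("sscnn", in_channels = 1), seed = 1)
  emb <- encoder_embedding(enc, random_segments(3, 1, seed = 7))
  expect_equal(dim(emb), c(3, 128))
})

test_that("pretext and classifier heads share the encoder by reference", {
  b <- build_sscnn(small_spec("sscnn", 1), seed = 2)
  segs <- random_segments(2, 1, seed = 8)
  before <- predict(b$classifier, segs, type = "logits")
  # hash of encoder weights seen from both heads is identical
  enc_layers <- asNamespace("stresswear")$flatten_layers(unclass(b$encoder))
  w_before <- lapply(enc_layers, function(l) l$params)
  # mutate encoder weights "via the pretext model" (same environments)
  first_conv <- Filter(function(l) length(l$params) > 0,
                       asNamespace("stresswear")$flatten_layers(b$pretext$layers))[[1]]
  first_conv$params$W <- first_conv$params$W + 0.5
  after <- predict(b$classifier, segs, type = "logits")
  expect_false(isTRUE(all.equal(before, after)))
})

test_that("forward pass is batch-order equivariant and rejects bad input", {
  m <- build_model(small_spec("stressnext", 2), seed = 3)
  segs <- random_segments(7, 2, seed = 9)
  lg <- predict(m, segs, type = "logits")
  expect_equal(nrow(lg), 7)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  expect_equal(predict(m, segs[perm, , , drop = FALSE], type = "logits"),
               lg[perm, ], tolerance = 1e-12)
  # zero input gives finite logits
  expect_true(all(is.finite(predict(m, array(0, dim = c(2, 2, 2560)),
                                    type = "logits"))))
  bad <- segs[1:2, , , drop = FALSE]
  bad[1, 1, 5] <- NaN
  expect_error(predict(m, bad), "non-finite")
  expect_error(predict(m, random_segments(2, 3, seed = 1)), "channels")
})

test_that("probabilities normalize and classes break ties to the lowest index", {
  m <- build_model(small_spec("lrcn", 1), seed = 4)
  segs <- random_segments(3, 1, seed = 10)
  pr <- predict(m, segs, type = "prob")
  expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-12)
  cls <- predict(m, segs, type = "class")
  expect_true(all(cls %in% 0:2))
  expect_equal(cls, max.col(predict(m, segs, type = "logits"),
                            ties.method = "first") - 1L)
})
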
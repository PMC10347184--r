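# The three stress-classification architectures, built as layer graphs over
# [channels x 2560] segments at 256 Hz.

#' Model specification
#'
#' Collects the architecture name, input channel count and the width knobs
#' of the three models. Channel counts follow the signal combinations:
#' 1 (ECG or EEG), 3 (PPG), 4 (PPG+ECG or PPG+EEG or ECG+EEG is 2 — any
#' value >= 1 is accepted), 5 (all three).
#'
#' @param model_name One of `"stressnext"`, `"lrcn"`, `"sscnn"`.
#' @param in_channels Number of input channels (>= 1).
#' @param n_classes Number of stress classes (3).
#' @param width Convolutional width of StressNeXt branches / LRCN convs.
#' @param lstm_hidden LSTM hidden size (LRCN).
#' @param encoder_filters,encoder_kernels Per-block filter counts and
#'   kernel sizes of the self-supervised encoder (3 blocks, filters
#'   strictly increasing). Defaults: 32/64/128 filters with kernels
#'   32/16/8, two convolutions per block, max pooling size 8 stride 2.
#' @param pretext_classes Number of pretext labels (6: original + 5
#'   transformations).
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("lrcn", in_channels = 1)
model_spec <- function(model_name = c("stressnext", "lrcn", "sscnn"),
                       in_channels = 1L,
                       n_classes = 3L,
                       width = 64L,
                       lstm_hidden = 128L,
                       encoder_filters = c(32L, 64L, 128L),
                       encoder_kernels = c(32L, 16L, 8L),
                       pretext_classes = 6L) {
  model_name <- match.arg(model_name)
  assert_that(is_count(in_channels), "in_channels must be >= 1")
  assert_that(n_classes == 3L, "n_classes must be 3")
  assert_that(length(encoder_filters) == 3 && all(diff(encoder_filters) > 0),
              "encoder needs exactly 3 blocks with strictly increasing filters")
  assert_that(length(encoder_kernels) == 3, "encoder needs 3 kernel sizes")
  structure(list(model_name = model_name,
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 width = as.integer(width),
                 lstm_hidden = as.integer(lstm_hidden),
                 encoder_filters = as.integer(encoder_filters),
                 encoder_kernels = as.integer(encoder_kernels),
                 pretext_classes = as.integer(pretext_classes)),
            class = "model_spec")
}

new_stress_model <- function(layers, spec, name, n_out) {
  structure(list(layers = layers, spec = spec, name = name, n_out = n_out),
            class = "stress_model")
}

#' Build the multi-kernel residual network (StressNeXt)
#'
#' A 1x1 convolutional projection first reduces the parameter count, then
#' four consecutive multi-kernel blocks process the sequence: each block
#' runs parallel convolutions with kernel sizes 1, 3, 5 and 7 over the same
#' input and combines their feature maps by elementwise addition (not
#' concatenation), followed by batch normalization, ReLU and stride-2
#' temporal downsampling. Global average pooling and a dense layer produce
#' the 3 class logits.
#'
#' @param spec A [model_spec()].
#' @param seed Seed for weight initialization.
#' @return A `stress_model`.
#' @export
build_stressnext <- function(spec = model_spec("stressnext"), seed = 1L) {
  with_seed(derive_seed(seed, "stressnext"), {
    W <- spec$width
    layers <- c(
      list(nn_conv1d(spec$in_channels, W, 1L), nn_bn1d(W), nn_relu()),
      lapply(1:4, function(i) nn_multikernel(W)),
      list(nn_global_avgpool(), nn_dense(W, spec$n_classes)))
    new_stress_model(layers, spec, "stressnext", spec$n_classes)
  })
}

#' Build the convolutional-recurrent network (LRCN)
#'
#' Two 1-D convolutional layers and a max pooling layer reduce computation,
#' two residual blocks (each two same-length convolutions with an identity
#' skip, ReLU activations) separated by max pooling layers refine the
#' features, and two stacked LSTM layers extract time-domain structure; the
#' final hidden state feeds a dense layer emitting 3 logits. This is the
#' 1-D baseline of the attention-LRCN family, without the attention module
#' and without STFT inputs.
#'
#' @inheritParams build_stressnext
#' @return A `stress_model`.
#' @export
build_lrcn <- function(spec = model_spec("lrcn"), seed = 1L) {
  with_seed(derive_seed(seed, "lrcn"), {
    W <- spec$width; H <- spec$lstm_hidden
    layers <- list(
      nn_conv1d(spec$in_channels, W, 7L, pad = "same"), nn_relu(),
      nn_conv1d(W, W, 7L, pad = "same"), nn_relu(),
      nn_maxpool1d(2L),
      nn_residual(W, 3L),
      nn_maxpool1d(2L),
      nn_residual(W, 3L),
      nn_maxpool1d(2L),
      nn_lstm(W, H),
      nn_lstm(H, H),
      nn_take_last(),
      nn_dense(H, spec$n_classes))
    new_stress_model(layers, spec, "lrcn", spec$n_classes)
  })
}

#' Build the self-supervised CNN encoder
#'
#' Three convolutional blocks of two 1-D convolutions each, followed by max
#' pooling of size 8 with stride 2: block 1 has 32 filters of size 32,
#' block 2 has 64 filters of size 16, block 3 has 128 filters of size 8.
#' Convolutions are unpadded in blocks 1-2 and same-length in block 3; the
#' resulting feature-map shape is computed from this arithmetic and
#' recorded in the `shapes` attribute. Global max pooling over the final
#' feature maps yields the 128-feature embedding.
#'
#' @param spec A [model_spec()] (its `encoder_filters` / `encoder_kernels`
#'   fields are used).
#' @param seed Seed for weight initialization.
#' @param input_len Segment length used to record the per-block output
#'   lengths.
#' @return A list of layers with class `sscnn_encoder`; attribute `shapes`
#'   holds the layer-by-layer (length, channels) map.
#' @export
build_sscnn_encoder <- function(spec = model_spec("sscnn"), seed = 1L,
                                input_len = 2560L) {
  with_seed(derive_seed(seed, "sscnn_enc"), {
    fl <- spec$encoder_filters
    kn <- spec$encoder_kernels
    in_ch <- c(spec$in_channels, fl[1], fl[2])
    pads <- c("valid", "valid", "same")
    layers <- list()
    L <- input_len
    shapes <- list(c(L, spec$in_channels))
    for (b in 1:3) {
      conv_out <- function(L, k) if (pads[b] == "same") L else L - k + 1L
      layers <- c(layers, list(
        nn_conv1d(in_ch[b], fl[b], kn[b], pad = pads[b]), nn_relu(),
        nn_conv1d(fl[b], fl[b], kn[b], pad = pads[b]), nn_relu(),
        nn_maxpool1d(8L, 2L)))
      L <- conv_out(conv_out(L, kn[b]), kn[b])
      L <- (L - 8L) %/% 2L + 1L
      shapes <- c(shapes, list(c(L, fl[b])))
    }
    structure(layers, class = "sscnn_encoder", shapes = shapes,
              embedding_dim = fl[3])
  })
}

#' Build the self-supervised CNN (shared encoder + two heads)
#'
#' Returns the pretext model (encoder + global max pooling + dense layer
#' emitting 6 pretext logits) and the classifier (the *same* encoder, by
#' reference, + global max pooling + dense layer emitting 3 class logits).
#' Because the encoder layers are shared by reference, pretext pretraining
#' updates are immediately visible to the classifier.
#'
#' @inheritParams build_stressnext
#' @param encoder Optionally a pre-built [build_sscnn_encoder()] to reuse.
#' @return A list of class `sscnn` with elements `encoder`, `pretext`
#'   (a `stress_model` with 6 outputs) and `classifier` (a `stress_model`
#'   with 3 outputs).
#' @export
build_sscnn <- function(spec = model_spec("sscnn"), seed = 1L, encoder = NULL) {
  if (is.null(encoder)) {
    encoder <- build_sscnn_encoder(spec, seed)
  } else {
    assert_that(inherits(encoder, "sscnn_encoder"),
                "encoder must come from build_sscnn_encoder()")
  }
  emb <- attr(encoder, "embedding_dim")
  with_seed(derive_seed(seed, "sscnn_heads"), {
    pretext <- new_stress_model(
      c(unclass(encoder), list(nn_global_maxpool(), nn_dense(emb, spec$pretext_classes))),
      spec, "sscnn_pretext", spec$pretext_classes)
    classifier <- new_stress_model(
      c(unclass(encoder), list(nn_global_maxpool(), nn_dense(emb, spec$n_classes))),
      spec, "sscnn", spec$n_classes)
  })
  structure(list(encoder = encoder, pretext = pretext, classifier = classifier,
                 spec = spec),
            class = "sscnn")
}

#' Encoder embedding of segments
#'
#' Runs segments through a [build_sscnn_encoder()] and applies global max
#' pooling, returning one embedding vector per segment.
#'
#' @param encoder An `sscnn_encoder`.
#' @param segments `[n x C x len]` array (or `segment_set`).
#' @return `[n x embedding_dim]` matrix.
#' @export
encoder_embedding <- function(encoder, segments) {
  if (inherits(segments, "segment_set")) segments <- segments$segments
  t <- net_forward(unclass(encoder), segments_to_tensor(segments), train = FALSE)
  gmp <- nn_global_maxpool()
  gmp$fwd(t, train = FALSE)$x
}

#' Build a model from its specification
#'
#' @param spec A [model_spec()].
#' @param seed Seed for weight initialization.
#' @return A `stress_model` (or an `sscnn` bundle for `model_name =
#'   "sscnn"`).
#' @export
build_model <- function(spec, seed = 1L) {
  switch(spec$model_name,
         stressnext = build_stressnext(spec, seed),
         lrcn = build_lrcn(spec, seed),
         sscnn = build_sscnn(spec, seed))
}

#' Number of trainable parameters
#'
#' @param model A `stress_model`, `sscnn` bundle or `sscnn_encoder`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  layers <- if (inherits(model, "stress_model")) model$layers
            else if (inherits(model, "sscnn")) model$classifier$layers
            else if (inherits(model, "sscnn_encoder")) unclass(model)
            else rlang::abort("unsupported model object")
  as.integer(net_n_params(layers))
}

#' Extract or restore model weights
#'
#' Weights are returned as a plain list of per-layer parameter lists, the
#' package's checkpoint format (serialize with [saveRDS()] if needed).
#' `set_model_weights()` writes a compatible snapshot back into a model of
#' identical architecture.
#'
#' @param model A `stress_model`, `sscnn` bundle or `sscnn_encoder`.
#' @param weights A snapshot from `model_weights()`.
#' @return `model_weights()`: the snapshot list; `set_model_weights()`:
#'   the model, invisibly (layers are environments, so the update is in
#'   place).
#' @export
model_weights <- function(model) {
  layers <- model_layer_list(model)
  lapply(flatten_layers(layers), function(ly) ly$params)
}

#' @rdname model_weights
#' @export
set_model_weights <- function(model, weights) {
  layers <- flatten_layers(model_layer_list(model))
  assert_that(length(layers) == length(weights),
              "weight snapshot does not match the model's layer structure")
  for (i in seq_along(layers)) {
    assert_that(identical(lapply(layers[[i]]$params, dim),
                          lapply(weights[[i]], dim)),
                sprintf("layer %d parameter shapes differ", i))
    layers[[i]]$params <- weights[[i]]
  }
  invisible(model)
}

model_layer_list <- function(model) {
  if (inherits(model, "stress_model")) model$layers
  else if (inherits(model, "sscnn")) model$classifier$layers
  else if (inherits(model, "sscnn_encoder")) unclass(model)
  else rlang::abort("unsupported model object")
}

#' Forward pass: predict classes, probabilities or logits
#'
#' @param object A `stress_model`.
#' @param segments `[n x C x len]` array of segments (or a `segment_set`).
#' @param type `"class"` (default; argmax with ties broken towards the
#'   lowest class index), `"prob"` or `"logits"`.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Class labels (0-based integers), probability matrix or logit
#'   matrix with `n` rows.
#' @export
predict.stress_model <- function(object, segments, type = c("class", "prob", "logits"),
                                 batch_size = 64L, ...) {
  type <- match.arg(type)
  if (inherits(segments, "segment_set")) segments <- segments$segments
  if (length(dim(segments)) == 2) {
    segments <- array(segments, dim = c(1, dim(segments)))
  }
  d <- dim(segments)
  assert_that(d[2] == object$spec$in_channels,
              sprintf("model expects %d channels, got %d",
                      object$spec$in_channels, d[2]))
  if (anyNA(segments) || any(!is.finite(segments))) {
    rlang::abort("non-finite values in input segments")
  }
  out <- matrix(NA_real_, d[1], object$n_out)
  for (start in seq(1, d[1], by = batch_size)) {
    idx <- start:min(start + batch_size - 1, d[1])
    t <- segments_to_tensor(segments[idx, , , drop = FALSE])
    out[idx, ] <- net_forward(object$layers, t, train = FALSE)$x
  }
  switch(type,
         logits = out,
         prob = {
           z <- out - apply(out, 1, max)
           ez <- exp(z)
           ez / rowSums(ez)
         },
         class = max.col(out, ties.method = "first") - 1L)
}

#' @export
print.stress_model <- function(x, ...) {
  cat("<stress_model> ", x$name, ": ", x$spec$in_channels, " channel(s) -> ",
      x$n_out, " logits, ", format(n_params(x), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

#' @export
print.sscnn <- function(x, ...) {
  shp <- attr(x$encoder, "shapes")
  last <- shp[[length(shp)]]
  cat("<sscnn> shared 3-block encoder (feature maps ", last[2], " x ", last[1],
      "), pretext head 6 logits, classifier head 3 logits\n", sep = "")
  invisible(x)
}
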
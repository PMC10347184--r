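# Self-supervised pretext transformations. Applied to segmented, normalized
# windows; the pretext task is to recognize which transformation (if any)
# produced an input.

#' Pretext transformation parameters
#'
#' Defaults follow the pretraining protocol: additive Gaussian noise with
#' mean 0 and standard deviation 0.01, amplitude scaling by 1.1, and
#' permutation of 20 randomly placed non-overlapping pieces of length one
#' quarter of the working sampling rate (64 samples at 256 Hz).
#'
#' @param noise_mu,noise_sigma Gaussian noise parameters.
#' @param scale_factor Amplitude scaling factor (non-zero).
#' @param permute_pieces Number of pieces swapped by [permute_segment()].
#' @param piece_len Piece length in samples (defaults to `rate / 4`).
#' @param rate Working sampling rate in Hz.
#' @param derange If `TRUE` (default) the permutation is a derangement: no
#'   selected piece keeps its original position.
#' @return An object of class `transform_spec`.
#' @export
#' @examples
#' transform_spec()
transform_spec <- function(noise_mu = 0, noise_sigma = 0.01,
                           scale_factor = 1.1, permute_pieces = 20L,
                           piece_len = NULL, rate = 256, derange = TRUE) {
  piece_len <- piece_len %||% as.integer(rate / 4)
  assert_that(is_number(noise_sigma) && noise_sigma > 0, "noise_sigma must be > 0")
  assert_that(is_number(scale_factor) && scale_factor != 0,
              "scale_factor must be non-zero")
  assert_that(is_count(permute_pieces) && is_count(piece_len),
              "permute_pieces and piece_len must be positive integers")
  structure(list(noise_mu = noise_mu, noise_sigma = noise_sigma,
                 scale_factor = scale_factor,
                 permute_pieces = as.integer(permute_pieces),
                 piece_len = as.integer(piece_len),
                 derange = isTRUE(derange)),
            class = "transform_spec")
}

as_seg_matrix <- function(segment) {
  if (is.null(dim(segment))) matrix(segment, nrow = 1) else as.matrix(segment)
}

restore_shape <- function(out, segment) {
  if (is.null(dim(segment))) drop(out) else out
}

#' Pretext transformations of a segment
#'
#' Operate on one segment (a `[channels x len]` matrix or a plain vector):
#' `add_noise()` adds i.i.d. Gaussian noise, `scale_segment()` multiplies
#' by the scale factor, `negate_segment()` flips the sign,
#' `hflip_segment()` reverses time, and [permute_segment()] swaps random
#' pieces. All preserve the segment's shape.
#'
#' @param segment Numeric vector or `[channels x len]` matrix.
#' @param spec A [transform_spec()].
#' @param seed RNG seed for the stochastic transformations.
#' @return Transformed segment, same shape.
#' @export
#' @examples
#' x <- sin(seq(0, 10, length.out = 2560))
#' all.equal(negate_segment(negate_segment(x)), x)
add_noise <- function(segment, spec = transform_spec(), seed = 1L) {
  m <- as_seg_matrix(segment)
  out <- with_seed(derive_seed(seed, "noise"), {
    m + matrix(rnorm(length(m), spec$noise_mu, spec$noise_sigma),
               nrow(m), ncol(m))
  })
  restore_shape(out, segment)
}

#' @rdname add_noise
#' @export
scale_segment <- function(segment, spec = transform_spec()) {
  segment * spec$scale_factor
}

#' @rdname add_noise
#' @export
negate_segment <- function(segment) {
  -segment
}

#' @rdname add_noise
#' @export
hflip_segment <- function(segment) {
  m <- as_seg_matrix(segment)
  restore_shape(m[, rev(seq_len(ncol(m))), drop = FALSE], segment)
}

# Sample `pieces` non-overlapping piece start positions, uniform over all
# valid (sorted) placements: draw ordered anchors in the compacted space and
# re-expand by the piece length (stars-and-bars construction; rejection
# sampling is hopeless here because the pieces cover half the segment).
sample_piece_starts <- function(len, pieces, plen) {
  anchors <- sort(sample.int(len - pieces * plen + pieces, pieces))
  anchors + (seq_len(pieces) - 1L) * (plen - 1L)
}

# Permutation of 1..n without fixed points (rejection sampling).
sample_derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Piece-permutation transform
#'
#' Randomly selects `permute_pieces` non-overlapping pieces of `piece_len`
#' samples and swaps their contents (by default through a derangement, so
#' every selected piece moves). Samples outside the selected pieces are
#' untouched and the multiset of sample values is conserved per channel.
#' The same piece positions are used for every channel of the segment.
#'
#' @inheritParams add_noise
#' @export
permute_segment <- function(segment, spec = transform_spec(), seed = 1L) {
  m <- as_seg_matrix(segment)
  len <- ncol(m)
  need <- spec$permute_pieces * spec$piece_len
  if (len < need) {
    rlang::abort(sprintf(
      "segment of %d samples too short for %d pieces of %d samples",
      len, spec$permute_pieces, spec$piece_len))
  }
  with_seed(derive_seed(seed, "permute"), {
    starts <- sample_piece_starts(len, spec$permute_pieces, spec$piece_len)
    perm <- if (spec$derange) sample_derangement(spec$permute_pieces)
            else sample.int(spec$permute_pieces)
    out <- m
    for (i in seq_along(starts)) {
      dst <- starts[i] + seq_len(spec$piece_len) - 1L
      src <- starts[perm[i]] + seq_len(spec$piece_len) - 1L
      out[, dst] <- m[, src, drop = FALSE]
    }
    attr(out, "piece_starts") <- starts
    attr(out, "piece_perm") <- perm
    restore_shape(out, segment)
  })
}

pretext_label_names <- c("original", "noised", "scaled", "negated",
                         "flipped", "permuted")

#' Assemble a labeled pretext batch
#'
#' Every source segment contributes six pretext examples: itself (label 0)
#' and one copy per transformation (1 = noised, 2 = scaled, 3 = negated,
#' 4 = flipped, 5 = permuted). The batch is shuffled deterministically and
#' is exactly class-balanced across the six pretext labels.
#'
#' @param segments Array `[n x C x len]` (e.g. `segment_set$segments`) or a
#'   `segment_set`.
#' @param spec A [transform_spec()].
#' @param seed RNG seed controlling noise, permutations and shuffling.
#' @return An object of class `pretext_batch`: list with `inputs`
#'   (`[6n x C x len]` array) and `labels` (integers 0-5).
#' @export
#' @examples
#' segs <- array(rnorm(2 * 1 * 2560), dim = c(2, 1, 2560))
#' batch <- make_pretext_batch(segs, seed = 1)
#' table(batch$labels)
make_pretext_batch <- function(segments, spec = transform_spec(), seed = 1L) {
  if (inherits(segments, "segment_set")) segments <- segments$segments
  d <- dim(segments)
  assert_that(length(d) == 3 && d[1] > 0, "segments must be a non-empty [n x C x len] array")
  n <- d[1]
  out <- array(NA_real_, dim = c(6L * n, d[2], d[3]))
  labels <- integer(6L * n)
  for (i in seq_len(n)) {
    seg <- array(segments[i, , ], dim = d[2:3])
    sd_i <- derive_seed(seed, "pretext", i)
    variants <- list(seg,
                     add_noise(seg, spec, seed = sd_i),
                     scale_segment(seg, spec),
                     negate_segment(seg),
                     hflip_segment(seg),
                     permute_segment(seg, spec, seed = sd_i))
    for (v in 0:5) {
      r <- (i - 1L) * 6L + v + 1L
      out[r, , ] <- variants[[v + 1L]]
      labels[r] <- v
    }
  }
  ord <- with_seed(derive_seed(seed, "shuffle"), sample.int(6L * n))
  structure(list(inputs = out[ord, , , drop = FALSE],
                 labels = labels[ord],
                 label_names = pretext_label_names),
            class = "pretext_batch")
}

#' @export
print.pretext_batch <- function(x, ...) {
  d <- dim(x$inputs)
  cat("<pretext_batch> ", d[1], " examples x ", d[2], " channels x ", d[3],
      " samples; labels 0-5 (", paste(x$label_names, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
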
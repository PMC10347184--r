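# Internal helpers shared across modules.

# Deterministic child-seed derivation: every stage / session draws its own
# seed from the one user-supplied seed, so single sessions are regenerable
# in isolation. Kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tags)) h <- (h * 131 + ch) %% 2147483647L
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)
is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
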
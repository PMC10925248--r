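# Internal helpers shared across modules.

# image accessors: images are integer matrices [y+1, x+1], 0-based coords
img_height <- function(image) nrow(image)
img_width <- function(image) ncol(image)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# FNV-1a 32-bit hash of a character scalar; used to fingerprint settings in
# data-file headers without a digest dependency.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)  # b < 256: xor touches low byte only
    # 32-bit modular multiply via 16-bit split (doubles stay exact)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * m + ((h1 * m) %% 65536) * 65536) %% 4294967296
  }
  h1 <- h %/% 65536
  sprintf("%04x%04x", h1, h %% 65536)
}

# deterministic per-purpose seed derived from a base seed; stays < 2^31
derive_seed <- function(seed, salt) {
  (as.numeric(seed) * 7919 + salt * 104729) %% 2147483647
}

# format numbers for text files: NaN/NA -> "NaN", full precision otherwise
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NaN" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}
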
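# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a base seed and a stream index,
# so that independent stages (anatomy, noise, misalignment, ...) never share
# a RNG stream.
sub_seed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + as.double(stream) * 30269) %% 2147483629
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Voxel-count bookkeeping used throughout: logical array -> integer count.
mask_count <- function(mask) sum(mask)

# 1-based integer voxel indices (n x 3) of TRUE voxels of a logical array.
mask_indices <- function(mask) {
  which(mask, arr.ind = TRUE)
}
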
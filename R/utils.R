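# Bitmask helpers for subcommunity identifiers. A subcommunity of an
# S-species pool is encoded as an integer bitmask (bit i-1 set <=> species i
# present, 1-based species indices). S <= 16 keeps masks well inside the
# 32-bit integer range.

mask_from_members <- function(members) {
  if (length(members) == 0L) return(0L)
  sum(bitwShiftL(1L, as.integer(members) - 1L))
}

members_from_mask <- function(mask, S) {
  which(bitwAnd(bitwShiftR(mask, 0:(S - 1L)), 1L) == 1L)
}

mask_size <- function(mask, S) {
  length(members_from_mask(mask, S))
}

mask_label <- function(mask, names, S) {
  m <- members_from_mask(mask, S)
  if (length(m) == 0L) return("{}")
  paste0("{", paste(names[m], collapse = ","), "}")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream-specific seed from a global seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629) + 1L
}
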
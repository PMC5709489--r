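# Internal helpers shared across modules.

# Nucleotide coding: A=1, C=2, G=3, T=4; anything else (N, -, ambiguity
# codes) is NA and is dropped pairwise in distance calculations.
BASES <- c("A", "C", "G", "T")

# 256-entry lookup from raw byte to base code (upper and lower case).
.byte_code <- local({
  m <- rep(NA_integer_, 256L)
  m[utf8ToInt("A") + 1L] <- 1L; m[utf8ToInt("a") + 1L] <- 1L
  m[utf8ToInt("C") + 1L] <- 2L; m[utf8ToInt("c") + 1L] <- 2L
  m[utf8ToInt("G") + 1L] <- 3L; m[utf8ToInt("g") + 1L] <- 3L
  m[utf8ToInt("T") + 1L] <- 4L; m[utf8ToInt("t") + 1L] <- 4L
  m
})

encode_seq <- function(s) {
  .byte_code[as.integer(charToRaw(s)) + 1L]
}

decode_codes <- function(x) {
  ch <- BASES[x]
  ch[is.na(x)] <- "N"
  paste(ch, collapse = "")
}

ind_key <- function(species, individual) paste(species, individual, sep = "|")

split_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  tibble::tibble(
    key = key,
    species = vapply(parts, `[`, "", 1L),
    individual = vapply(parts, function(p) paste(p[-1L], collapse = "|"), "")
  )
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL uses the current stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Deterministic child-seed derivation so one top-level seed fans out to
# independent per-component streams (kept below 2^31).
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
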
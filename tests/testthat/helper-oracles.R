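# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most literal route available (double loops, exhaustive
# search) so they stay independent of the implementation they check.

# Pairwise Mann-Whitney AUC with half-credit for ties, by explicit
# enumeration of every (positive, negative) pair.
brute_force_auc <- function(pos, neg) {
  wins <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(wins) / (length(pos) * length(neg))
}

# Exhaustive search over a coefficient grid for the 2-predictor linear
# combination, with the stated tie rule (smallest |b|, then grid order).
brute_force_combination <- function(c1, c2, labels, grid) {
  ord <- order(abs(grid), seq_along(grid))
  best <- NULL
  for (b in grid[ord]) {
    s <- c1 + b * c2
    a <- brute_force_auc(s[labels == 1], s[labels == 0])
    if (is.null(best) || a > best$auc + 1e-12) best <- list(beta = b, auc = a)
  }
  best
}

# Exhaustive (T, P) search with the flag-count score and the stated tie rule
# (smaller P, then smaller T).
brute_force_threshold_rule <- function(prob, err, labels, t_mean, nt, np) {
  t_grid <- t_mean * seq_len(nt) / (nt + 1)
  p_grid <- 0.5 + 0.5 * seq_len(np) / (np + 1)
  best <- NULL
  for (p_thr in p_grid) for (t_thr in t_grid) {
    s <- as.integer(err > t_thr) + as.integer(prob > p_thr)
    a <- brute_force_auc(s[labels == 1], s[labels == 0])
    if (is.null(best) || a > best$auc + 1e-12) {
      best <- list(t = t_thr, p = p_thr, auc = a)
    }
  }
  best
}

# Brute-force Tomek-link cleaning on a feature matrix.
brute_force_tomek <- function(x, y) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  nn1 <- apply(d, 1, which.min)
  majority <- as.integer(names(which.max(table(y))))
  drop <- logical(n)
  for (i in seq_len(n)) {
    j <- nn1[i]
    if (y[i] != y[j] && nn1[j] == i) drop[if (y[i] == majority) i else j] <- TRUE
  }
  !drop
}

# Brute-force edited-nearest-neighbour cleaning (keep unless a strict
# majority of the k neighbours disagrees).
brute_force_enn <- function(x, y, k = 3) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  keep <- logical(n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    keep[i] <- sum(y[nb] != y[i]) <= k / 2
  }
  keep
}

# --- minimal hand-rolled PNG writer (grayscale, 8 or 16 bit) -------------
# Uses stored (uncompressed) deflate blocks inside a zlib stream plus CRC-32
# chunk checksums, which is all the PNG container requires; png::readPNG
# decodes it like any other PNG. Exists so bit-depth handling can be tested
# without any binary fixture on disk.

png_crc_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
      } else bitwShiftR(bitwAnd(c, -2L), 1)
      c <- bitwAnd(c, -1L)
    }
    tab[n + 1] <- c
  }
  tab
})

png_crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes)) {
    c <- bitwXor(png_crc_table[bitwAnd(bitwXor(c, b), 255L) + 1L],
                 bitwShiftR(bitwAnd(c, -256L), 8))
  }
  bitwXor(c, -1L)
}

int_to_bytes <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 2^8) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  payload <- c(charToRaw(type), data)
  crc <- png_crc32(payload)
  c(int_to_bytes(length(data)), payload, int_to_bytes(crc))
}

# Raw zlib stream with a single stored deflate block and Adler-32 trailer.
zlib_stored <- function(data) {
  len <- length(data)
  stopifnot(len < 65536)
  a <- 1; b <- 0
  for (v in as.integer(data)) {
    a <- (a + v) %% 65521
    b <- (b + a) %% 65521
  }
  c(as.raw(c(0x78, 0x01, 0x01)),
    as.raw(c(len %% 256, len %/% 256,
             bitwAnd(bitwNot(len %% 256), 255L),
             bitwAnd(bitwNot(len %/% 256), 255L))),
    data,
    int_to_bytes(b * 65536 + a))
}

write_gray_png <- function(values, path, bit_depth = 16) {
  h <- nrow(values); w <- ncol(values)  # integer sample values
  rows <- lapply(seq_len(h), function(r) {
    v <- as.integer(values[r, ])
    if (bit_depth == 16) {
      as.raw(c(0L, rbind(v %/% 256L, v %% 256L)))
    } else {
      as.raw(c(0L, v))
    }
  })
  idat <- zlib_stored(do.call(c, rows))
  ihdr <- c(int_to_bytes(w), int_to_bytes(h),
            as.raw(c(bit_depth, 0, 0, 0, 0)))
  bytes <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
             png_chunk("IHDR", ihdr),
             png_chunk("IDAT", idat),
             png_chunk("IEND", raw(0)))
  writeBin(bytes, path)
  invisible(path)
}

# Small shared phantom fixtures (built once per test run).
tiny_phantom_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom_dataset(
        phantom_config(image_size = 64, n_normal = 8, n_abnormal = 4,
                       seed = 42))
    }
    cache
  }
})
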
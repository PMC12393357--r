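# Internal helpers shared across modules.

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# px, py: point coordinates; vx, vy: polygon vertices (closed implicitly).
point_in_polygon <- function(px, py, vx, vy) {
  stopifnot(length(vx) == length(vy), length(vx) >= 3)
  inside <- rep(FALSE, length(px))
  n <- length(vx)
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; yj <- vy[j]
    xi <- vx[i]; xj <- vx[j]
    if (yi != yj) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

# Signed polygon area (shoelace); zero for degenerate polygons.
polygon_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  sum(vx[j] * vy - vx * vy[j]) / 2
}

# Translate a matrix by (dx, dy) pixels: content at (x, y) moves to
# (x + dx, y + dy); exposed regions take `fill`. x = column, y = row.
translate_matrix <- function(m, dx, dy, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- max(1, 1 - dy):min(h, h - dy)
  src_c <- max(1, 1 - dx):min(w, w - dx)
  if (length(src_r) > 0 && length(src_c) > 0 &&
      src_r[1] <= src_r[length(src_r)] && src_c[1] <= src_c[length(src_c)]) {
    out[src_r + dy, src_c + dx] <- m[src_r, src_c]
  }
  out
}

# Population standard deviation (divide by n, not n - 1).
pop_sd <- function(x) {
  mu <- mean(x)
  v <- mean(x * x) - mu * mu
  sqrt(max(v, 0))
}

# Reflect an out-of-range index into [1, n] (symmetric, edge repeated:
# ... c b a | a b c ... ), the padding used by gaussian_smooth.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# --- binary packing helpers -------------------------------------------------

u16_be <- function(x) as.raw(c(floor(x / 256) %% 256, x %% 256))
u32_be <- function(x) as.raw(c(floor(x / 16777216) %% 256, floor(x / 65536) %% 256,
                               floor(x / 256) %% 256, x %% 256))
u16_le <- function(x) as.raw(c(x %% 256, floor(x / 256) %% 256))
u32_le <- function(x) as.raw(c(x %% 256, floor(x / 256) %% 256,
                               floor(x / 65536) %% 256, floor(x / 16777216) %% 256))
be_u16 <- function(b) 256 * as.integer(b[1]) + as.integer(b[2])
be_u32 <- function(b) ((as.integer(b[1]) * 256 + as.integer(b[2])) * 256 +
                         as.integer(b[3])) * 256 + as.integer(b[4])

# --- CRC-32 (IEEE 802.3), needed for the stored-entry ZIP writer ------------

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) {
            bitwXor(-306674912L, bitwShiftR(c, 1))  # 0xEDB88320 as signed
          } else {
            bitwShiftR(c, 1)
          }
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

# CRC-32 of a raw vector, returned as a double in [0, 2^32).
crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints) {
    crc <- bitwXor(bitwShiftR(crc, 8), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  u <- as.numeric(crc)
  if (u < 0) u <- u + 2^32
  u
}

# Write a ZIP archive with stored (uncompressed) entries.
# entries: named list of raw vectors. Timestamps fixed so output is
# byte-stable for identical content.
write_stored_zip <- function(entries, path) {
  stopifnot(length(entries) > 0, !is.null(names(entries)))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  pos <- 0
  central <- list()
  for (i in seq_along(entries)) {
    nm <- names(entries)[i]
    data <- entries[[i]]
    nmraw <- charToRaw(nm)
    crc <- crc32(data)
    local_hdr <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)),
      u16_le(20), u16_le(0), u16_le(0),      # version, flags, method=stored
      u16_le(0), u16_le(33),                 # time, date (1980-01-01)
      u32_le(crc), u32_le(length(data)), u32_le(length(data)),
      u16_le(length(nmraw)), u16_le(0),
      nmraw
    )
    offsets[i] <- pos
    writeBin(local_hdr, con)
    writeBin(data, con)
    pos <- pos + length(local_hdr) + length(data)
    central[[i]] <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)),
      u16_le(20), u16_le(20), u16_le(0), u16_le(0),
      u16_le(0), u16_le(33),
      u32_le(crc), u32_le(length(data)), u32_le(length(data)),
      u16_le(length(nmraw)), u16_le(0), u16_le(0),
      u16_le(0), u16_le(0), u32_le(0),
      u32_le(offsets[i]),
      nmraw
    )
  }
  cd_start <- pos
  for (c_e in central) {
    writeBin(c_e, con)
    pos <- pos + length(c_e)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)),
    u16_le(0), u16_le(0),
    u16_le(length(entries)), u16_le(length(entries)),
    u32_le(pos - cd_start), u32_le(cd_start),
    u16_le(0)
  )
  writeBin(eocd, con)
  invisible(path)
}

# RFC 4180 field quoting for the CSV writers.
csv_quote <- function(x) {
  x <- as.character(x)
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
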
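# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Plain dynamic-programming Levenshtein distance.
levDP <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (x[i] != y[j]))
  d[n + 1, m + 1]
}

# Direct two-loop reference for the cross-cycle SD image.
sdTwoLoop <- function(px) {
  d <- dim(px)  # cycle, channel, row, col
  out <- matrix(0, d[3], d[4])
  for (r in seq_len(d[3])) for (cc in seq_len(d[4])) {
    s <- 0
    for (ch in 2:5) {
      v <- px[, ch, r, cc]
      s <- s + sqrt(mean((v - mean(v))^2))
    }
    out[r, cc] <- s / 4
  }
  out
}

# Cyclic roll of a matrix by (sy, sx).
rollMat <- function(m, sy, sx) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - sy) %% h) + 1, ((seq_len(w) - 1 - sx) %% w) + 1]
}

# Non-exclusive 2-px matching of called reads against ground-truth spots.
matchReadsToTruth <- function(reads, gt, max_px = 2) {
  if (!nrow(reads)) return(list(matched = 0, accuracy = NA_real_))
  d2 <- outer(reads$row, gt$row_px, "-")^2 +
    outer(reads$col, gt$col_px, "-")^2
  nn <- apply(d2, 1, which.min)
  ok <- sqrt(d2[cbind(seq_len(nrow(reads)), nn)]) <= max_px
  list(matched = mean(ok),
       accuracy = mean(reads$barcode[ok] == gt$barcode[nn[ok]]))
}

# Filled disk mask.
diskMask <- function(h, w, row, col, rad) {
  (outer(seq_len(h), rep(1, w)) - row)^2 +
    (outer(rep(1, h), seq_len(w)) - col)^2 <= rad^2
}

# Intensity list (as produced by extractIntensities) from a spot x cycle x 4
# array, for driving the calling stages directly.
asIntensities <- function(values, source = "raw") {
  list(values = values, clipped = rep(FALSE, dim(values)[1]), source = source)
}

# One-hot intensity tensor for the barcode strings given.
tensorFromBarcodes <- function(barcodes, amplitude = 100, mixing = diag(4)) {
  nc <- nchar(barcodes[1])
  v <- array(0, dim = c(length(barcodes), nc, 4))
  for (i in seq_along(barcodes)) for (cyc in seq_len(nc)) {
    b <- match(substr(barcodes[i], cyc, cyc), SBS_BASES)
    v[i, cyc, ] <- mixing[, b] * amplitude
  }
  v
}

# Independent enumeration oracle: U by pair counting, p by combn over labels.
mwOracle <- function(x, y) {
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  combs <- combn(length(pooled), length(x))
  Us <- apply(combs, 2, function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  p <- min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
  list(U = U, p = p)
}

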
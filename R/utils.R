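# small internal helpers shared across modules

# half-up rounding of a fraction to a percentage with one decimal,
# matching how assay performance figures are conventionally reported
# (round() would round half-even)
pctHalfUp <- function(frac) {
  if (is.na(frac)) return(NA_real_)
  floor(frac * 1000 + 0.5) / 10
}

# integer-pixel translation of a matrix; vacated pixels take `fill`
shiftMatrix <- function(m, dRow, dCol, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  srcR <- seq_len(nrow(m)) - dRow
  srcC <- seq_len(ncol(m)) - dCol
  okR <- srcR >= 1L & srcR <= nrow(m)
  okC <- srcC >= 1L & srcC <= ncol(m)
  out[okR, okC] <- m[srcR[okR], srcC[okC]]
  out
}

clamp01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

# numeric factor of a titer label such as "1:32" -> 32
titerStepFactor <- function(steps) {
  f <- suppressWarnings(as.numeric(sub("^1\\s*:\\s*", "", steps)))
  if (any(is.na(f)))
    stop("titer steps must look like '1:10'; got: ",
         paste(steps[is.na(f)], collapse = ", "))
  f
}

# highest titer level whose dilution factor is covered by `factor`
# (a positive reaction at 1:100 implies titer >= 1:100); 0 if below all
titerLevelForDilution <- function(factor, steps) {
  sum(titerStepFactor(steps) <= factor + 1e-9)
}

# area of the convex hull of a pixel set: shoelace area of the hull polygon
# through pixel centers. The mask pixel count uses the same lattice
# convention, so the ratio (solidity) is ~1 for convex masks.
convexHullArea <- function(rows, cols) {
  if (length(rows) < 3L) return(length(rows))
  h <- chull(cols, rows)
  x <- cols[h]; y <- rows[h]
  n <- length(h)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x * y[j] - x[j] * y)) / 2
}
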
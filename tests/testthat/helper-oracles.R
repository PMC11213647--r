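# Exhaustive-search reference implementation of the same gamma definition
bruteGamma <- function(ref, ev, sp, doseTol, dta, thrAbs, radius, step) {
  d <- dim(ref)
  offs <- expand.grid(dz = seq(-radius, radius, by = step),
                      dy = seq(-radius, radius, by = step),
                      dx = seq(-radius, radius, by = step))
  offs <- offs[sqrt(rowSums(offs^2)) <= radius + 1e-9, ]
  out <- array(NA_real_, d)
  tri <- function(fz, fy, fx) {
    if (fz < 0 || fy < 0 || fx < 0 || fz > d[1] - 1 || fy > d[2] - 1 ||
        fx > d[3] - 1) return(NA_real_)
    z0 <- min(floor(fz), d[1] - 2); y0 <- min(floor(fy), d[2] - 2)
    x0 <- min(floor(fx), d[3] - 2)
    wz <- fz - z0; wy <- fy - y0; wx <- fx - x0
    acc <- 0
    for (iz in 0:1) for (iy in 0:1) for (ix in 0:1)
      acc <- acc + ev[z0 + iz + 1, y0 + iy + 1, x0 + ix + 1] *
        (if (iz) wz else 1 - wz) * (if (iy) wy else 1 - wy) *
        (if (ix) wx else 1 - wx)
    acc
  }
  for (iz in 1:d[1]) for (iy in 1:d[2]) for (ix in 1:d[3]) {
    dr <- ref[iz, iy, ix]
    if (dr < thrAbs) next
    best <- Inf
    for (o in seq_len(nrow(offs))) {
      de <- tri(iz - 1 + offs$dz[o] / sp[1], iy - 1 + offs$dy[o] / sp[2],
                ix - 1 + offs$dx[o] / sp[3])
      if (is.na(de)) next
      g2 <- ((de - dr) / (doseTol * dr))^2 +
        (offs$dz[o]^2 + offs$dy[o]^2 + offs$dx[o]^2) / dta^2
      best <- min(best, g2)
    }
    out[iz, iy, ix] <- sqrt(best)
  }
  out
}
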
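# Shared fixture builders: curves sampled from explicit polylines and
# small gridded grayscale scenes, so expected values are known by
# construction.

# sample a polyline (d, f) on the standard 0.002 mm grid
polylineCurve <- function(d, f, dx = 0.002) {
  grid <- dx * (0:round(max(d) / dx))
  ForceDistanceCurve(grid, approx(d, f, xout = grid, rule = 2)$y)
}

# closed-form area under a polyline (trapezoid-exact)
polylineArea <- function(d, f) {
  i <- seq_len(length(d) - 1)
  sum((d[i + 1] - d[i]) * (f[i + 1] + f[i]) / 2)
}

# grayscale scene: light background with dark filled ellipses
# centers: list of c(y, x); axes c(b, a) in pixels
ellipseScene <- function(H, W, centers, axes = c(8, 12),
                         bg = 95, fg = 40) {
  L <- matrix(bg, H, W)
  for (ct in centers) {
    yy <- 1:H; xx <- 1:W
    sel <- outer((yy - ct[1])^2 / axes[1]^2,
                 (xx - ct[2])^2 / axes[2]^2, "+") <= 1
    L[sel] <- fg
  }
  L
}

# balanced score table with fully controlled effect components
scoreGrid <- function(nJudges, nSessions, k = 5,
                      attr = "color") {
  expand.grid(judge = paste0("J", seq_len(nJudges)),
              session = paste0("S", seq_len(nSessions)),
              sample = paste0("MS", seq_len(k)),
              attribute = attr,
              stringsAsFactors = FALSE)
}
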
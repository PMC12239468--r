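# Shared fixtures: canonical lines, random rigid motions, brute-force oracles.

vline <- function(x = 0) directed_line(pnt(x, 0), c(0, 1))
hline <- function(y = 0) directed_line(pnt(0, y), c(1, 0))

# independent rotation-matrix oracle (kept separate from the package's rot_mat)
rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

random_rigid <- function() {
  list(angle = stats::runif(1, -180, 180),
       shift = stats::runif(2, -200, 200))
}

# brute-force support line: the vertex through which a line of direction `d`
# can pass with all other vertices in one closed half-plane on the stated side
brute_support_vertex <- function(curve, d, side = "right") {
  d <- d / sqrt(sum(d^2))
  n <- if (side == "right") c(d[2], -d[1]) else c(-d[2], d[1])
  m <- unclass(curve)
  scores <- m %*% n
  best <- which.max(scores)
  # verify the support property by definition
  stopifnot(all(scores <= scores[best] + 1e-9))
  m[best, ]
}

# brute-force point-to-line distance by dense sampling along the line
brute_point_line_distance <- function(p, l, half_span = 500, step = 0.01) {
  t <- seq(-half_span, half_span, by = step)
  xs <- l$anchor[1] + t * l$direction[1]
  ys <- l$anchor[2] + t * l$direction[2]
  min(sqrt((xs - p[1])^2 + (ys - p[2])^2))
}

# a generated bone pair for reuse
fixture_femur <- function(dfb = 4.4) generate_femur(femur_params(dfb = dfb))
fixture_tibia <- function(ptb = 2, tps = 8.2, tst = 8.8)
  generate_tibia(tibia_params(ptb = ptb, native_tps = tps, tst = tst))
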
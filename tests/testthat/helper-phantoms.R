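# Shared fixtures and oracles. Expensive phantom pipelines are memoised so
# several test files can reuse them within one session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# endpoints trimmed `mm` inside the tube ends (as a user would place them,
# clear of the end caps)
trimmed_endpoints <- function(truth, mm) {
  L <- max(truth$arclength_mm)
  rbind(as.numeric(truth[which.min(abs(truth$arclength_mm - mm)), c("x", "y", "z")]),
        as.numeric(truth[which.min(abs(truth$arclength_mm - (L - mm))), c("x", "y", "z")]))
}

# analytic centerline object from exact points (for Frenet closed-form tests)
analytic_centerline <- function(pts, misr = 1) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  structure(list(branches = list(list(
    id = 1L, points = pts, misr_mm = rep(misr, nrow(pts)),
    arclength_mm = c(0, cumsum(seg)), parent = NA_integer_))),
    class = "cv_centerline")
}

# full measurement chain on a phantom: mask -> mesh -> centerline -> features
phantom_chain <- function(spec, spacing = 0.284, trim_mm = 4) {
  ph <- make_tube_phantom(spec, spacing)
  ends <- trimmed_endpoints(ph$truth, trim_mm)
  cl <- resample_centerline(compute_centerline(ph$mask, list(ends)))
  mesh <- extract_surface(ph$mask)
  feats <- point_features(mesh, cl)
  list(phantom = ph, mask = ph$mask, mesh = mesh, centerline = cl,
       features = feats)
}

cylinder_chain <- function() memo("cylinder_chain",
  phantom_chain(tube_spec("cylinder", radius_mm = 2, length_mm = 40)))

torus_chain <- function() memo("torus_chain",
  phantom_chain(tube_spec("torus_arc", radius_mm = 2, bend_radius_mm = 10,
                          arc_deg = 180)))

helix_chain <- function() memo("helix_chain",
  phantom_chain(tube_spec("helix", radius_mm = 1.2, coil_radius_mm = 5,
                          pitch_mm = 2, turns = 1.5)))

# middle portion of a per-point table (clear of one-sided end stencils)
mid_rows <- function(df, lo = 0.2, hi = 0.8) {
  n <- nrow(df)
  df[round(lo * n):round(hi * n), , drop = FALSE]
}

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments (mid-ranks); the independent oracle for paired_wilcoxon.
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  sums <- vapply(0:(2^n - 1), function(m) {
    bits <- as.integer(intToBits(m))[seq_len(n)]
    sum(r[bits == 1])
  }, 0)
  min(1, 2 * min(mean(sums <= V + 1e-9), mean(sums >= V - 1e-9)))
}

# Rician mean for signal nu and scale sigma, by numerical integration of the
# density x/sigma^2 exp(-(x^2+nu^2)/(2 sigma^2)) I0(x nu / sigma^2); the
# scaled Bessel keeps the product in floating range:
# exp(-(x^2+nu^2)/(2s^2)) I0(x nu/s^2) = exp(-(x-nu)^2/(2s^2)) I0_scaled(.)
rician_mean <- function(nu, sigma) {
  stats::integrate(function(x)
    x * x / sigma^2 * exp(-(x - nu)^2 / (2 * sigma^2)) *
      besselI(x * nu / sigma^2, 0, expon.scaled = TRUE),
    lower = max(0, nu - 12 * sigma), upper = nu + 12 * sigma,
    rel.tol = 1e-9)$value
}

# small atlas CSV on disk for atlas tests
write_mini_atlas <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# perimeter of an ellipse by numerical quadrature (oracle for contour tests)
ellipse_perimeter <- function(a, b) {
  stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                   0, 2 * pi, rel.tol = 1e-10)$value
}
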
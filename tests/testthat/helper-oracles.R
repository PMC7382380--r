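# Independent oracles and small random-data builders shared across tests.

# Brute-force orthogonal-SSE minimizer: grid over the line angle (offset is
# optimal at the centroid projection for any direction), then local
# refinement. Independent of the closed-form/eigen path in fit_orthogonal.
brute_force_tls <- function(x, y, grid_n = 3601) {
  sse <- function(theta) {
    nx <- -sin(theta); ny <- cos(theta)           # unit normal
    proj <- nx * x + ny * y
    sum((proj - mean(proj))^2)
  }
  thetas <- seq(-pi / 2, pi / 2, length.out = grid_n)
  vals <- vapply(thetas, sse, numeric(1))
  i <- which.min(vals)
  lo <- thetas[max(1, i - 1)]; hi <- thetas[min(grid_n, i + 1)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
  theta <- opt$minimum
  slope <- tan(theta)
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept, theta = theta)
}

# Signed perpendicular projection onto the unit normal of y = a + b x,
# oriented so points above the line are positive.
projection_distance <- function(x, y, a, b) {
  (y - a - b * x) / sqrt(1 + b^2)
}

# Random anisotropic point cloud with a known-ish principal direction.
random_tls_points <- function(n, angle_max_deg = 80) {
  theta <- stats::runif(1, -angle_max_deg, angle_max_deg) * pi / 180
  t <- stats::rnorm(n, sd = stats::runif(1, 1, 4))
  o <- stats::rnorm(n, sd = stats::runif(1, 0.05, 0.3))
  ctr <- stats::runif(2, -5, 5)
  list(x = ctr[1] + t * cos(theta) - o * sin(theta),
       y = ctr[2] + t * sin(theta) + o * cos(theta))
}

# One random valid plant as a 3-row record table; allocations recomputable
# by hand from the raw numbers.
random_plant <- function(id) {
  dw <- stats::runif(3, c(50, 300, 5), c(500, 2500, 1200))
  n <- stats::runif(3, 0.3, 5)
  c_ <- stats::runif(3, 30, 60)
  a15 <- 0.3660 + stats::runif(3, -0.005, 1.5)
  data.frame(plant_id = id, genotype = sample(c("7", "63", "83"), 1),
             condition = sample(c("control", "drought"), 1),
             experiment = "1", organ = c("rosette", "stem", "seeds"),
             dw_mg = dw, n_pct = n, c_pct = c_, a15_pct = a15)
}

random_plants_dataset <- function(n_plants) {
  rec <- do.call(rbind, lapply(seq_len(n_plants),
                               function(i) random_plant(sprintf("p%04d", i))))
  nue_dataset(rec)
}

# A tiny three-organ plant with chosen dry weights and uniform N%, C%.
plant_with_dw <- function(dw, id = "p1", n_pct = c(2.5, 2.8, 4.0),
                          a15 = c(0.466, 0.446, 0.491)) {
  data.frame(plant_id = id, genotype = "63", condition = "control",
             experiment = "1", organ = c("rosette", "stem", "seeds"),
             dw_mg = dw, n_pct = n_pct, c_pct = c(40, 42, 55),
             a15_pct = a15)
}
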
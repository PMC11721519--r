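# shared fixtures: the two model systems studied throughout (repulsions
# off and reference) at the two extreme patch sizes

model_ro_55 <- ipp_model(55, 0, 0)
model_ref_55 <- ipp_model(55, 0.5, 2)
model_ro_30 <- ipp_model(30, 0, 0)
model_ref_30 <- ipp_model(30, 0.5, 2)

# Monte Carlo oracle for the lens volume: fraction of points in a bounding
# box of the smaller sphere that fall inside both spheres. Kept independent
# of the closed-form implementation on purpose.
mc_overlap_volume <- function(R1, R2, d, n = 2e5, seed = 1) {
  set.seed(seed)
  # sample inside the smaller sphere's bounding cube, centred on it
  if (R2 < R1) {
    tmp <- R1; R1 <- R2; R2 <- tmp
  }
  pts <- matrix(runif(3 * n, -R1, R1), ncol = 3)
  in1 <- rowSums(pts^2) <= R1^2
  pts2 <- pts
  pts2[, 1] <- pts2[, 1] - d # second sphere centred at (d, 0, 0)
  hit <- in1 & rowSums(pts2^2) <= R2^2
  p <- mean(hit)
  box <- (2 * R1)^3
  list(v = box * p, se = box * sqrt(p * (1 - p) / n))
}

# random unit vector
runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# random rotation matrix (QR of a Gaussian matrix, det fixed to +1)
rrot <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
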
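# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# --- rotation-search superposition oracle -------------------------------
# Minimal RMSD over rigid transforms found by scanning random unit
# quaternions and polishing the best candidates with Nelder-Mead over the
# rotation vector. Independent of the SVD (Kabsch) route.

quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotvec_to_mat <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  a <- r / th
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

mat_to_rotvec <- function(R) {
  ang <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-9) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  ax <- ax / sqrt(sum(ax^2))
  ax * ang
}

oracle_superpose_rmsd <- function(mobile, reference, weights = NULL,
                                  n_quat = 2000) {
  n <- nrow(mobile)
  w <- if (is.null(weights)) rep(1, n) else weights
  w <- w / sum(w)
  P <- sweep(mobile, 2, colSums(mobile * w))
  Q <- sweep(reference, 2, colSums(reference * w))
  score_R <- function(R) sqrt(sum(w * rowSums((P %*% t(R) - Q)^2)))
  quats <- matrix(rnorm(4 * n_quat), ncol = 4)
  scores <- apply(quats, 1, function(q) score_R(quat_to_mat(q)))
  best <- order(scores)[1:3]
  polished <- vapply(best, function(i) {
    r0 <- mat_to_rotvec(quat_to_mat(quats[i, ]))
    stats::optim(r0, function(r) score_R(rotvec_to_mat(r)),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$value
  }, 0)
  min(polished)
}

# --- small builders -----------------------------------------------------

random_coords <- function(n, spread = 5) {
  matrix(rnorm(3 * n, sd = spread), ncol = 3)
}

static_traj <- function(n_frames = 5, n_res = 10) {
  ref <- helical_reference(n_res)
  trajectory(ref$atoms, matrix(rep(as.numeric(t(ref$coords)), n_frames),
                               nrow = n_frames, byrow = TRUE))
}

write_tmp_tsv <- function(d) {
  f <- tempfile(fileext = ".tsv")
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
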
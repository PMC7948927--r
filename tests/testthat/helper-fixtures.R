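# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests write themselves.

# minimal protein model: one residue per entry of `residues`,
# residues given as list(resid=, atoms=character vector); coordinates
# are arbitrary but distinct
tiny_model <- function(residues, chain = "A") {
  rows <- list(); xyz <- numeric(0)
  k <- 0
  for (i in seq_along(residues)) {
    r <- residues[[i]]
    for (el in r$atoms) {
      k <- k + 1
      rows[[k]] <- data.frame(type = "ATOM", elety = el, resid = r$resid,
                              chain = chain, resno = i, insert = NA_character_,
                              elesy = mdvar:::guess_element(el),
                              stringsAsFactors = FALSE)
      xyz <- c(xyz, k * 1.7, i * 3.1, (k %% 3) * 0.9)
    }
  }
  structure_model(do.call(rbind, rows), xyz)
}

heavy_atoms <- function(model, key) {
  idx <- residue_keys(model) == key & model$atoms$elesy != "H"
  model$atoms$elety[idx]
}

# random symmetric distance matrix with zero diagonal
random_dm <- function(n, labels = LETTERS[seq_len(n)]) {
  m <- matrix(runif(n * n, 0.1, 10), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  m
}

# proper 3D rotation from three angles
rotation3 <- function(a, b, c) {
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# apply a rigid motion to every frame of a trajectory
rigid_move <- function(traj, rot, shift) {
  out <- traj
  for (f in seq_len(n_frames(traj))) {
    m <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    out$xyz[f, ] <- as.vector(t(m %*% t(rot) + matrix(shift, nrow(m), 3, byrow = TRUE)))
  }
  out
}

# independent dihedral oracle: explicit two-plane-normal formula with
# sign from the scalar triple product (kept separate from the package's
# vectorized implementation)
dihedral_oracle <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  wrap_angle(ang)
}

# count grid with a declared total
count_grid <- function(counts, N = sum(counts)) {
  g <- as.matrix(counts)
  storage.mode(g) <- "integer"
  attr(g, "N") <- N
  g
}
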
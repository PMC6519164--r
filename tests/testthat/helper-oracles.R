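# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Isochromat (Bloch rotation) simulation of the gradient-spoiled sequence:
# nspins spins uniformly dephased over 2 pi per TR, explicit 3x1
# magnetization vectors, rotation about x, relaxation, spoiler rotation
# about z. The F0 signal emerges as the spin average.
iso_fisp_oracle <- function(t1, t2, fa_deg, tr, te, invert, nspins = 301) {
  phi <- 2 * pi * (0:(nspins - 1)) / nspins
  M <- matrix(0, 3, nspins)
  M[3, ] <- if (invert) -1 else 1
  E1 <- exp(-tr / t1); E2 <- exp(-tr / t2)
  out <- complex(length(fa_deg))
  cph <- cos(phi); sph <- sin(phi)
  for (n in seq_along(fa_deg)) {
    a <- fa_deg[n] * pi / 180
    Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
    M <- Rx %*% M
    out[n] <- mean(complex(real = M[1, ], imaginary = M[2, ])) * exp(-te / t2)
    M[1, ] <- M[1, ] * E2
    M[2, ] <- M[2, ] * E2
    M[3, ] <- 1 + (M[3, ] - 1) * E1
    x <- M[1, ] * cph - M[2, ] * sph
    y <- M[1, ] * sph + M[2, ] * cph
    M[1, ] <- x; M[2, ] <- y
  }
  out
}

# dense (slow) 2D DFT matrix for an n x n image at arbitrary coords
dense_dft_matrix <- function(coords, n) {
  xc <- rep((0:(n - 1)) - n / 2, n)
  yc <- rep((0:(n - 1)) - n / 2, each = n)
  exp(-2i * pi * (outer(coords[, 1], xc) + outer(coords[, 2], yc)))
}

flatten_kdata <- function(kd) {
  matrix(aperm(kd$samples, c(1, 3, 2)), ncol = dim(kd$samples)[2])
}

all_coords <- function(traj) {
  cbind(as.vector(traj$coords[, 1, ]), as.vector(traj$coords[, 2, ]))
}

rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))
}

modal_value <- function(v) as.numeric(names(sort(table(v), decreasing = TRUE))[1])

# small 4-neighbourhood erosion for comparing maps away from tissue borders
erode_mask_for_tests <- function(mask, iter = 2) {
  for (k in seq_len(iter)) {
    n1 <- nrow(mask); n2 <- ncol(mask)
    m <- mask
    m[-1, ] <- m[-1, ] & mask[-n1, ]
    m[-n1, ] <- m[-n1, ] & mask[-1, ]
    m[, -1] <- m[, -1] & mask[, -n2]
    m[, -n2] <- m[, -n2] & mask[, -1]
    mask <- m
  }
  mask
}
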
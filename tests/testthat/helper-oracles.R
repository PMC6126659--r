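# Independent oracles: these re-derive results by a different route than the
# package (closed-quaternion absolute orientation; exhaustive alignment
# enumeration) and must stay free of the package's fitting/alignment code.

# Horn (1987) closed-form absolute orientation via the unit quaternion
# maximizing the correlation; returns the rmsd of mapping a onto b.
horn_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  S <- crossprod(a0, b0)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  fit <- sweep(a0 %*% t(R), 2, cb, "+")
  sqrt(mean(rowSums((fit - b)^2)))
}

# Exhaustive local-alignment oracle: enumerates every monotone residue pair
# set between two sequences (lengths <= 8) and scores it with affine gaps
# (gap of length k costs open + (k - 1) * ext; the A-side and B-side gap
# costs of a pair set are independent, so they separate).
sw_enumerate <- function(sa, sb, subst, open = 10, ext = 1) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  stopifnot(n <= 8, m <= 8)
  gap_cost <- function(idx) {
    g <- diff(idx) - 1L
    sum(ifelse(g > 0, open + (g - 1) * ext, 0))
  }
  best <- 0
  for (k in seq_len(min(n, m))) {
    A <- utils::combn(n, k); B <- utils::combn(m, k)
    total <- matrix(0, ncol(A), ncol(B))
    for (r in seq_len(k))
      total <- total + outer(A[r, ], B[r, ],
                             function(i, j) subst[cbind(a[i], b[j])])
    ga <- apply(A, 2, gap_cost); gb <- apply(B, 2, gap_cost)
    best <- max(best, max(total - outer(ga, gb, "+")))
  }
  best
}

random_peptide <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"), n, TRUE),
        collapse = "")
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_about_axis(ax, stats::runif(1, 0, 360))
}

random_rigid <- function(tmax = 20) {
  rigid_transform(random_rotation(), stats::runif(3, -tmax, tmax))
}
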
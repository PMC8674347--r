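# Independent oracles used across the suite.

# Asymmetric-least-squares baseline via Matrix sparse algebra: an
# independent route to the same minimisation as the package's banded
# C++ solver.
als_reference <- function(y, lambda, p, maxit) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(maxit)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

# Brute-force gap clustering: all-pairs adjacency + transitive closure by
# repeated boolean matrix squaring, quadratic in the number of pixels.
# Returns pixel groupings like the package's clustering but computed with
# no graph library and no neighbourhood bucketing.
brute_force_clusters <- function(px, step, max_gap = 2, exclude = "NMP",
                                 metric = "chebyshev") {
  px <- px[!(px$class %in% exclude), , drop = FALSE]
  n <- nrow(px)
  if (n == 0L) return(list())
  ix <- round(px$x / step); iy <- round(px$y / step)
  d <- if (metric == "chebyshev") {
    pmax(abs(outer(ix, ix, "-")), abs(outer(iy, iy, "-")))
  } else {
    sqrt(outer(ix, ix, "-")^2 + outer(iy, iy, "-")^2)
  }
  A <- (d <= max_gap + 1e-9) & outer(px$class, px$class, "==")
  diag(A) <- TRUE
  R <- A
  repeat {
    R2 <- ((R %*% R) > 0) | R
    if (identical(R2, R)) break
    R <- R2
  }
  comp <- apply(R, 1L, function(r) min(which(r)))
  split(paste(px$x, px$y, px$class), paste(px$class, comp))
}

# canonicalise a particle list into a comparable set-of-sets
particle_pixel_sets <- function(particles) {
  sets <- lapply(particles, function(p) {
    sort(paste(p$pixels[, "x"], p$pixels[, "y"], p$class))
  })
  sort(vapply(sets, paste, "", collapse = ";"))
}

# random labelled grid for clustering property tests
random_label_grid <- function(nx, ny, step = 5, fill = 0.3,
                              classes = c("PE", "PP", "NMP")) {
  pts <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  keep <- runif(nrow(pts)) < fill
  pts <- pts[keep, , drop = FALSE]
  data.frame(x = pts$ix * step, y = pts$iy * step,
             class = sample(classes, nrow(pts), replace = TRUE),
             confidence = runif(nrow(pts)),
             stringsAsFactors = FALSE)
}
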
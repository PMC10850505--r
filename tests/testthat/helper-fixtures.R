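# shared fixtures and independent oracles used across the test files

# small two-domain spec for fast sampler/refinement tests
small_spec <- function(mode = "apo") {
  two_domain_spec(n1 = 30, n_link = 7, n2 = 25, mode = mode)
}

# a deterministic pool of bead conformers with cached profiles
fixture_pool <- function(n, q_grid, mode = "apo", seed = 1,
                         spec = two_domain_spec(mode = mode)) {
  spec$mode <- mode
  pool_profiles(make_pool(spec, n, seed = seed), q_grid)
}

# brute-force oracle for the optimal scale factor: dense grid search
grid_search_mu <- function(calc, exp, rel_width = 0.5, n_grid = 40001) {
  mu0 <- sum(calc$I * exp$I / exp$sigma^2) / sum(calc$I^2 / exp$sigma^2)
  grid <- seq(mu0 * (1 - rel_width), mu0 * (1 + rel_width), length.out = n_grid)
  chi2 <- vapply(grid, function(m)
    sum(((m * calc$I - exp$I) / exp$sigma)^2), numeric(1))
  grid[which.min(chi2)]
}

# brute-force motif oracle: regex per gap length at every start (overlaps kept)
motif_scan_oracle <- function(bases, pattern) {
  set_re <- function(sets) paste(vapply(sets, function(s)
    paste0("[", paste(s, collapse = ""), "]"), character(1)), collapse = "")
  hl <- length(pattern$head); tl <- length(pattern$tail)
  L <- nchar(bases)
  hits <- list()
  gaps <- if (tl == 0L) 0L else pattern$gap_min:pattern$gap_max
  for (g in gaps) {
    len <- hl + if (tl > 0L) g + tl else 0L
    re <- paste0("^", set_re(pattern$head),
                 if (tl > 0L) paste0(".{", g, "}", set_re(pattern$tail)) else "")
    for (s in seq_len(max(L - len + 1L, 0L))) {
      if (grepl(re, substr(bases, s, s + len - 1L)))
        hits[[length(hits) + 1L]] <- c(start = s, gap_len = g, end = s + len - 1L)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(0), gap_len = integer(0), end = integer(0)))
  df <- as.data.frame(do.call(rbind, hits))
  df <- df[order(df$start, df$gap_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# brute-force NSD oracle: fine rotation grid (centroids aligned), translation
# refined for the best grid rotations
nsd_oracle <- function(a, b, n_ang = 24, top = 50) {
  A <- sweep(a$points, 2, colMeans(a$points))
  B <- sweep(b$points, 2, colMeans(b$points))
  nn2 <- function(p) {
    dm <- as.matrix(dist(p)); diag(dm) <- Inf; mean(apply(dm, 1, min))^2
  }
  dA2 <- nn2(A); dB2 <- nn2(B)
  nsd_pts <- function(A, B) {
    cross <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    cross[cross < 0] <- 0
    sqrt(0.5 * (mean(apply(cross, 1, min)) / dB2 + mean(apply(cross, 2, min)) / dA2))
  }
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  a1 <- seq(0, 2 * pi, length.out = n_ang + 1)[-(n_ang + 1)]
  a2 <- seq(0, pi, length.out = n_ang / 2 + 1)
  grid <- as.matrix(expand.grid(a1, a2, a1))
  vals <- apply(grid, 1, function(g) nsd_pts(A, B %*% t(rot(g))))
  # local polish (rotation + translation) from the best grid rotations
  best <- numeric(0)
  for (i in order(vals)[seq_len(top)]) {
    o <- optim(c(grid[i, ], 0, 0, 0), function(par)
      nsd_pts(A, sweep(B %*% t(rot(par[1:3])), 2, par[4:6], "+")),
      method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
    best <- c(best, o$value)
  }
  min(c(vals, best))
}

# analytic Guinier curve I = i0 exp(-q^2 rg^2 / 3)
guinier_curve <- function(rg, i0 = 100, q = seq(0.005, 0.12, length.out = 60),
                          sigma = NULL) {
  scattering_curve(q, i0 * exp(-q^2 * rg^2 / 3), sigma)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
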
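test_that("zero displacement reconstructs zero traction", {
  x <- (0:31) * 2e-6
  z <- matrix(0, 32, 32)
  fld <- displacement_field(x, x, z, z)
  tr <- fttc_reconstruct(fld, paam(), 0.01)
  expect_equal(max(abs(c(tr$tx, tr$ty))), 0)
})

test_that("forward-FTTC round trip recovers a smooth traction field", {
  sub <- paam()
  N <- 64L; h <- 1.3e-6
  x <- (0:(N - 1)) * h
  X <- matrix(x, N, N, byrow = TRUE); Y <- matrix(x, N, N)
  c0 <- max(x) / 2
  tx <- 200 * exp(-((X - c0)^2 + (Y - 0.8 * c0)^2) / (2 * (6e-6)^2)) -
    150 * exp(-((X - 1.3 * c0)^2 + (Y - c0)^2) / (2 * (7e-6)^2))
  ty <- 180 * exp(-((X - 0.7 * c0)^2 + (Y - 1.2 * c0)^2) / (2 * (6e-6)^2))
  tx <- tx - mean(tx); ty <- ty - mean(ty)
  u <- kspace_forward(tx, ty, h, sub$E, sub$nu)
  fld <- displacement_field(x, x, u$ux, u$uy)
  tr <- fttc_reconstruct(fld, sub, 0)
  rel <- sqrt(sum((tr$tx - tx)^2 + (tr$ty - ty)^2)) / sqrt(sum(tx^2 + ty^2))
  expect_lt(rel, 0.02)
  expect_equal(tr$lambda_used, 0)
})

test_that("reconstructed stresses sum to the zero vector for any input", {
  set.seed(21)
  x <- (0:23) * 2.6e-6   # non-power-of-two grid exercises the padding
  ux <- matrix(stats::rnorm(24^2), 24, 24) * 1e-7
  uy <- matrix(stats::rnorm(24^2), 24, 24) * 1e-7
  fld <- displacement_field(x, x, ux, uy)
  for (l in c(0, 1e-3, 0.1)) {
    tr <- fttc_reconstruct(fld, paam(), l)
    expect_equal(sum(tr$tx), 0, tolerance = 1e-10)
    expect_equal(sum(tr$ty), 0, tolerance = 1e-10)
    expect_true(all(is.finite(c(tr$tx, tr$ty))))
  }
  expect_error(fttc_reconstruct(fld, paam(), -1), "lambda")
})

test_that("total traction norm is non-increasing in lambda", {
  set.seed(22)
  x <- (0:31) * 2e-6
  ux <- matrix(stats::rnorm(32^2), 32, 32) * 1e-7
  uy <- matrix(stats::rnorm(32^2), 32, 32) * 1e-7
  fld <- displacement_field(x, x, ux, uy)
  norms <- vapply(c(0, 1e-4, 1e-3, 1e-2, 0.1, 1, 10), function(l) {
    tr <- fttc_reconstruct(fld, paam(), l)
    sqrt(sum(tr$tx^2 + tr$ty^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-9 * norms[1]))
})

test_that("GCV function matches a dense-matrix brute force on a tiny grid", {
  sub <- elastic_substrate(5e3, 0.45)
  N <- 4L; h <- 2e-6
  x <- (0:(N - 1)) * h
  set.seed(31)
  ux <- matrix(stats::rnorm(N^2), N, N) * 1e-8
  uy <- matrix(stats::rnorm(N^2), N, N) * 1e-8
  fld <- displacement_field(x, x, ux, uy)
  # dense forward operator built column by column via the independent
  # k-space multiply, then SVD -> filter factors -> V(lambda)
  B <- matrix(0, 2 * N^2, 2 * N^2)
  for (j in seq_len(2 * N^2)) {
    tx <- matrix(0, N, N); ty <- matrix(0, N, N)
    if (j <= N^2) tx[j] <- 1 else ty[j - N^2] <- 1
    u <- kspace_forward(tx, ty, h, sub$E, sub$nu)
    B[, j] <- c(u$ux, u$uy)
  }
  sv <- svd(B)
  keep <- sv$d > 1e-12 * max(sv$d)         # drop the two k = 0 null modes
  shat <- sv$d[keep] / max(sv$d)
  coef2 <- as.numeric(t(sv$u[, keep]) %*% c(ux, uy))^2
  m <- 2 * (N^2 - 1)
  v_dense <- function(l) {
    r <- l^2 / (shat^2 + l^2)
    (sum(r^2 * coef2) / m) / ((sum(r) / m)^2)
  }
  for (l in c(1e-3, 0.05, 0.3, 2)) {
    expect_equal(gcv_function(fld, sub, l), v_dense(l), tolerance = 1e-8)
  }
})

test_that("GCV selects a tiny lambda on noiseless data, a sensible one under noise", {
  sub <- paam()
  N <- 32L; h <- 2.6e-6
  x <- (0:(N - 1)) * h
  X <- matrix(x, N, N, byrow = TRUE); Y <- matrix(x, N, N)
  c0 <- max(x) / 2
  tx <- 150 * exp(-((X - c0)^2 + (Y - c0)^2) / (2 * (8e-6)^2))
  ty <- -120 * exp(-((X - 0.6 * c0)^2 + (Y - 1.3 * c0)^2) / (2 * (9e-6)^2))
  tx <- tx - mean(tx); ty <- ty - mean(ty)
  u <- kspace_forward(tx, ty, h, sub$E, sub$nu)
  fld <- displacement_field(x, x, u$ux, u$uy)
  expect_lt(gcv_select_lambda(fld, sub), 1e-3)
  # 10% noise: selected lambda within one decade of the oracle optimum
  set.seed(33)
  sdn <- 0.1 * max(sqrt(u$ux^2 + u$uy^2))
  fn <- fld
  fn$ux <- u$ux + matrix(stats::rnorm(N^2, 0, sdn), N)
  fn$uy <- u$uy + matrix(stats::rnorm(N^2, 0, sdn), N)
  l_gcv <- gcv_select_lambda(fn, sub)
  lg <- 10^seq(-5, 0, length.out = 30)
  err <- vapply(lg, function(l) {
    tr <- fttc_reconstruct(fn, sub, l)
    sqrt(sum((tr$tx - tx)^2 + (tr$ty - ty)^2))
  }, numeric(1))
  l_star <- lg[which.min(err)]
  expect_lt(abs(log10(l_gcv) - log10(l_star)), 1)
  # degenerate all-zero field
  z <- displacement_field(x, x, matrix(0, N, N), matrix(0, N, N))
  expect_error(gcv_select_lambda(z, sub), "zero")
})

test_that("window integration: area times stress, and bounded leakage", {
  x <- (0:63) * 1e-6
  tx <- matrix(100, 64, 64); ty <- matrix(0, 64, 64)
  tr <- traction_field(x, x, tx, ty)
  # uniform (100, 0) Pa over a 10x10 um window (100 nodes x 1 um^2)
  f <- integrate_window_traction(tr, c(20e-6, 29e-6, 20e-6, 29e-6))
  expect_equal(f, c(100 * 100 * 1e-12, 0))
  z <- traction_field(x, x, matrix(0, 64, 64), matrix(0, 64, 64))
  expect_equal(integrate_window_traction(z, c(0, 10e-6, 0, 10e-6)), c(0, 0))
  expect_error(integrate_window_traction(tr, c(1e-3, 2e-3, 1e-3, 2e-3)),
               "no grid nodes")
  # forward-simulated single 2 um patch: window of 3 radii recovers the
  # generating force within 10%
  sub <- paam()
  p <- circular_patch(1, c(32e-6, 32e-6), 2e-6)
  g <- list(x = x, y = x)
  f0 <- c(5e-9, -2e-9)
  fld <- forward_displacement_field(list(p), rbind(f0), g, sub)
  lam <- gcv_select_lambda(fld, sub)
  trr <- fttc_reconstruct(fld, sub, lam)
  fi <- integrate_window_traction(trr, c(32e-6 - 6e-6, 32e-6 + 6e-6,
                                         32e-6 - 6e-6, 32e-6 + 6e-6))
  expect_lt(sqrt(sum((fi - f0)^2)) / sqrt(sum(f0^2)), 0.10)
})

test_that("patch and FTTC methods agree on a balanced-dipole cell", {
  sub <- paam()
  scen <- default_scenario("colinear", n_frames = 2L)
  truth <- scenario_truth_forces(scen)
  f0 <- truth[[1]]                       # zero-monopole frame
  N <- 64L; h <- 1.3e-6
  g <- list(x = (0:(N - 1)) * h, y = (0:(N - 1)) * h)
  fld <- forward_displacement_field(scen$patches, f0, g, sub)
  lam <- gcv_select_lambda(fld, sub)
  tr <- fttc_reconstruct(fld, sub, lam)
  wins <- scenario_windows(scen)
  fttc_f <- t(vapply(seq_len(nrow(wins)), function(k) {
    integrate_window_traction(tr, c(wins$xmin[k], wins$xmax[k],
                                    wins$ymin[k], wins$ymax[k]))
  }, numeric(2)))
  fm <- field_magnitude(fld)
  ctr <- detect_patch_centers(fm, wins)
  rad <- estimate_patch_radius(fm, ctr)
  ps <- lapply(1:9, function(k) circular_patch(k, ctr[k, ], rad[k]))
  pfs <- fit_patch_forces(fld, ps, sub)
  cmp <- compare_methods(pfs, fttc_f, wins$label)
  # identical inputs -> zero differences
  self <- compare_methods(pfs, pfs$forces)
  expect_equal(self$rel_diff, rep(0, 9))
  # cross-method agreement on the loaded patches
  loaded <- sqrt(rowSums(f0^2)) > 1e-9
  expect_lt(stats::median(cmp$rel_diff[loaded]), 0.20)
  # with noise: finite, no crash
  fn <- add_field_noise(fld, 0.05, seed = 13L)
  lam_n <- gcv_select_lambda(fn, sub)
  tr_n <- fttc_reconstruct(fn, sub, lam_n)
  fttc_n <- t(vapply(seq_len(nrow(wins)), function(k) {
    integrate_window_traction(tr_n, c(wins$xmin[k], wins$xmax[k],
                                      wins$ymin[k], wins$ymax[k]))
  }, numeric(2)))
  cmp_n <- compare_methods(fit_patch_forces(fn, ps, sub), fttc_n)
  expect_true(all(is.finite(cmp_n$rel_diff)))
})
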
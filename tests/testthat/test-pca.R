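test_that("assembled matrix columns are standardized against the mean profile", {
  set.seed(2)
  windows <- replicate(30, 0.8 + 0.05 * rnorm(200), simplify = FALSE)
  std <- assemble_matrix(windows)
  expect_equal(dim(std$matrix), c(200, 30))
  expect_equal(colMeans(std$matrix^2), rep(1, 30), tolerance = 1e-10)
  expect_equal(std$mean_profile, rowMeans(matrix(unlist(windows), 200)))
  # identical windows: zero variance after mean-profile subtraction
  same <- replicate(5, rep(0.8, 100), simplify = FALSE)
  expect_error(assemble_matrix(same, ids = letters[1:5]), "degenerate record.*a")
})

test_that("the threshold coefficient matches the published cubic", {
  expect_equal(gavish_donoho_omega(1e-9), 1.43, tolerance = 1e-6)
  expect_equal(gavish_donoho_omega(1), 2.86)
  expect_equal(gavish_donoho_omega(368 / 1600), 1.805, tolerance = 1e-3)
  expect_error(gavish_donoho_omega(0), "0, 1")
  expect_error(gavish_donoho_omega(1.2), "0, 1")
})

planted_matrix <- function(m, n, k, margin = 1.5, seed = 1) {
  set.seed(seed)
  E <- matrix(rnorm(m * n), m, n)
  tau0 <- gavish_donoho_omega(n / m) * median(svd(E, nu = 0, nv = 0)$d)
  U <- qr.Q(qr(matrix(rnorm(m * k), m, k)))
  V <- qr.Q(qr(matrix(rnorm(n * k), n, k)))
  E + U %*% diag(rep(margin * tau0, k), k) %*% t(V)
}

test_that("SVD reconstructs and the hard threshold finds planted rank", {
  X <- planted_matrix(200, 60, 3, seed = 4)
  d <- fit_decomposition(X)
  R <- d$left_vectors %*% diag(d$singular_values) %*% t(d$right_vectors)
  expect_lt(norm(R - X, "F") / norm(X, "F"), 1e-8)
  ks <- vapply(1:20, function(s) fit_decomposition(planted_matrix(200, 60, 3, seed = s))$k,
               integer(1))
  expect_true(all(ks == 3))
})

test_that("retained rank is invariant to column permutation", {
  X <- planted_matrix(150, 40, 4, seed = 9)
  d1 <- fit_decomposition(X)
  set.seed(1)
  d2 <- fit_decomposition(X[, sample(ncol(X))])
  expect_equal(d1$k, d2$k)
  expect_equal(d1$singular_values, d2$singular_values, tolerance = 1e-8)
})

test_that("noise-only matrices keep at most the floored minimum rank", {
  ks <- vapply(1:5, function(s) {
    set.seed(s)
    fit_decomposition(matrix(rnorm(1600 * 368), 1600, 368))$k
  }, integer(1))
  expect_true(all(ks <= 2))
})

test_that("projection reproduces training coefficients and obeys Bessel", {
  set.seed(6)
  windows <- replicate(40, 0.8 + cumsum(rnorm(120, sd = 0.01)), simplify = FALSE)
  std <- assemble_matrix(windows)
  d <- fit_decomposition(std)
  sv_t <- diag(d$singular_values) %*% t(d$right_vectors)
  for (j in c(1, 17, 40)) {
    coef <- project_record(d, windows[[j]])
    expect_equal(coef, sv_t[seq_len(d$k), j], tolerance = 1e-8)
  }
  new_w <- 0.8 + cumsum(rnorm(120, sd = 0.01))
  x <- new_w - d$mean_profile
  x <- x / sqrt(mean(x^2))
  expect_lte(sum(project_record(d, new_w)^2), sum(x^2) + 1e-10)
  expect_error(project_record(d, rep(0.8, 120) * 0 + d$mean_profile), "degenerate")
  expect_error(project_record(d, rnorm(10)), "window length")
})

test_that("fitting ignores rows outside the training set", {
  set.seed(8)
  train <- replicate(25, 0.8 + cumsum(rnorm(100, sd = 0.01)), simplify = FALSE)
  test1 <- replicate(5, 0.8 + cumsum(rnorm(100, sd = 0.01)), simplify = FALSE)
  test2 <- lapply(test1, function(w) w + 10)   # wildly different test rows
  d1 <- fit_decomposition(assemble_matrix(train))
  p1 <- lapply(test1, project_record, decomp = d1)
  d2 <- fit_decomposition(assemble_matrix(train))
  expect_identical(d1$left_vectors, d2$left_vectors)
  expect_identical(d1$k, d2$k)
  # projecting different test rows does not alter the decomposition
  invisible(lapply(test2, project_record, decomp = d2))
  expect_identical(d1$singular_values, d2$singular_values)
})

test_that("decomposition archives round-trip through JSON", {
  X <- planted_matrix(80, 30, 2, seed = 3)
  d <- fit_decomposition(X)
  path <- withr::local_tempfile(fileext = ".json")
  write_decomposition(d, path)
  back <- read_decomposition(path)
  expect_equal(back$k, d$k)
  expect_equal(back$threshold, d$threshold)
  expect_equal(back$left_vectors, d$left_vectors[, seq_len(d$k)], tolerance = 1e-12)
  w <- X[, 1] * 0.01 + 0.8
  expect_equal(project_record(back, w), project_record(d, w), tolerance = 1e-10)
})

test_that("tidy and glance summarise the decomposition", {
  d <- fit_decomposition(planted_matrix(100, 30, 2, seed = 2))
  td <- tidy(d)
  expect_equal(nrow(td), 30)
  expect_equal(sum(td$retained), d$k)
  g <- glance(d)
  expect_equal(g$k, d$k)
  expect_true(g$frac_energy_retained > 0 && g$frac_energy_retained <= 1)
})
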
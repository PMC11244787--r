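test_that("intensity statistics match their definitions", {
  const <- matrix(37, 8, 8)
  expect_equal(fm_api(const), 37)
  expect_equal(fm_sd(const), 0)
  half <- matrix(rep(c(0, 255), each = 32), 8, 8)
  expect_equal(fm_api(half), 127.5)
  expect_equal(fm_sd(half), 127.5)
  r <- rand_raw8(16, 16, 201)
  expect_equal(fm_sd(r), oracle_sd(r), tolerance = 1e-10)
  expect_equal(fm_api(r), sum(r) / 256, tolerance = 1e-12)
})

test_that("average gradient matches ramps and the oracle", {
  expect_equal(fm_ag(matrix(5, 6, 6)), 0)
  ramp <- matrix(rep(1:8, each = 8), 8, 8)  # horizontal step 1
  expect_equal(fm_ag(ramp), 1)
  r <- rand_raw8(16, 16, 202)
  expect_equal(fm_ag(r), oracle_ag(r), tolerance = 1e-10)
  # as-printed normalization divides by mn instead
  expect_equal(fm_ag(r, denom = "mn"), oracle_ag(r) * (15 * 15) / (16 * 16),
               tolerance = 1e-10)
})

test_that("entropy attains its characteristic values and bounds", {
  expect_equal(fm_entropy(matrix(9, 5, 5)), 0)
  two <- matrix(rep(c(10, 200), each = 18), 6, 6)
  expect_equal(fm_entropy(two), 1.0)
  uniform <- matrix(0:255, 16, 16)
  expect_equal(fm_entropy(uniform), 8.0)
  for (seed in 1:3) {
    r <- rand_raw8(12, 12, seed + 210)
    h <- fm_entropy(r)
    expect_gte(h, 0); expect_lte(h, 8)
    expect_equal(h, oracle_entropy(r), tolerance = 1e-10)
  }
})

test_that("mutual information is symmetric, non-negative, H on identity", {
  x <- rand_raw8(16, 16, 220); y <- rand_raw8(16, 16, 221)
  expect_equal(fm_mi(x, x), fm_entropy(x), tolerance = 1e-12)
  expect_equal(fm_mi(x, y), fm_mi(y, x), tolerance = 1e-12)
  expect_gte(fm_mi(x, y), 0)
  expect_equal(fm_mi(x, y), oracle_mi(x, y), tolerance = 1e-10)
  # independent images share almost no information once the finite-sample
  # bias is negligible: with a 2x2 joint histogram the bias is
  # ~ 1/(2 N ln 2) ~ 4e-5 bits at 128x128, far under 0.05
  set.seed(224)
  a <- matrix(255 * rbinom(128 * 128, 1, 0.5), 128, 128)
  b <- matrix(255 * rbinom(128 * 128, 1, 0.5), 128, 128)
  expect_lt(fm_mi(a, b), 0.05)
  # at full 256-level resolution the bias dominates instead:
  # ~ (K-1)(L-1)/(2 N ln 2) ~ 2.9 bits for independent uniform images
  au <- rand_raw8(128, 128, 222); bu <- rand_raw8(128, 128, 223)
  expect_gt(fm_mi(au, bu), 1)   # pure bias, no real dependence
  expect_lt(fm_mi(au, bu), 255 * 255 / (2 * 128 * 128 * log(2)))
  expect_error(fm_mi(x, rand_raw8(8, 8, 1)),
               class = "ncfuse_validation_error")
})

test_that("spatial frequency matches the oracle", {
  expect_equal(fm_sf(matrix(3, 7, 7)), 0)
  cb <- 255 * outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(fm_sf(cb), oracle_sf(cb), tolerance = 1e-10)
  r <- rand_raw8(16, 16, 230)
  expect_equal(fm_sf(r), oracle_sf(r), tolerance = 1e-10)
})

test_that("correlation coefficient spans its range and matches cor()", {
  A <- rand_raw8(16, 16, 240)
  expect_equal(fm_cc(A, A, A), 1)
  expect_equal(fm_cc(A, A, 255 - A), -1)
  B <- rand_raw8(16, 16, 241); F <- rand_raw8(16, 16, 242)
  ref <- (stats::cor(as.vector(A), as.vector(F)) +
          stats::cor(as.vector(B), as.vector(F))) / 2
  expect_equal(fm_cc(A, B, F), ref, tolerance = 1e-12)
  expect_true(abs(fm_cc(A, B, F)) <= 1)
  expect_error(fm_cc(matrix(5, 4, 4), B[1:4, 1:4], F[1:4, 1:4]),
               class = "ncfuse_validation_error")
})

test_that("fusion symmetry lies in [1.5, 2] with equality at even split", {
  A <- rand_raw8(24, 24, 250)
  expect_equal(fm_fs(A, A, A), 2)  # MI_AF = MI_BF by construction
  for (seed in 1:4) {
    a <- rand_raw8(16, 16, seed + 260)
    b <- rand_raw8(16, 16, seed + 270)
    f <- round((a + b) / 2)
    fs <- fm_fs(a, b, f)
    expect_gte(fs, 1.5); expect_lte(fs, 2)
  }
  expect_error(fm_fs(matrix(0, 4, 4), matrix(0, 4, 4), matrix(0, 4, 4)),
               class = "ncfuse_validation_error")
})

test_that("edge_field produces Sobel strengths and orientations", {
  ef <- edge_field(matrix(50, 6, 6))
  expect_equal(ef$g, matrix(0, 6, 6))
  expect_equal(ef$alpha, matrix(0, 6, 6))
  # vertical step edge: purely horizontal change -> alpha = 0 on the edge
  step <- matrix(rep(c(0, 0, 255, 255, 255), each = 5), 5, 5, byrow = TRUE)
  step <- t(step)
  ef <- edge_field(step)
  expect_equal(ef$alpha[3, 2], 0)
  expect_gt(ef$g[3, 2], 0)
  # strength is invariant to intensity offset
  r <- rand_raw8(9, 9, 280)
  expect_equal(edge_field(r)$g, edge_field(r + 30)$g, tolerance = 1e-9)
  # matches the loop oracle
  orc <- oracle_sobel(r)
  expect_equal(edge_field(r)$g, orc$g, tolerance = 1e-10)
  expect_equal(edge_field(r)$alpha, orc$alpha, tolerance = 1e-10)
})

test_that("gradient preservation family is complementary and oracle-exact", {
  a <- rand_raw8(32, 32, 290); b <- rand_raw8(32, 32, 291)
  f <- round((a + b) / 2)
  gp <- gradient_preservation(a, b, f)
  orc <- oracle_qlnm(a, b, f)
  expect_equal(gp$Q_abf, orc$Q, tolerance = 1e-10)
  expect_equal(gp$N_abf, orc$N, tolerance = 1e-10)
  expect_equal(gp$Nm_abf, orc$Nm, tolerance = 1e-10)
  expect_equal(gp$L_abf_direct, orc$L, tolerance = 1e-10)
  # identity: both the enforced and the independently summed loss agree
  expect_equal(gp$Q_abf + gp$L_abf + gp$Nm_abf, 1, tolerance = 1e-12)
  expect_equal(gp$L_abf, gp$L_abf_direct, tolerance = 1e-10)
  # F = A never has gradients above both sources: no artifacts
  gpa <- gradient_preservation(a, b, a)
  expect_equal(gpa$N_abf, 0)
  expect_equal(gpa$Nm_abf, 0)
  # degenerate all-flat triple is vacuous with a warning
  z <- matrix(0, 8, 8)
  expect_warning(gpz <- gradient_preservation(z, z, z), "vacuous")
  expect_equal(gpz$Q_abf, 1)
})

test_that("a faithful fusion scores higher transfer than noise", {
  a <- rand_raw8(24, 24, 295); b <- a
  noise <- rand_raw8(24, 24, 296)
  expect_gte(gradient_preservation(a, b, a)$Q_abf,
             gradient_preservation(a, b, noise)$Q_abf)
})

test_that("metric_report composes the individual operations exactly", {
  pair <- fixture_pair(64)
  res <- fuse_pipeline(pair$ct, pair$mri)
  A <- pair$ct; B <- pair$mri; F <- res$fused
  rep <- metric_report(A, B, F)
  expect_s3_class(rep, "metric_report")
  expect_equal(rep$API, fm_api(F))
  expect_equal(rep$SD, fm_sd(F))
  expect_equal(rep$AG, fm_ag(F))
  expect_equal(rep$H, fm_entropy(F))
  expect_equal(rep$MI, fm_mi_total(A, B, F))
  expect_equal(rep$FS, fm_fs(A, B, F))
  expect_equal(rep$CC, fm_cc(A, B, F))
  expect_equal(rep$SF, fm_sf(F))
  gp <- gradient_preservation(A, B, F)
  expect_equal(rep$Q_abf, gp$Q_abf)
  expect_equal(rep$Nm_abf, gp$Nm_abf)
  # degenerate constant triple: CC is undefined and reported as an error
  z <- gray_image(matrix(100, 8, 8), "raw8")
  suppressWarnings(  # the vacuous-gradient warning precedes the error
    expect_error(metric_report(z, z, z), class = "ncfuse_validation_error"))
})

test_that("metric reports serialize to JSON and CSV", {
  pair <- fixture_pair(64)
  res <- fuse_pipeline(pair$ct, pair$mri)
  rep <- metric_report(pair$ct, pair$mri, res$fused)
  pj <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, pj, "json")
  write_metric_report(rep, pc, "csv")
  back <- jsonlite::read_json(pj)
  expect_equal(back$Q_abf, rep$Q_abf, tolerance = 1e-9)
  tab <- utils::read.csv(pc)
  expect_equal(nrow(tab), 12L)
  expect_equal(tab$value[tab$metric == "H"], rep$H, tolerance = 1e-9)
})
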
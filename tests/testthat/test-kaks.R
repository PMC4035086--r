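test_that("NG86 reproduces the hand-computed alanine-run case", {
  a <- strrep("GCT", 10)
  b <- paste0(strrep("GCT", 9), "GCC")
  r <- kaks_ng86(a, b)
  expect_equal(r$S_sites, 10)
  expect_equal(r$N_sites, 20)
  expect_equal(r$S_sub, 1)
  expect_equal(r$N_sub, 0)
  expect_equal(r$ks, -0.75 * log(1 - 4 / 3 * 0.1), tolerance = 1e-12)
  expect_equal(r$ka, 0)
  expect_equal(r$ratio, 0)  # Ka = 0 with Ks > 0 is a defined ratio of zero
})

test_that("identical CDSs give zero rates and an undefined ratio", {
  s <- random_cds(50, seed = 31)
  for (fn in list(kaks_ng86, kaks_yn00)) {
    r <- fn(s, s)
    expect_equal(r$ka, 0)
    expect_equal(r$ks, 0)
    expect_true(is.na(r$ratio))
  }
})

test_that("NG86 S sites equal the codon count for fourfold-family runs", {
  fams <- c("GCT", "GGA", "CCC", "ACG", "GTA")
  s <- paste(rep(fams, 8), collapse = "")
  r <- kaks_ng86(s, s)
  expect_equal(r$S_sites, 40)
})

test_that("NG86 equals the brute-force pathway oracle on short pairs", {
  set.seed(43)
  n_checked <- 0
  while (n_checked < 20) {
    n_cod <- sample(2:5, 1)
    a <- random_cds(n_cod)
    b <- a
    # mutate 1-3 positions (possibly multiple in one codon)
    for (k in seq_len(sample(1:3, 1))) {
      p <- sample(nchar(b), 1)
      substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(b, p, p)), 1)
    }
    cods <- substring(b, seq(1, nchar(b) - 2, 3), seq(3, nchar(b), 3))
    if (any(vapply(cods, oracle_translate, character(1)) == "*")) next
    r <- kaks_ng86(a, b)
    o <- oracle_ng86(a, b)
    expect_equal(r$S_sites, o$S, tolerance = 1e-10, label = paste(a, b))
    expect_equal(r$S_sub, o$S_sub, tolerance = 1e-10, label = paste(a, b))
    expect_equal(r$N_sub, o$N_sub, tolerance = 1e-10, label = paste(a, b))
    expect_equal(r$ks, o$ks, tolerance = 1e-10, label = paste(a, b))
    expect_equal(r$ka, o$ka, tolerance = 1e-10, label = paste(a, b))
    n_checked <- n_checked + 1
  }
})

test_that("both estimators are symmetric in their arguments", {
  p <- sim_cds_pair(300, omega = 0.3, kappa = 2, t = 0.15, seed = 51)
  for (fn in list(kaks_ng86, kaks_yn00)) {
    r1 <- fn(p$a, p$b)
    r2 <- fn(p$b, p$a)
    expect_equal(r1$ka, r2$ka, tolerance = 1e-9)
    expect_equal(r1$ks, r2$ks, tolerance = 1e-9)
    expect_equal(r1$S_sites, r2$S_sites, tolerance = 1e-9)
  }
})

test_that("YN00 agrees with NG86 when kappa is 1 and usage flat", {
  est <- vapply(1:5, function(r) {
    p <- sim_cds_pair(3000, omega = 0.5, kappa = 1, t = 0.1, seed = 600 + r)
    y <- kaks_yn00(p$a, p$b)
    n <- kaks_ng86(p$a, p$b)
    c(y$ka / n$ka, y$ks / n$ks)
  }, numeric(2))
  expect_lt(max(abs(est - 1)), 0.10)
})

test_that("estimated Ks grows with divergence time", {
  ks_at <- vapply(c(0.05, 0.1, 0.2), function(t) {
    p <- sim_cds_pair(1000, omega = 0.2, kappa = 2, t = t, seed = 71)
    kaks_yn00(p$a, p$b)$ks
  }, numeric(1))
  expect_true(all(diff(ks_at) > 0))
})

test_that("a purifying cohort yields no positive-selection calls", {
  res <- lapply(1:12, function(r) {
    p <- sim_cds_pair(1000, omega = 0.1, kappa = 2, t = 0.05, seed = 800 + r)
    kaks_yn00(p$a, p$b, pair_id = paste0("p", r))
  })
  cls <- classify_selection(res)
  expect_equal(cls$summary$n_positive, 0)
  expect_gt(cls$summary$n_defined, 0)
  expect_true(all(cls$calls$call %in% c("purifying", "undefined")))
})

test_that("selection classification counts ratios around one correctly", {
  tab <- data.frame(pair_id = c("p1", "p2", "p3"),
                    Ka = c(0.01, 0.02, 0), Ks = c(0.02, 0.01, 0),
                    ratio = c(0.5, 2.0, NA))
  cls <- classify_selection(tab)
  expect_equal(cls$calls$call, c("purifying", "positive", "undefined"))
  expect_equal(cls$summary$n_defined, 2)
  expect_equal(cls$summary$pct_purifying, 50)
})

test_that("Ka-on-Ks regression through the origin recovers omega", {
  pts <- t(vapply(1:25, function(r) {
    t <- runif(1, 0.05, 0.3)
    set.seed(900 + r)
    p <- sim_cds_pair(600, omega = 0.2, kappa = 2, t = t, seed = 900 + r)
    y <- kaks_yn00(p$a, p$b)
    c(ka = y$ka, ks = y$ks)
  }, numeric(2)))
  slope <- sum(pts[, "ka"] * pts[, "ks"]) / sum(pts[, "ks"]^2)
  expect_lt(abs(slope - 0.2) / 0.2, 0.25)
})
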
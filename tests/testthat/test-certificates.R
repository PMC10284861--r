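test_that("property values match their definitions", {
  expect_equal(property_sparsity(c(1, 0, 0, 2), 0), 2)
  expect_equal(property_sparsity(rep(0, 5)), 0)
  expect_equal(property_sparsity(c(1e-9, 1), 1e-6), 1)

  I <- identity_map(2)
  expect_equal(property_rel_error(I, c(3, 4), c(3, 4)), 0)
  expect_equal(property_rel_error(I, c(0, 0), c(3, 4)), 1)
  expect_equal(property_rel_error(I, c(3, 0), c(3, 4)), 0.8)
  expect_error(property_rel_error(I, c(1, 1), c(0, 0)), "undefined")

  expect_equal(property_total_variation(matrix(1, 3, 3)), 0)
  expect_equal(property_total_variation(matrix(c(0, 1), 1, 2)), 1)
  expect_equal(property_total_variation(matrix(c(0, 0, 1, 1), 2, 2)), 2)

  expect_equal(property_box_distance(c(0.2, 0.8)), 0)
  expect_equal(property_box_distance(1.5), 0.5)
  expect_equal(property_box_distance(c(-3, 2)), sqrt(10))

  st <- iterate_to_fixed_point(function(x) x / 2, 1, tol = 1e-9, max_iter = 3)
  expect_equal(property_iterate_residual(st), 0.125)
  st_id <- iterate_to_fixed_point(identity, 5, tol = 1e-9)
  expect_equal(property_iterate_residual(st_id), 0)
})

test_that("the empirical CDF counts inclusively and is monotone", {
  tab <- calibrate(property_spec("v", function(r) r$v),
                   lapply(c(1, 2, 3, 4), function(v) list(v = v)))
  expect_equal(empirical_cdf(2.5, tab), 0.5)
  expect_equal(empirical_cdf(0.3, tab), 0)
  expect_equal(empirical_cdf(4, tab), 1)    # ties included per the printed form
  expect_equal(empirical_cdf(9, tab), 1)
  # strict variant sits below at atoms
  expect_equal(empirical_cdf(4, tab, ties = "strict"), 0.75)
  expect_equal(empirical_cdf(2, tab, ties = "strict"), 0.25)

  set.seed(12)
  tab2 <- calibrate(property_spec("v", function(r) r$v),
                    lapply(rexp(50), function(v) list(v = v)))
  qs <- seq(0, 8, length.out = 1000)
  cdfs <- vapply(qs, empirical_cdf, numeric(1), table = tab2)
  expect_true(all(diff(cdfs) >= 0))
  expect_true(all(cdfs >= 0 & cdfs <= 1))
})

test_that("calibration is deterministic and concentrates for uniform draws", {
  set.seed(13)
  recs <- lapply(runif(100), function(v) list(v = v))
  sp <- property_spec("v", function(r) r$v)
  t1 <- calibrate(sp, recs)
  t2 <- calibrate(sp, recs)
  expect_identical(t1$samples, t2$samples)
  expect_equal(t1$N, 100L)
  # binomial concentration: CDF(0.5) within [0.35, 0.65] for n = 100
  expect_gt(empirical_cdf(0.5, t1), 0.35)
  expect_lt(empirical_cdf(0.5, t1), 0.65)
  # single record
  t3 <- calibrate(sp, list(list(v = 2)))
  expect_equal(empirical_cdf(2, t3), 1)
  expect_error(calibrate(sp, list()), "nonempty")
})

test_that("labels partition [0,1] exactly as the half-open bands prescribe", {
  pol <- label_policy(0.95, 0, 0.05)
  expect_equal(assign_label(0.5, pol), "pass")
  expect_equal(assign_label(0.96, pol), "fail")   # warning band [0.95, 0.95) empty
  expect_equal(assign_label(0.95, pol), "fail")
  pol2 <- label_policy(0.8, 0.15, 0.05)
  expect_equal(assign_label(0.85, pol2), "warning")
  expect_equal(assign_label(0.8, pol2), "warning")
  expect_equal(assign_label(0.95, pol2), "fail")
  # exactly one label everywhere, including boundaries
  for (cdf in c(0, 0.25, 0.8 - 1e-12, 0.8, 0.95 - 1e-12, 0.95, 1)) {
    lab <- assign_label(cdf, pol2)
    expect_true(lab %in% c("pass", "warning", "fail"))
  }
  expect_error(assign_label(1.2, pol), "\\[0, 1\\]")
  expect_error(label_policy(0.5, 0.2, 0.2), "sum to 1")
})

test_that("certify produces one certificate per property and flags outliers", {
  sp1 <- property_spec("a", function(r) r$a)
  sp2 <- property_spec("b", function(r) r$b)
  set.seed(14)
  recs <- lapply(1:101, function(i) list(a = runif(1), b = rexp(1)))
  tabs <- list(a = calibrate(sp1, recs), b = calibrate(sp2, recs))
  med <- list(a = stats::median(tabs$a$samples), b = stats::median(tabs$b$samples))
  ct <- certify(med, list(sp1, sp2), tabs)
  expect_equal(ct$name, c("a", "b"))
  expect_true(all(ct$label == "pass"))
  expect_true(is_trustworthy(ct))

  # one property above the calibration maximum fails
  bad <- list(a = med$a, b = max(tabs$b$samples) + 1)
  ct2 <- certify(bad, list(sp1, sp2), tabs)
  expect_equal(ct2$label[ct2$name == "b"], "fail")
  expect_false(is_trustworthy(ct2))

  expect_equal(nrow(certify(med, list(), tabs)), 0L)
  expect_error(certify(med, list(sp1), tabs["b"]), "no calibration table")
})

test_that("values tied with calibration mass rank with it, not above it", {
  # all-zero constraint distances: the certificate must pass, exactly the
  # by-construction behaviour of a constraint-satisfying model
  sp <- property_spec("box", function(r) r$v)
  tab <- list(box = calibrate(sp, lapply(rep(0, 50), function(v) list(v = v))))
  ct <- certify(list(v = 0), list(sp), tab, label_policy(0.95, 0, 0.05))
  expect_equal(ct$label, "pass")
  expect_equal(ct$cdf, 0)
  # but a strictly larger value still fails
  ct2 <- certify(list(v = 1e-9), list(sp), tab, label_policy(0.95, 0, 0.05))
  expect_equal(ct2$label, "fail")
})

test_that("pass rate under continuous calibration approximates p_pass", {
  set.seed(15)
  sp <- property_spec("v", function(r) r$v)
  tab <- list(v = calibrate(sp, lapply(rexp(500), function(v) list(v = v))))
  labs <- vapply(rexp(1000), function(v)
    certify(list(v = v), list(sp), tab, label_policy(0.9, 0, 0.1))$label,
    character(1))
  p <- mean(labs == "pass")
  expect_lt(abs(p - 0.9), 3 * sqrt(0.9 * 0.1 / 1000) + 1 / 500)
})

test_that("certificates serialize to JSON with their policy", {
  sp <- property_spec("v", function(r) r$v)
  tab <- list(v = calibrate(sp, lapply(1:20, function(v) list(v = v))))
  ct <- certify(list(v = 5), list(sp), tab)
  path <- tempfile(fileext = ".json")
  write_certificates(ct, label_policy(), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$certificates$name, "v")
  expect_equal(back$policy$p_pass, 0.95)
  expect_true(is.logical(back$trustworthy))
})
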
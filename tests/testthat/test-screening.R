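test_that("desirability is a normalised, unimodal double sigmoid", {
  p <- c(a = 0.2, b = 10, c = 5, d = 2, e = 1.5, f = 1.2)
  xs <- seq(-40, 50, by = 0.01)
  vals <- desirability(xs, p)
  expect_true(all(vals > 0 & vals <= 1))
  expect_equal(max(vals), 1, tolerance = 1e-6)       # peak normalised to 1
  peak <- xs[which.max(vals)]
  left <- vals[xs < peak - 1]
  right <- vals[xs > peak + 1]
  expect_true(all(diff(left) > -1e-12))               # rises to the peak
  expect_true(all(diff(right) < 1e-12))               # falls after it
  # plateaus at the extremes
  expect_lt(desirability(-1e6, p), desirability(peak, p))
  expect_lt(desirability(1e6, p), desirability(peak, p))
})

test_that("symmetric parameters give a symmetric desirability", {
  p <- c(a = 0.1, b = 5, c = 3, d = 0, e = 0.8, f = 0.8)
  for (t in c(0.5, 1, 2.5, 7)) {
    expect_equal(desirability(3 + t, p), desirability(3 - t, p),
                 tolerance = 1e-10)
  }
})

test_that("published MW desirability matches a direct evaluation of the form", {
  # independent re-evaluation of the closed form at the same coefficients
  a <- 2.817065973; b <- 392.5754953; c <- 290.7489764; d <- 2.419764353
  e <- 49.22325677; f <- 65.37051707; dmax <- 104.9805561
  x <- 300
  raw <- a + (b / (1 + exp(-(x - c + d / 2) / e))) *
    (1 - 1 / (1 + exp(-(x - c - d / 2) / f)))
  expect_equal(desirability(300, "MW"), raw / dmax, tolerance = 1e-12)
})

test_that("degenerate sigmoid coefficients are rejected", {
  expect_error(desirability(1, c(a = 0, b = 1, c = 0, d = 0, e = 0, f = 1)),
               "Degenerate")
  expect_error(desirability(1, c(a = 0, b = 1, c = 0, d = 0, e = 1, f = 0)),
               "Degenerate")
  expect_error(desirability(1, "NOPE"), "Unknown descriptor")
})

test_that("QED is the weighted geometric mean of the desirabilities", {
  d <- list(MW = 320, ALOGP = 2.2, HBA = 4, HBD = 1, TPSA = 75,
            ROTB = 4, AROM = 2, ALERTS = 0)
  des <- vapply(names(d), function(nm) desirability(d[[nm]], nm), numeric(1))
  for (mode in c("weighted", "unweighted", "max")) {
    w <- netpharm:::QED_WEIGHTS[[mode]]
    expected <- exp(sum(w * log(des)) / sum(w))
    got <- qed_score(d$MW, d$ALOGP, d$HBA, d$HBD, d$TPSA, d$ROTB, d$AROM,
                     d$ALERTS, mode = mode)
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # weighted and unweighted genuinely differ here
  expect_false(isTRUE(all.equal(
    qed_score(320, 2.2, 4, 1, 75, 4, 2, 0, mode = "weighted"),
    qed_score(320, 2.2, 4, 1, 75, 4, 2, 0, mode = "unweighted")
  )))
})

test_that("QED is scale-free in weights and monotone in each descriptor's desirability", {
  w <- netpharm:::QED_WEIGHTS$weighted
  q1 <- qed_score(320, 2.2, 4, 1, 75, 4, 2, 0, weights = w)
  q2 <- qed_score(320, 2.2, 4, 1, 75, 4, 2, 0, weights = w * 7.3)
  expect_equal(q1, q2, tolerance = 1e-12)

  # moving MW toward the desirability peak (holding the rest fixed) never
  # decreases the score
  mw_grid <- c(800, 600, 450, 305)  # increasing MW desirability
  des <- desirability(mw_grid, "MW")
  expect_true(all(diff(des) > 0))
  qeds <- vapply(mw_grid, function(mw) qed_score(mw, 2.2, 4, 1, 75, 4, 2, 0),
                 numeric(1))
  expect_true(all(diff(qeds) > 0))

  expect_error(qed_score(300, 2, 4, 1, 70, 3, 2, 0,
                         weights = setNames(rep(0, 8), netpharm:::QED_DESCRIPTORS)),
               "at least one positive")
})

test_that("Veber's rule uses inclusive bounds", {
  expect_true(veber_pass(rotb = 10, tpsa = 140))
  expect_false(veber_pass(rotb = 11, tpsa = 50))
  expect_false(veber_pass(rotb = 3, tpsa = 141))
  expect_equal(veber_pass(c(10, 11), c(140, 10)), c(TRUE, FALSE))
  expect_error(veber_pass(rotb = 3, tpsa = NULL), "tpsa")
  expect_error(veber_pass(rotb = NA, tpsa = 100), "rotb")
})

test_that("EAC selection is an inclusive conjunction, idempotent and monotone", {
  tbl <- tibble::tibble(
    compound_id = c("a", "b", "c", "d"),
    qed = c(0.30, 0.95, 0.29999, 0.8),
    ob_pass = c(TRUE, FALSE, TRUE, TRUE)
  )
  out <- select_eac(tbl)
  expect_equal(out$is_eac, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$compound_id, tbl$compound_id)   # order preserved
  expect_identical(select_eac(out), out)           # idempotent

  # raising the cutoff never adds compounds
  cuts <- c(0, 0.2, 0.3, 0.5, 0.9, 1)
  sel <- lapply(cuts, function(ct) which(select_eac(tbl, ct)$is_eac))
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(sel[[i]] %in% sel[[i - 1]]))
  }

  expect_equal(nrow(select_eac(tbl[0, ])), 0L)     # empty in, empty out
  expect_error(select_eac(tbl, qed_cutoff = 1.5), "0, 1")
  expect_error(select_eac(tbl[, c("compound_id", "qed")]), "ob_pass")
})

test_that("screen_compounds scores, flags and summarises a descriptor table", {
  tbl <- tibble::tibble(
    compound_id = c("c1", "c2"),
    name = c("drug-like", "veber-fail"),
    MW = c(320, 320), ALOGP = c(2.1, 2.1), HBA = c(5, 5), HBD = c(2, 2),
    TPSA = c(80, 80), ROTB = c(3, 14), AROM = c(2, 2), ALERTS = c(0, 0)
  )
  out <- screen_compounds(tbl)
  expect_s3_class(out, "np_screen")
  expect_equal(out$ob_pass, c(TRUE, FALSE))
  expect_equal(out$is_eac, c(TRUE, FALSE))
  expect_true(all(out$qed > 0 & out$qed <= 1))
  g <- glance(out)
  expect_equal(g$n_eac, 1L)
  expect_equal(g$qed_mode, "weighted")

  # lower-case headers are accepted; missing descriptors named in the error
  names(tbl) <- tolower(names(tbl))
  expect_equal(screen_compounds(tbl)$is_eac, c(TRUE, FALSE))
  expect_error(screen_compounds(tbl[, -4]), "ALOGP")
})

test_that("QED agrees with the RDKit reference on standard drugs", {
  got_w <- with(qed_reference,
                qed_score(MW, ALOGP, HBA, HBD, TPSA, ROTB, AROM, ALERTS,
                          mode = "weighted"))
  got_u <- with(qed_reference,
                qed_score(MW, ALOGP, HBA, HBD, TPSA, ROTB, AROM, ALERTS,
                          mode = "unweighted"))
  expect_equal(got_w, qed_reference$qed_weighted, tolerance = 1e-6)
  expect_equal(got_u, qed_reference$qed_unweighted, tolerance = 1e-6)
})
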
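test_that("RMSD handles identity, uniform translation, and relabeled symmetry", {
  m <- toy_molecule()
  expect_identical(rmsd(m, m), 0)
  shifted <- coords(m) + matrix(rep(c(3, 4, 0), each = 4), ncol = 3)
  for (mode in c("all_atom", "heavy_atom", "heavy_symmetry")) {
    expect_equal(rmsd(m, shifted, mode = mode), 5.0, tolerance = 1e-12,
                 info = mode)
  }
  # swapping two like-element atoms: plain RMSD sees it, symmetry mode forgives
  at <- data.frame(name = c("C1", "C2", "O1"), type = c("C.3", "C.3", "O.2"),
                   x = c(0, 3, 1.5), y = c(0, 0, 1), z = 0,
                   charge = 0, stringsAsFactors = FALSE)
  ref <- assign_vdw_parameters(molecule("sym", at))
  swapped <- coords(ref)[c(2, 1, 3), ]
  expect_gt(rmsd(ref, swapped, mode = "all_atom"), 2)
  expect_equal(rmsd(ref, swapped, mode = "heavy_symmetry"), 0,
               tolerance = 1e-12)
  expect_error(rmsd(ref, swapped[1:2, ]), "mismatch")
})

test_that("RMSD with fixed correspondence behaves like a metric on fixtures", {
  a <- toy_molecule("a")
  b <- set_coords(a, coords(a) + matrix(rnorm(12, sd = 1), ncol = 3))
  c3 <- set_coords(a, coords(a) + matrix(rnorm(12, sd = 1), ncol = 3))
  expect_equal(rmsd(a, b), rmsd(b, coords(a)), tolerance = 1e-12)
  expect_lte(rmsd(a, coords(c3)),
             rmsd(a, coords(b)) + rmsd(b, coords(c3)) + 1e-12)
  expect_gt(rmsd(a, coords(b)), 0)
})

test_that("ROC construction matches the hand-enumerated worked example", {
  scr <- data.frame(label = c("active", "decoy", "active", "decoy"),
                    E_total = c(-10, -8, -6, -4))
  r <- roc_curve(scr)
  expect_true(all(c(diff(r$fpr), diff(r$tpr)) >= 0))
  expect_true(all(apply(rbind(c(0, 0.5), c(0.5, 1), c(1, 1)), 1, function(p) {
    any(abs(r$fpr - p[1]) < 1e-12 & abs(r$tpr - p[2]) < 1e-12)
  })))
  expect_equal(roc_auc(scr), 75)
  # perfect separation passes through (0, 1)
  perf <- data.frame(label = c("active", "active", "decoy"),
                     E_total = c(-9, -8, -1))
  rp <- roc_curve(perf)
  expect_true(any(rp$fpr == 0 & rp$tpr == 1))
  expect_error(roc_curve(data.frame(label = c("active", "active"),
                                    E_total = c(-1, -2))), "at least one")
})

test_that("label-shuffled screens score near 50% AUC and flipping labels mirrors it", {
  set.seed(14)
  aucs <- replicate(8, {
    scr <- data.frame(label = sample(rep(c("active", "decoy"), c(40, 160))),
                      E_total = seq_len(200))
    roc_auc(scr)
  })
  # null sd of AUC here is ~5 percentage points; stay within ~3 sd
  expect_lt(max(abs(aucs - 50)), 15)
  scr <- data.frame(label = sample(rep(c("active", "decoy"), c(30, 90))),
                    E_total = rnorm(120))
  flip <- scr
  flip$label <- ifelse(scr$label == "active", "decoy", "active")
  expect_equal(roc_auc(scr) + roc_auc(flip), 100, tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  scr <- data.frame(label = sample(rep(c("active", "decoy"), c(25, 75))),
                    E_total = rnorm(100))
  ref <- suppressMessages(
    pROC::auc(pROC::roc(response = scr$label == "active",
                        predictor = -scr$E_total, direction = "<"))
  )
  expect_equal(roc_auc(scr), 100 * as.numeric(ref), tolerance = 1e-9)
})

test_that("adjusted LogAUC hits its analytic anchors", {
  expect_equal(logauc_random_area(1e-3),
               100 * (1 - 1e-3) / (3 * log(10)), tolerance = 1e-9)
  expect_equal(round(logauc_random_area(1e-3), 1), 14.5)
  n <- 1500
  alternating <- data.frame(label = rep(c("active", "decoy"), n),
                            E_total = seq_len(2 * n))
  expect_equal(adjusted_logauc(alternating), 0, tolerance = 0.2)
  perfect <- data.frame(label = c(rep("active", 5), rep("decoy", 2000)),
                        E_total = seq_len(2005))
  expect_equal(adjusted_logauc(perfect), 100 - logauc_random_area(),
               tolerance = 1e-6)
  anti <- data.frame(label = c(rep("decoy", 2000), rep("active", 5)),
                     E_total = seq_len(2005))
  expect_equal(adjusted_logauc(anti), -logauc_random_area(),
               tolerance = 1e-6)
})

test_that("adjusted LogAUC is invariant to monotone energy transforms", {
  set.seed(5)
  scr <- data.frame(label = sample(rep(c("active", "decoy"), c(20, 80))),
                    E_total = rnorm(100))
  base <- adjusted_logauc(scr)
  expect_identical(adjusted_logauc(transform(scr, E_total = 3 * E_total + 7)),
                   base)
  expect_identical(adjusted_logauc(transform(scr, E_total = exp(E_total / 4))),
                   base)
})

test_that("net-charge histograms follow the ranking and the generator bookkeeping", {
  scr <- data.frame(label = rep("decoy", 6),
                    E_total = c(-9, -8, -7, -3, -2, -1),
                    net_charge = c(0, -1, 0, -2, -2, -3))
  top <- charge_distribution(scr, top_fraction = 0.5)
  expect_equal(as.integer(top[c("-1", "0")]), c(1L, 2L))
  all_of <- charge_distribution(scr, top_fraction = 1)
  expect_equal(sum(all_of), 6)
  neutral <- data.frame(label = "decoy", E_total = -1, net_charge = 0)
  expect_equal(names(charge_distribution(neutral, 1)), "0")
  # generator cross-check on a seeded screen set
  spec <- fixture_spec(seed = 6, n_active = 2, decoy_ratio = 10)
  ss <- make_screen_set(spec)
  drawn <- table(round(sapply(ss$decoys, net_charge)))
  expect_equal(as.integer(drawn[names(table(ss$decoy_net_charges))]),
               as.integer(table(ss$decoy_net_charges)))
})
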
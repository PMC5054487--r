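test_that("descriptors of reference structures match the Ertl fragment constants", {
  d <- compute_descriptors(
    c("chorismate", "anthranilate", "indole", "tryptophan", "butane"),
    c("C(=C)(OC1C=CC(=CC1O)C(=O)[O-])C(=O)[O-]",
      "Nc1ccccc1C(=O)[O-]",
      "c1ccc2c(c1)cc[nH]2",
      "c1ccc2c(c1)c(c[nH]2)C[C@@H](C(=O)O)N",
      "CCCC"))
  expect_equal(d$tpsa, c(109.72, 66.15, 15.79, 79.11, 0), tolerance = 1e-4)
  expect_equal(d$mw[3], 117.15, tolerance = 5e-4)
  expect_equal(d$mw[4], 204.228, tolerance = 2e-4)
  expect_equal(d$mw[2], 136.13, tolerance = 5e-4)
  # an apolar alkane has no donors or acceptors
  expect_equal(d$hbd[5], 0)
  expect_equal(d$hba[5], 0)
})

test_that("TPSA is additive over isolated carboxylate fragments", {
  # k isolated carboxylates and no other polar atoms: k x 40.13
  smis <- c("CCCC(=O)[O-]",
            "[O-]C(=O)CCCC(=O)[O-]",
            "[O-]C(=O)CC(CC(=O)[O-])CC(=O)[O-]")
  d <- compute_descriptors(paste0("acid", 1:3), smis)
  expect_equal(d$tpsa, 40.13 * (1:3), tolerance = 1e-6)
})

test_that("descriptor computation is deterministic and rejects bad SMILES", {
  a <- compute_descriptors("indole", "c1ccc2c(c1)cc[nH]2")
  b <- compute_descriptors("indole", "c1ccc2c(c1)cc[nH]2")
  expect_identical(a, b)
  expect_error(compute_descriptors("broken", "c1ccc("), "broken")
})

test_that("the default ruleset reproduces the full reference classification", {
  tab <- classify_permeability(compute_pathway_descriptors(trp_pathway_fixture()))
  expect_identical(tab$perm_class_1,
                   c("MH", "MH", "ML", "ML", "ML", "H", "MH"))
  expect_identical(tab$perm_class_3,
                   c("H", "H", "ML", "ML", "MH", "H", "ML"))
})

test_that("rising TPSA never makes a metabolite more permeable", {
  rs <- permeability_ruleset()
  grid <- expand.grid(tpsa = seq(0, 300, by = 7.3),
                      logp = c(-3, 0.5, 1.2, 2.5), mw = c(120, 350, 600))
  for (lp in unique(grid$logp)) for (w in unique(grid$mw)) {
    sub <- grid[grid$logp == lp & grid$mw == w, ]
    rec <- data.frame(tpsa = sub$tpsa, logp_primary = sub$logp, mw = sub$mw)
    cl <- classify_permeability(rec, rs)
    r1 <- metsplit:::.class_rank(cl$perm_class_1, rs)
    r3 <- metsplit:::.class_rank(cl$perm_class_3, rs)
    expect_true(all(diff(r1) <= 0))
    expect_true(all(diff(r3) <= 0))
  }
})

test_that("a descriptor exactly on a threshold falls to the less permeable class", {
  rs <- permeability_ruleset()
  thr <- rs$one_param$tpsa[[1]]
  rec <- data.frame(tpsa = c(thr - 1e-9, thr), logp_primary = -5,
                    mw = 100)
  cl <- classify_permeability(rec, rs)
  expect_identical(cl$perm_class_1, c("H", "MH"))
  expect_false(cl$threshold_tie[1])
  expect_true(cl$threshold_tie[2])
})

test_that("classification refuses records without descriptors", {
  expect_error(classify_permeability(data.frame(name = "x")),
               "compute_descriptors")
})

test_that("the tryptophan pathway splits at anthranilate once channeling is known", {
  tab <- classify_permeability(compute_pathway_descriptors(trp_pathway_fixture()))
  bp <- predict_breaking_point(tab)
  expect_identical(bp$name, "Anthranilate")
  expect_identical(bp$position, 2L)
  # ignoring the channeling constraint, indole and anthranilate share the top
  # class and indole wins the TPSA tie-break
  bp2 <- predict_breaking_point(tab, ignore_channeling = TRUE)
  expect_identical(bp2$name, "Indole")
  expect_identical(sort(unique(tab$perm_class_3[tab$position %in% c(2, 6)])),
                   "H")
  # with every intermediate channeled there is no prediction
  allch <- tab
  allch$channeled <- TRUE
  res <- predict_breaking_point(allch)
  expect_true(is.na(res$position))
})

test_that("a unique low-TPSA intermediate is always the predicted split", {
  rec <- data.frame(name = letters[1:5], position = 1:5, channeled = FALSE,
                    tpsa = c(200, 180, 25, 190, 210),
                    logp_primary = 0, mw = c(300, 310, 120, 320, 330))
  bp <- predict_breaking_point(rec)
  expect_identical(bp$position, 3L)
})
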
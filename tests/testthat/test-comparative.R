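test_that("genus thermal preference is the pooled mean of band climates", {
  recs <- data.frame(gradient_id = c("G1", "G1", "G2"),
                     genus = c("A", "A", "B"),
                     elevation_m = c(500, 1500, 250), class = "all",
                     stringsAsFactors = FALSE)
  bs <- data.frame(gradient_id = c("G1", "G1", "G2"),
                   elevation_m = c(500, 1500, 250), class = "all",
                   bio1 = c(10, 14, 21), stringsAsFactors = FALSE)
  pref <- genus_temp_pref(recs, bs, "bio1")
  expect_equal(unname(pref["A"]), 12)
  expect_equal(unname(pref["B"]), 21)

  # genera with no climate-bearing record are excluded and logged
  bs$bio1[3] <- NA
  pref2 <- genus_temp_pref(recs, bs, "bio1")
  expect_false("B" %in% names(pref2))
  expect_equal(attr(pref2, "dropped"), "B")

  # group-by oracle on synthetic data
  d <- synth_dataset(synth_config(seed = 17, n_tips = 50, n_gradients = 3))
  prof <- rate_table(d$tree, d$genus_table)
  b <- attach_climate(band_stats(d$records, prof, class_filter = "all"),
                      fit_climate_models(d$climate_points))
  recs2 <- dedupe(d$records[d$records$class == "all", ])
  pref3 <- genus_temp_pref(recs2, b, "bio1")
  key_b <- paste(b$gradient_id, b$elevation_m)
  vals <- b$bio1[match(paste(recs2$gradient_id, recs2$elevation_m), key_b)]
  oracle <- tapply(vals, recs2$genus, mean)
  expect_equal(pref3[names(oracle)], oracle[names(oracle)],
               ignore_attr = TRUE)
})

test_that("the lambda transform rescales exactly the shared paths", {
  tree <- simulate_chronogram(synth_config(seed = 18, n_tips = 4))
  V1 <- lambda_transform(tree, 1)
  expect_equal(V1, ape::vcv.phylo(tree))
  V0 <- lambda_transform(tree, 0)
  expect_equal(V0, diag(diag(ape::vcv.phylo(tree))), ignore_attr = TRUE)
  Vh <- lambda_transform(tree, 0.5)
  off <- row(V1) != col(V1)
  expect_equal(Vh[off], V1[off] / 2)
  expect_equal(diag(Vh), diag(V1))
  expect_error(lambda_transform(tree, 1.2), "lambda")
})

test_that("lambda ML fit matches an independent implementation and a grid", {
  cfg <- synth_config(seed = 19, n_tips = 60, trait_lambda = 0.7)
  tree <- simulate_chronogram(cfg)
  x <- simulate_trait(tree, cfg)
  fit <- pagel_lambda(tree, x)
  expect_gte(fit$lambda, 0)
  expect_lte(fit$lambda, 1)
  expect_gte(fit$logLik, fit$logLik0)
  expect_gte(fit$logLik, fit$logLik1)
  expect_gte(fit$lr_statistic, 0)

  # independent route: phytools' lambda ML
  ps <- phytools::phylosig(tree, x, method = "lambda")
  expect_equal(fit$lambda, ps$lambda, tolerance = 1e-4)
  expect_equal(fit$logLik, ps$logL, tolerance = 1e-6)

  # profile maximum matches a grid search within 0.01 logL units
  V1 <- ape::vcv.phylo(tree)
  grid <- vapply(seq(0, 1, by = 0.01), function(lam) {
    V <- lam * V1; diag(V) <- diag(V1)
    n <- length(x)
    iV <- solve(V)
    mu <- sum(iV %*% x) / sum(iV)
    s2 <- as.numeric(t(x - mu) %*% iV %*% (x - mu)) / n
    -n / 2 * log(2 * pi * s2) - determinant(V)$modulus / 2 - n / 2
  }, 0)
  expect_lte(max(grid) - fit$logLik, 0.01)
})

test_that("an iid trait shows no phylogenetic signal", {
  tree <- simulate_chronogram(synth_config(seed = 20, n_tips = 100))
  set.seed(20)
  x <- setNames(rnorm(100, 10, 2), tree$tip.label)
  fit <- pagel_lambda(tree, x)
  expect_lte(fit$lambda, 0.15)
})

test_that("BM ancestral states solve the worked examples", {
  # two-tip closed form: inverse-branch-length weighting
  t2 <- ape::read.tree(text = "(A:1,B:2);")
  asr2 <- asr_bm(t2, c(A = 0, B = 3))
  expect_equal(asr2$estimate, 1.0)

  # constant tips reconstruct the constant with positive variance
  tree <- simulate_chronogram(synth_config(seed = 22, n_tips = 12))
  xc <- setNames(rep(7.5, 12), tree$tip.label)
  asrc <- asr_bm(tree, xc)
  expect_equal(asrc$estimate, rep(7.5, tree$Nnode))
  expect_equal(nrow(asrc), tree$Nnode)
  expect_true(all(asrc$ci_low <= asrc$estimate & asrc$estimate <= asrc$ci_high))
})

test_that("ancestral estimates match the independent ML route on random trees", {
  for (seed in c(23, 24, 25)) {
    cfg <- synth_config(seed = seed, n_tips = 8)
    tree <- simulate_chronogram(cfg)
    x <- simulate_trait(tree, cfg)
    asr <- asr_bm(tree, x)
    fa <- phytools::fastAnc(tree, x)
    expect_equal(asr$estimate, as.numeric(fa), tolerance = 1e-8)
    # convexity: node estimates lie inside the tip range
    expect_true(all(asr$estimate >= min(x) - 1e-9 &
                      asr$estimate <= max(x) + 1e-9))
  }
})

test_that("ancestral states are shift-equivariant and scale linearly", {
  cfg <- synth_config(seed = 26, n_tips = 20)
  tree <- simulate_chronogram(cfg)
  x <- simulate_trait(tree, cfg)
  a0 <- asr_bm(tree, x)
  a_shift <- asr_bm(tree, x + 11)
  expect_equal(a_shift$estimate, a0$estimate + 11)
  a_scale <- asr_bm(tree, 3 * x)
  expect_equal(a_scale$estimate, 3 * a0$estimate)
})

test_that("annotated Newick output carries the node estimates", {
  cfg <- synth_config(seed = 27, n_tips = 10)
  tree <- simulate_chronogram(cfg)
  x <- simulate_trait(tree, cfg)
  asr <- asr_bm(tree, x)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_asr_newick(asr, path)
  back <- ape::read.tree(path)
  # node numbering may change on serialization; the label set must not
  expect_equal(sort(as.numeric(back$node.label)),
               sort(signif(asr$estimate, 6)))
})
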
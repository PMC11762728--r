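test_that("dedupe keeps one record per genus per band per class", {
  r <- toy_records()
  doubled <- rbind(r, r)
  expect_equal(nrow(dedupe(doubled)), nrow(r))
  # same genus in two bands stays twice
  expect_equal(sum(dedupe(r)$genus == "A" & dedupe(r)$gradient_id == "G1"), 2L)
})

test_that("band statistics reproduce the worked means and relative scales", {
  bs <- band_stats(toy_records(), toy_profiles())
  g1_500 <- bs[bs$gradient_id == "G1" & bs$elevation_m == 500, ]
  expect_equal(g1_500$div_elev, mean(c(0, 0.1, 0.2)))
  expect_equal(g1_500$age_elev, 60)
  expect_equal(g1_500$richness, 3)

  recs <- data.frame(gradient_id = "G", genus = c("A", "B", "C"),
                     elevation_m = c(500, 1000, 2000), class = "all",
                     stringsAsFactors = FALSE)
  bs2 <- band_stats(recs, toy_profiles())
  expect_equal(bs2$rel_elev, c(25, 50, 100))
  expect_true(all(bs2$rel_rich > 0 & bs2$rel_rich <= 100))
})

test_that("band statistics equal a brute-force group-by oracle", {
  d <- synth_dataset(synth_config(seed = 21, n_tips = 60, n_gradients = 5))
  prof <- rate_table(d$tree, d$genus_table)
  recs <- d$records[d$records$class == "all", ]
  bs <- band_stats(recs, prof)

  merged <- merge(dedupe(recs), prof, by = "genus")
  oracle <- aggregate(cbind(div_rate, stem_age_ma) ~ gradient_id + elevation_m,
                      data = merged, FUN = mean)
  key_o <- paste(oracle$gradient_id, oracle$elevation_m)
  key_b <- paste(bs$gradient_id, bs$elevation_m)
  idx <- match(key_b, key_o)
  expect_false(anyNA(idx))
  expect_equal(bs$div_elev, oracle$div_rate[idx])
  expect_equal(bs$age_elev, oracle$stem_age_ma[idx])
  rich <- aggregate(genus ~ gradient_id + elevation_m, data = merged,
                    FUN = function(g) length(unique(g)))
  expect_equal(bs$richness, rich$genus[match(key_b,
               paste(rich$gradient_id, rich$elevation_m))])

  # invariant to record order and duplication
  shuffled <- recs[sample(nrow(recs)), ]
  bs_shuf <- band_stats(rbind(shuffled, shuffled), prof)
  expect_equal(bs_shuf, bs, ignore_attr = TRUE)
})

test_that("records without a genus profile are dropped and logged", {
  r <- toy_records()
  r$genus[1] <- "Unknownia"
  bs <- band_stats(r, toy_profiles())
  dropped <- attr(bs, "dropped")
  expect_equal(nrow(dropped), 1L)
  expect_equal(dropped$genus, "Unknownia")
  expect_equal(dropped$reason, "no_genus_profile")
})

test_that("one-way ANOVA matches the hand table and handles degeneracy", {
  res <- one_way_anova(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 3L)
  # hand table: SSB = 16 (MSB 8), SSW = 1.5 (MSW 0.5) -> F = 16
  expect_equal(res$F, 16)
  oracle <- anova(lm(y ~ g, data = data.frame(
    y = c(1, 2, 3, 4, 5, 6), g = factor(rep(letters[1:3], each = 2)))))
  expect_equal(res$F, oracle$`F value`[1])
  expect_equal(res$p, oracle$`Pr(>F)`[1])

  same <- one_way_anova(list(a = 1:3, b = 1:3, c = 1:3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  sep <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p, 0)

  ident <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(ident$F, 0)
  expect_equal(ident$p, 1)
})

test_that("ANOVA F is shift- and scale-invariant", {
  set.seed(1)
  g <- list(a = rnorm(8), b = rnorm(10, 1), c = rnorm(6, -1))
  f0 <- one_way_anova(g)$F
  expect_equal(one_way_anova(lapply(g, `+`, 100))$F, f0)
  expect_equal(one_way_anova(lapply(g, `*`, 3.7))$F, f0)
})

test_that("Tukey-Kramer differences behave on degenerate and shifted groups", {
  same <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$diff, 0)
  expect_true(same$p_adj > 0.05)

  set.seed(7)
  g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 10))
  tk <- tukey_hsd(g)
  sig <- tk$p_adj < 0.05
  expect_setequal(tk$pair[sig], c("c-a", "c-b"))
  expect_false(sig[tk$pair == "b-a"])

  ident <- tukey_hsd(list(a = c(5, 5), b = c(5, 5)))
  expect_equal(ident$diff, 0)
  expect_equal(ident$p_adj, 1)
})

test_that("Tukey adjusted p is at least the unadjusted pooled t-test p", {
  # the studentized-range adjustment over k groups can only inflate the
  # p of the pooled two-group comparison on the same error variance
  set.seed(12)
  for (rep in 1:10) {
    g <- list(a = rnorm(10), b = rnorm(12, rnorm(1)), c = rnorm(8, rnorm(1)))
    tk <- tukey_hsd(g)
    y <- unlist(g); gr <- factor(rep(names(g), lengths(g)))
    msw <- sum(tapply(y, gr, function(v) sum((v - mean(v))^2))) /
      (length(y) - 3)
    for (i in seq_len(nrow(tk))) {
      pair <- strsplit(tk$pair[i], "-")[[1]]
      se <- sqrt(msw * (1 / length(g[[pair[1]]]) + 1 / length(g[[pair[2]]])))
      tt <- abs(mean(g[[pair[1]]]) - mean(g[[pair[2]]])) / se
      pt <- 2 * pt(tt, df = length(y) - 3, lower.tail = FALSE)
      expect_gte(tk$p_adj[i] + 1e-10, pt)
    }
  }
})

test_that("group_comparison gates the post-hoc test on ANOVA significance", {
  # deterministic fixtures: negligible vs overwhelming group separation
  base <- c(-1.5, -0.5, 0.5, 1.5)
  g_null <- list(a = base, b = base + 0.01, c = base - 0.01)
  g_alt <- list(a = base, b = base + 0.01, c = base + 50)
  expect_null(group_comparison(g_null)$tukey)
  expect_false(is.null(group_comparison(g_alt)$tukey))
})
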
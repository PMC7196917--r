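test_that("enrichment score reproduces hand-enumerated running sums", {
  r <- as_ranked_list(setNames(c(3, 2, 1, -1, -2), paste0("g", 1:5)))

  up <- enrichment_score(r, c("g1", "g3"))
  expect_equal(up$es, 0.75)
  expect_equal(up$running_sum, c(0.75, 0.75 - 1 / 3, 2 / 3, 1 / 3, 0),
    tolerance = 1e-12
  )
  expect_equal(up$leading_edge, "g1")

  down <- enrichment_score(r, c("g4", "g5"))
  expect_equal(down$es, -1)
  expect_equal(down$leading_edge, c("g4", "g5"))

  single <- enrichment_score(r, "g1")
  expect_equal(single$es, 1)

  expect_error(enrichment_score(r, paste0("g", 1:5)), "every ranked gene")
  expect_error(enrichment_score(r, "absent"), "no members")
})

test_that("running sum matches a direct-accumulation oracle", {
  set.seed(3)
  for (i in 1:20) {
    N <- sample(10:40, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    r <- as_ranked_list(setNames(scores, sprintf("x%02d", seq_len(N))))
    k <- sample(2:5, 1)
    set <- sample(names(r), k)
    for (w in c(0, 1)) {
      got <- enrichment_score(r, set, weight_exponent = w)
      ref <- oracle_es(unname(r), names(r) %in% set, w)
      expect_equal(got$es, ref$es, tolerance = 1e-12)
      expect_equal(got$running_sum, ref$running_sum, tolerance = 1e-12)
      expect_true(abs(got$es) <= 1 + 1e-12)
      if (w == 0) {
        expect_equal(got$running_sum[N], 0, tolerance = 1e-12)
      }
    }
  }
})

test_that("reversing the list and negating scores negates the ES", {
  set.seed(8)
  for (i in 1:10) {
    N <- 20
    scores <- sort(rnorm(N), decreasing = TRUE)
    r <- as_ranked_list(setNames(scores, sprintf("x%02d", seq_len(N))))
    set <- sample(names(r), 4)
    fwd <- enrichment_score(r, set)$es
    rev_r <- as_ranked_list(setNames(-unname(r), names(r)))
    bwd <- enrichment_score(rev_r, set)$es
    expect_equal(bwd, -fwd, tolerance = 1e-12)
  }
})

test_that("permutation null is reproducible and converges to enumeration", {
  r <- as_ranked_list(setNames(c(2, 1.5, 0.5, -1), paste0("g", 1:4)))
  n1 <- permutation_null(r, 2, n_perm = 200, seed = 10)
  n2 <- permutation_null(r, 2, n_perm = 200, seed = 10)
  expect_identical(n1, n2)
  expect_true(all(abs(n1$es) <= 1 + 1e-12))

  # N = 4, k = 2: the sampled distribution matches all C(4,2) subsets
  exact <- sort(oracle_exhaustive_null(unname(r), 2))
  big <- permutation_null(r, 2, n_perm = 6000, seed = 1)
  for (v in unique(exact)) {
    expect_equal(mean(big$es <= v + 1e-12), mean(exact <= v + 1e-12),
      tolerance = 0.05
    )
  }
  expect_error(permutation_null(r, 4, 10), "set_size")
  expect_error(permutation_null(r, 2, 0), "n_perm")
})

test_that("NES normalization and add-one nominal p", {
  expect_equal(
    nes_and_pvalue(0, list(es = rnorm(100))),
    list(nes = 0, p_nominal = 1)
  )
  null <- list(es = c(0.4, 0.5, 0.6, -0.3, -0.7)) # positive mean 0.5
  res <- nes_and_pvalue(0.75, null)
  expect_equal(res$nes, 1.5)
  expect_equal(res$p_nominal, 1 / 4) # 0 of 3 positive draws >= 0.75

  big_null <- list(es = abs(rnorm(10000)) / 20) # all same-sign, all below
  res2 <- nes_and_pvalue(0.9, big_null)
  expect_equal(res2$p_nominal, 1 / 10001)

  # no same-sign null values: reported as NES 0, p 1
  res3 <- nes_and_pvalue(-0.5, list(es = c(0.1, 0.2)))
  expect_equal(res3, list(nes = 0, p_nominal = 1))
  expect_error(nes_and_pvalue(1.5, null), "outside")
})

test_that("preranked GSEA table: FDR oracle and set-order invariance", {
  set.seed(15)
  scores <- sort(rnorm(40), decreasing = TRUE)
  r <- as_ranked_list(setNames(scores, sprintf("y%02d", 1:40)))
  sets <- list(
    top = names(r)[1:5], # extreme positive enrichment
    mid = names(r)[18:23],
    rand = sample(names(r), 6)
  )
  res <- gsea_preranked(r, sets, n_perm = 100, seed = 3, return_null = TRUE)
  expect_equal(res$set_name, names(sets))
  expect_gt(res$es[1], 0)
  expect_equal(sign(res$nes), sign(res$es))

  # direct FDR recomputation from the stored nulls
  nulls <- attr(res, "null")
  null_nes <- unlist(lapply(nulls, function(es) {
    out <- numeric(length(es))
    out[es > 0] <- es[es > 0] / mean(es[es > 0])
    out[es < 0] <- es[es < 0] / mean(abs(es[es < 0]))
    out
  }), use.names = FALSE)
  for (i in which(res$nes > 0)) {
    num <- sum(null_nes >= res$nes[i]) / sum(null_nes > 0)
    den <- sum(res$nes >= res$nes[i] & res$nes > 0) / sum(res$nes > 0)
    expect_gte(res$q_fdr[i] + 1e-12, min(1, num / den)) # monotonized >= raw
  }
  one <- gsea_preranked(r, sets["mid"], n_perm = 100, seed = 3,
    return_null = TRUE
  )
  es_null <- attr(one, "null")$mid
  sgn <- sign(one$es)
  nn <- es_null[sign(es_null) == sgn] / mean(abs(es_null[sign(es_null) == sgn]))
  raw <- min(1, mean(abs(nn) >= abs(one$nes)))
  expect_equal(one$q_fdr, raw, tolerance = 1e-12)

  # invariant to gene-set input order
  res_shuffled <- gsea_preranked(r, sets[c(3, 1, 2)], n_perm = 100, seed = 3)
  reord <- res_shuffled[match(res$set_name, res_shuffled$set_name), ]
  rownames(reord) <- NULL
  expect_equal(reord, res, ignore_attr = TRUE)

  # extreme positive set sits near the add-one floor
  top_only <- gsea_preranked(r, sets["top"], n_perm = 500, seed = 2)
  expect_lte(top_only$p_nominal, 5 / 500)
})

test_that("preranked GSEA agrees with an established implementation", {
  skip_if_not_installed("fgsea")
  set.seed(33)
  scores <- sort(rnorm(200), decreasing = TRUE)
  names(scores) <- sprintf("z%03d", 1:200)
  r <- as_ranked_list(scores)
  sets <- list(a = names(r)[c(1:10, 50:54)], b = names(r)[180:195])
  ours <- gsea_preranked(r, sets, n_perm = 2000, seed = 5)
  theirs <- suppressWarnings(
    fgsea::fgsea(sets, r, nPermSimple = 2000, scoreType = "std")
  )
  theirs <- theirs[match(ours$set_name, theirs$pathway), ]
  # the ES statistic is identical by construction; NES/p agree approximately
  expect_equal(ours$es, theirs$ES, tolerance = 1e-6)
  expect_equal(sign(ours$nes), sign(theirs$NES))
})
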
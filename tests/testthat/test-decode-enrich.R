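test_that("parcel means are exact, linear, and reject bad input", {
  m <- test_mesh3()
  parc <- build_parcellation(m, 50, seed = 1)
  V <- nrow(m$vertices)
  expect_equal(parcel_mean_map(rep(3, V), parc), rep(3, 50))
  # one-hot vertex map: only its parcel is nonzero, value 1/parcel_size
  onehot <- numeric(V); onehot[10] <- 1
  pm <- parcel_mean_map(onehot, parc)
  k <- parc$assignment[10]
  expect_equal(pm[k], 1 / parc$sizes[k])
  expect_equal(sum(pm != 0), 1L)
  set.seed(2)
  a <- rnorm(V); b <- rnorm(V)
  expect_equal(parcel_mean_map(a + b, parc),
               parcel_mean_map(a, parc) + parcel_mean_map(b, parc),
               tolerance = 1e-12)
  expect_error(parcel_mean_map(a[-1], parc), "match")
})

test_that("a gene whose map equals the input decodes with r = 1 and minimal p", {
  m <- test_mesh3()
  parc <- build_parcellation(m, 80, seed = 3)
  set.seed(4)
  map <- parcel_mean_map(smooth_vertex_map(m, rnorm(642), 20), parc)
  expr <- rbind(as.numeric(scale(map)),
                matrix(rnorm(5 * 80), 5))
  expr <- t(scale(t(expr)))
  rownames(expr) <- paste0("G", 1:6)
  atlas <- structure(list(genes = rownames(expr), expr = expr,
                          parcellation = parc, background = rownames(expr)),
                     class = "expression_atlas")
  dec <- spatial_decode(map, atlas, n_spins = 200, seed = 5)
  expect_equal(dec$r[1], 1, tolerance = 1e-10)
  expect_equal(dec$p_spin[1], min(dec$p_spin))
  expect_error(spatial_decode(rep(1, 80), atlas, n_spins = 200), "constant")
})

test_that("decoding is equivariant under a consistent parcel permutation", {
  m <- test_mesh3()
  parc <- build_parcellation(m, 60, seed = 6)
  set.seed(7)
  map <- parcel_mean_map(smooth_vertex_map(m, rnorm(642), 20), parc)
  expr <- t(scale(t(matrix(rnorm(8 * 60), 8))))
  rownames(expr) <- paste0("G", 1:8)
  atlas <- structure(list(genes = rownames(expr), expr = expr,
                          parcellation = parc, background = rownames(expr)),
                     class = "expression_atlas")
  perm <- sample(60)
  parc2 <- parc
  parc2$centroids <- parc$centroids[perm, ]
  parc2$sizes <- parc$sizes[perm]
  atlas2 <- atlas
  atlas2$expr <- expr[, perm]
  atlas2$parcellation <- parc2
  d1 <- spatial_decode(map, atlas, n_spins = 150, seed = 9)
  d2 <- spatial_decode(map[perm], atlas2, n_spins = 150, seed = 9)
  expect_equal(d2$r, d1$r, tolerance = 1e-12)
  expect_equal(d2$p_spin, d1$p_spin)
})

test_that("Fisher enrichment matches the enumeration oracle and fisher.test", {
  r <- fisher_enrichment(paste0("g", 1:50),
                         c(paste0("g", 1:10), paste0("h", 1:90)),
                         c(paste0("g", 1:50), paste0("h", 1:90),
                           paste0("x", 1:860)))
  expect_equal(unlist(r[c("a", "b", "c", "d")]), c(a = 10, b = 40, c = 90,
                                                   d = 860))
  expect_equal(r$odds_ratio, (10 * 860) / (40 * 90), tolerance = 1e-12)
  expect_equal(r$p, fisher_enum_oracle(10, 40, 90, 860), tolerance = 1e-12)
  expect_equal(r$p, fisher.test(matrix(c(10, 40, 90, 860), 2,
                                       byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # all small-margin tables agree with exhaustive enumeration to 1e-12
  set.seed(11)
  for (i in 1:200) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    bg <- paste0("g", seq_len(a + b + c_ + d))
    dec <- bg[seq_len(a + b)]
    gs <- c(bg[seq_len(a)], bg[a + b + seq_len(c_)])
    rr <- fisher_enrichment(dec, gs, bg)
    expect_equal(rr$p, fisher_enum_oracle(a, b, c_, d), tolerance = 1e-12)
  }
})

test_that("odds-ratio edge cases follow the cross-product convention", {
  bg <- paste0("g", 1:100)
  # empty intersection with a nonempty set: OR = 0
  r0 <- fisher_enrichment(bg[1:10], bg[11:20], bg)
  expect_equal(r0$odds_ratio, 0)
  # zero b*c with positive a*d: infinite OR
  rI <- fisher_enrichment(bg[1:10], bg[1:10], bg)
  expect_equal(rI$odds_ratio, Inf)
  # decoded = background: degenerate margin, p = 1
  rB <- fisher_enrichment(bg, bg[1:10], bg)
  expect_equal(rB$p, 1)
  # empty decoded list: undefined OR, p = 1
  rE <- fisher_enrichment(character(0), bg[1:10], bg)
  expect_false(rE$or_defined)
  expect_equal(rE$p, 1)
})

test_that("BH q-values equal the hand step-up and keep their guarantees", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(12)
  p <- runif(50)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("background restriction recomputes the universe consistently", {
  m <- test_mesh3()
  parc <- build_parcellation(m, 100, seed = 13)
  set.seed(14)
  target <- parcel_mean_map(smooth_vertex_map(m, rnorm(642), 20), parc)
  spec <- atlas_spec(n_genes = 400, n_parcels = 100,
                     signal_sets = list(list(name = "sig", size = 40, r = 0.85,
                                             effect = "t")),
                     seed = 15)
  gen <- generate_expression_atlas(spec, m, parc, list(t = target))
  # identity restriction changes nothing
  same <- restrict_background(gen$atlas, gen$atlas$genes)
  expect_identical(same$expr, gen$atlas$expr)
  # random halving keeps counts summing to the new universe
  set.seed(16)
  half <- sample(gen$atlas$genes, 200)
  red <- restrict_background(gen$atlas, half)
  expect_length(red$background, 200L)
  dec <- spatial_decode(target, red, n_spins = 200, seed = 17)
  en <- fisher_enrichment(decoded_genes(dec),
                          intersect(gen$gene_sets$sig, red$background),
                          red$background)
  expect_equal(en$a + en$b + en$c + en$d, 200)
  # decoded genes outside the new background are dropped from the a-cell
  en2 <- fisher_enrichment(gen$atlas$genes[1:50], gen$gene_sets$sig[1:10],
                           gen$atlas$genes[26:400])
  expect_equal(en2$a + en2$b + en2$c + en2$d, 375)
  expect_error(restrict_background(gen$atlas, "nope"), "empty intersection")
})

test_that("the joint enrichment table corrects across all contrast-set pairs", {
  bg <- paste0("g", 1:300)
  dec <- list(c1 = bg[1:30], c2 = bg[250:300])
  sets <- list(s1 = bg[1:25], s2 = bg[100:150])
  tab <- enrichment_table(dec, sets, bg)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$q, bh_fdr(tab$p))
  expect_true(tab$significant[tab$contrast == "c1" & tab$gene_set == "s1"])
})
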
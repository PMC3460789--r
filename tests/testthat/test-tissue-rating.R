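test_that("z-scores match closed-form arithmetic", {
  # one-hot high over 10 tissues: z_high = (n-1)/sqrt(n)
  z <- zscores(c(100, rep(1, 9)))
  expect_equal(z[1], 9 / sqrt(10), tolerance = 1e-12)
  expect_equal(round(z[1], 3), 2.846)
  expect_equal(unname(round(z[2:10], 3)), rep(-0.316, 9))

  # two-high pattern
  z2 <- zscores(c(100, 100, rep(1, 8)))
  expect_equal(round(z2[1], 3), 1.897)
  expect_equal(round(z2[3], 3), -0.474)

  # constant vector: sd = 0 rule
  expect_equal(zscores(rep(5, 10)), rep(0, 10))
  expect_error(zscores(3), "at least 2")
})

test_that("z-scores are location/scale invariant and standardized", {
  set.seed(4)
  for (i in 1:10) {
    x <- runif(12, 1, 100)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(zscores(a * x + b), zscores(x), tolerance = 1e-10)
    expect_equal(sum(zscores(x)), 0, tolerance = 1e-10)
    expect_equal(sd(zscores(x)), 1, tolerance = 1e-10)
  }
  # population-sd mode gives unit population sd
  z <- zscores(runif(10), sd_mode = "population")
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
})

test_that("single-dataset rating assigns the most specific satisfied level", {
  cfg <- rating_config()
  # one-hot high, call P everywhere: z 2.846 >= z3, others below z2 -> SP
  ds <- one_gene_dataset(c(100, rep(1, 9)), rep("P", 10))
  expect_equal(unname(rate_one_dataset(ds, cfg)[1, 1]), "SP")
  # two equal highs: z 1.897 in [z1, z2) -> HP
  ds2 <- one_gene_dataset(c(100, 100, rep(1, 8)), rep("P", 10))
  expect_equal(unname(rate_one_dataset(ds2, cfg)[1, 1]), "HP")
  # an A call overrides any z-score
  ds3 <- one_gene_dataset(c(100, rep(1, 9)), c("A", rep("P", 9)))
  lev3 <- rate_one_dataset(ds3, cfg)
  expect_equal(unname(lev3[1, 1]), "A")
  # constant present vector -> all P
  ds4 <- one_gene_dataset(rep(5, 10), rep("P", 10))
  expect_true(all(rate_one_dataset(ds4, cfg) == "P"))
  # every cell receives exactly one level
  expect_true(all(rate_one_dataset(ds2, cfg) %in% E3_LEVELS))
})

test_that("two tissues above z2 block SP in favor of MS", {
  # with sample sd the z-scores satisfy sum(z^2) = n - 1, so a second tissue
  # above z2 = 1.96 next to one above z3 = 2.58 needs > 10 tissues
  x <- c(10, 8, rep(0, 13))
  z <- zscores(x)
  expect_gt(z[1], 2.58)
  expect_gt(z[2], 1.96)
  ds <- one_gene_dataset(x, rep("P", 15))
  expect_equal(unname(rate_one_dataset(ds)[1, 1]), "MS")
})

test_that("the SP attainability warning fires for small tissue counts", {
  ds8 <- one_gene_dataset(c(100, rep(1, 7)), rep("P", 8))
  expect_warning(rate_one_dataset(ds8), "SP")
  ds9 <- one_gene_dataset(c(100, rep(1, 8)), rep("P", 9))
  expect_silent(rate_one_dataset(ds9))
})

test_that("EST voters use count > 0 presence and CPM z-scores", {
  # g3 is a deep flat background so the library sizes are comparable
  counts <- matrix(c(500, rep(5, 9),
                     rep(0, 10),
                     rep(10000, 10)), 3, 10, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"), paste0("t", 1:10)))
  ds <- expression_dataset("est", counts, NULL, "est_counts")
  lev <- rate_one_dataset(ds)
  expect_equal(unname(lev["g1", 1]), "SP")
  expect_true(all(lev["g2", ] == "A"))  # zero counts -> absent
  expect_error(expression_dataset("est", counts, matrix("P", 3, 10), "est_counts"),
               "no P/A calls")
  expect_error(expression_dataset("est", counts / 3, NULL, "est_counts"),
               "integers")
})

test_that("ballot follows the quoted vote rules", {
  expect_equal(ballot(c("SP", "SP", "MS", "MS", "P")), "MS")  # tie -> less specific
  expect_equal(ballot(c("SP", "SP", "HP", "P", "A")), "SP")
  expect_equal(ballot(c("SP", "HP", "MS", "P", NA)), "UNCLASSIFIED")
  expect_error(ballot(c(NA, NA)), "abstain")
  expect_error(ballot("QQ"), "unknown")
})

test_that("ballot equals the exhaustive oracle over all 5-voter multisets", {
  choices <- c(E3_LEVELS, "abstain")
  grid <- expand.grid(rep(list(choices), 5), stringsAsFactors = FALSE)
  cfg <- rating_config()
  for (i in seq_len(nrow(grid))) {
    votes <- unlist(grid[i, ], use.names = FALSE)
    if (all(votes == "abstain")) next
    got <- ballot(ifelse(votes == "abstain", NA, votes), cfg)
    expect_identical(got, ballot_oracle(votes), label = paste(votes, collapse = ","))
  }
})

test_that("ballot is voter-order invariant and unaffected by abstentions", {
  set.seed(9)
  for (i in 1:50) {
    votes <- sample(c(E3_LEVELS, NA), sample(2:6, 1), replace = TRUE)
    if (all(is.na(votes))) next
    expect_identical(ballot(votes), ballot(sample(votes)))
    expect_identical(ballot(votes), ballot(c(votes, NA, NA)))
  }
})

test_that("rate_all ballots across voters and handles missing genes", {
  cfg0 <- panel_config(n_genes = 60, noise_log_sd = 0, call_flip_rate = 0,
                       seed = 31)
  panel <- generate_panel_voters(cfg0)
  ratings <- rate_all(panel$datasets)
  truth <- panel$truth
  got <- ratings$final[truth$gene_id, "testis"]
  expect_true(all(got == truth$label))  # unanimity on noiseless voters

  # a gene present in only one voter stays unclassified
  d1 <- panel$datasets[[1]]
  extra <- matrix(c(999, rep(1, 9)), 1, 10,
                  dimnames = list("lonely", colnames(d1$values)))
  d1b <- expression_dataset("d1b", rbind(d1$values, extra),
                            rbind(d1$calls, matrix("P", 1, 10,
                                                   dimnames = dimnames(extra))),
                            "array")
  ratings2 <- rate_all(c(list(d1b), panel$datasets[-1]))
  expect_true(all(ratings2$final["lonely", ] == "UNCLASSIFIED"))

  # disjoint gene namespaces are an error
  d_alone <- expression_dataset("alone",
    matrix(1, 1, 10, dimnames = list("zz", colnames(d1$values))))
  expect_error(rate_all(list(d1, d_alone)), "overlapping")
})

test_that("level cross-tab counts planted joint truth with exact margins", {
  cfg <- panel_config(n_genes = 80, noise_log_sd = 0, call_flip_rate = 0,
                      seed = 17)
  panel <- generate_panel_voters(cfg)
  ratings <- rate_all(panel$datasets)
  fams <- stats::setNames(
    rep(c("zf-C3HC4", "HECT", "U-box"), length.out = 80), panel$truth$gene_id)
  path <- withr::local_tempfile(fileext = ".domtblout")
  write_domain_fixture(fams, path)
  cat_ <- classify_families(parse_domtblout(path),
                            identity_map(panel$truth$gene_id))
  tab <- level_cross_tab(cat_, ratings, "testis")
  # planted joint counts
  fam_of <- c(`zf-C3HC4` = "RING", HECT = "HECT", `U-box` = "U-box")[fams]
  for (f in c("RING", "HECT", "U-box")) {
    for (l in c("SP", "MS", "HP", "P", "A")) {
      expect_equal(tab[f, l],
                   sum(fam_of == f & panel$truth$label == l))
    }
  }
  # margins are conserved
  expect_equal(unname(tab["Total", ]), unname(colSums(tab[1:3, ])))
  expect_equal(unname(tab[, "Total"]), unname(rowSums(tab[, 1:6])))
  expect_equal(tab["Total", "Total"], 80L)

  # empty catalogue -> all-zero table
  empty <- classify_families(make_hits(character(), character(), numeric()),
                             character())
  expect_true(all(level_cross_tab(empty, ratings, "testis") == 0))
})
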
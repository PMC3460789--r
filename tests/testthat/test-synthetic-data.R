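test_that("largest-remainder apportionment conserves counts", {
  expect_equal(unname(apportion_counts(10, c(A = 0.55, B = 0.45))), c(6L, 4L))
  expect_error(apportion_counts(10, c(A = 0.5, B = 0.4)), "sum to 1")
  set.seed(6)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    p <- runif(k); p <- p / sum(p); names(p) <- letters[1:k]
    n <- sample(0:500, 1)
    cnt <- apportion_counts(n, p)
    expect_equal(sum(cnt), n)
    expect_true(all(abs(cnt - n * p) <= 1))  # never off by more than one item
  }
})

test_that("panel generation is deterministic under the seed", {
  cfg <- panel_config(n_genes = 40, seed = 99)
  expect_identical(generate_tissue_panel(cfg), generate_tissue_panel(cfg))
  expect_identical(generate_est_voter(cfg), generate_est_voter(cfg))
  course_cfg <- course_config(n_genes = 40, seed = 99)
  expect_identical(generate_stage_course(course_cfg),
                   generate_stage_course(course_cfg))
  # different seeds give different noise
  cfg2 <- panel_config(n_genes = 40, seed = 100)
  expect_false(identical(generate_tissue_panel(cfg)$datasets[[1]]$values,
                         generate_tissue_panel(cfg2)$datasets[[1]]$values))
})

test_that("panel config validates tissues and proportions", {
  expect_error(panel_config(tissues = c("testis")), "at least 2")
  expect_error(panel_config(tissues = c(rep("testis", 2), paste0("t", 1:8))),
               "duplicates")
  expect_error(panel_config(target_tissue = "antenna"), "target tissue")
  expect_error(panel_config(class_proportions = c(A = 0.5, P = 0.6, HP = 0,
                                                  MS = 0, SP = 0)), "sum to 1")
  expect_error(panel_config(sp_fold = 2), "sp_fold")
})

test_that("planted one-hot SP genes carry the closed-form testis z-score", {
  cfg <- panel_config(n_genes = 20, noise_log_sd = 0, call_flip_rate = 0,
                      class_proportions = c(A = 0, P = 0.5, HP = 0, MS = 0,
                                            SP = 0.5),
                      seed = 3)
  panel <- generate_tissue_panel(cfg)
  truth <- panel$truth
  sp_gene <- truth$gene_id[truth$label == "SP"][1]
  v <- panel$datasets[[1]]$values[sp_gene, ]
  # one-hot-high: elevated in testis only
  expect_equal(unname(which.max(v)), which(names(v) == "testis"))
  expect_equal(length(unique(round(v[names(v) != "testis"], 9))), 1)
  expect_equal(unname(zscores(v)["testis"]), 9 / sqrt(10), tolerance = 1e-9)
  lev <- rate_one_dataset(panel$datasets[[1]])
  expect_equal(unname(lev[sp_gene, "testis"]), "SP")
})

test_that("degenerate all-absent mixtures are called A everywhere", {
  cfg <- panel_config(n_genes = 15, noise_log_sd = 0, call_flip_rate = 0,
                      class_proportions = c(A = 1, P = 0, HP = 0, MS = 0,
                                            SP = 0), seed = 2)
  panel <- generate_tissue_panel(cfg)
  for (d in panel$datasets) expect_true(all(d$calls == "A"))
})

test_that("the EST voter is Poisson around the planted pattern", {
  cfg <- panel_config(n_genes = 30, seed = 14)
  est <- generate_est_voter(cfg)
  expect_equal(est$kind, "est_counts")
  expect_null(est$calls)
  expect_true(all(est$values >= 0 & est$values == round(est$values)))
  # planted A genes have near-zero rates: all-zero or tiny rows
  truth <- generate_tissue_panel(cfg)$truth
  a_rows <- est$values[truth$gene_id[truth$label == "A"], , drop = FALSE]
  expect_lt(mean(a_rows), 1)
  # empty config gives an empty dataset
  est0 <- generate_est_voter(panel_config(n_genes = 0, seed = 1))
  expect_equal(nrow(est0$values), 0)
})

test_that("class counts follow apportioned proportions in every dataset", {
  cfg <- panel_config(n_genes = 123, seed = 4)
  panel <- generate_panel_voters(cfg)
  expected <- apportion_counts(123, cfg$class_proportions)
  got <- table(factor(panel$truth$label, levels = names(expected)))
  expect_equal(as.integer(got), unname(expected))
  for (d in panel$datasets) expect_equal(nrow(d$values), 123)
})

test_that("expression matrices round-trip through TSV with calls sibling", {
  cfg <- panel_config(n_genes = 12, seed = 7)
  ds <- generate_tissue_panel(cfg)$datasets[[1]]
  path <- file.path(withr::local_tempdir(), "d1.tsv")
  write_expression_tsv(ds, path)
  expect_true(file.exists(sub("\\.tsv$", ".calls.tsv", path)))
  back <- read_expression_tsv(path, name = ds$name)
  expect_equal(back$values, ds$values, tolerance = 1e-12)
  expect_identical(back$calls, ds$calls)
})

test_that("mixed-domain fixtures classify by the best E-value", {
  path <- withr::local_tempfile(fileext = ".domtblout")
  fix <- data.frame(protein_id = c("g1", "g1"), gene_id = c("g1", "g1"),
                    domain = c("zf-C3HC4", "U-box"),
                    evalue = c(1e-8, 1e-3))
  write_domain_fixture(fix, path)
  cat_ <- classify_families(parse_domtblout(path), c(g1 = "g1"))
  expect_equal(cat_$family, "RING")
})
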
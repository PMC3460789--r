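spermatogenic_phases <- c("mitotic", "meiotic", "post-meiotic", "post-meiotic")

test_that("fold filter applies the 3-fold rule with a pseudo-intensity floor", {
  expect_true(fold_filter(c(10, 35, 40, 38)))   # 41/11 = 3.73
  expect_false(fold_filter(c(10, 12, 14, 13)))  # 15/11 < 3
  expect_false(fold_filter(rep(7, 4)))          # constant: ratio 1
  expect_error(fold_filter(c(-1, 5)), "negative")
  expect_error(fold_filter(5), "at least 2")
})

test_that("onset stage is the first half-max crossing", {
  expect_equal(onset_stage(c(5, 50, 60, 55)), 2)  # half-max 32.5
  expect_equal(onset_stage(c(5, 6, 40, 45)), 3)
  expect_equal(onset_stage(c(50, 55, 20, 10)), 1) # high from the start
})

test_that("group assignment maps onset phase to MI/ME/PM", {
  cfg <- stage_config()
  expect_equal(assign_group(c(5, 50, 60, 55), spermatogenic_phases, cfg), "ME")
  expect_equal(assign_group(c(50, 55, 20, 10), spermatogenic_phases, cfg), "MI")
  expect_equal(assign_group(c(5, 6, 40, 45), spermatogenic_phases, cfg), "PM")
  expect_equal(assign_group(c(10, 12, 14, 13), spermatogenic_phases, cfg), "NONE")
})

test_that("fold filter and onset are invariant under positive scaling", {
  set.seed(2)
  for (i in 1:10) {
    x <- runif(5, 0, 60)
    a <- runif(1, 0.5, 20)
    cfg <- stage_config()
    cfg_scaled <- stage_config(floor = cfg$floor * a)
    expect_identical(fold_filter(a * x, cfg_scaled), fold_filter(x, cfg))
    expect_identical(onset_stage(a * x), onset_stage(x))
  }
})

test_that("late-rising monotone profiles are never MI or ME", {
  set.seed(3)
  for (i in 1:20) {
    lo <- runif(1, 1, 10)
    profile <- c(lo, lo * runif(1, 0.9, 1.1), lo * runif(1, 0.9, 1.1),
                 lo * runif(1, 4, 30))  # rises only at the last (post-meiotic) stage
    g <- assign_group(profile, spermatogenic_phases)
    expect_true(g %in% c("PM", "NONE"))
  }
})

test_that("group ballot needs two concordant votes out of three", {
  expect_equal(group_ballot(c("ME", "ME", "PM")), "ME")
  expect_equal(group_ballot(c("MI", "ME", "PM")), "NONE")
  expect_equal(group_ballot(c("ME", "ME", "ME")), "ME")
  expect_equal(group_ballot(c("NONE", "NONE", "PM")), "NONE")
  # with > 3 voters a tie at the maximum resolves to the earlier phase
  expect_equal(group_ballot(c("MI", "MI", "PM", "PM")), "MI")
  expect_error(group_ballot(c("ME", NA)), "at least 2")
})

test_that("stage datasets validate phase ordering", {
  v <- matrix(1, 2, 4, dimnames = list(c("g1", "g2"), NULL))
  expect_error(stage_dataset("d", v, c("meiotic", "mitotic", "post-meiotic",
                                       "post-meiotic")),
               "non-decreasing")
  expect_error(stage_dataset("d", v[, 1, drop = FALSE], "mitotic"), "2 stages")
})

test_that("days-postpartum map to phases via breakpoints", {
  expect_equal(dpp_phases(c(1, 8, 10, 17, 20, 35)),
               c("mitotic", "mitotic", "meiotic", "meiotic",
                 "post-meiotic", "post-meiotic"))
})

test_that("planted stage groups are recovered exactly without noise", {
  cfg <- course_config(n_genes = 300, noise_log_sd = 0, seed = 12)
  course <- generate_stage_course(cfg)
  groups <- stage_all(course$datasets)
  expect_true(all(groups$final[course$truth$gene_id] == course$truth$label))
  # a planted ME profile is low-high-high-high crossing half-max at pacSC
  me_gene <- course$truth$gene_id[course$truth$label == "ME"][1]
  profile <- course$datasets[[1]]$values[me_gene, ]
  expect_equal(onset_stage(profile), 2)
})

test_that("an all-NONE mixture yields no grouped genes", {
  cfg <- course_config(n_genes = 50,
                       group_proportions = c(MI = 0, ME = 0, PM = 0, NONE = 1),
                       noise_log_sd = 0, seed = 5)
  course <- generate_stage_course(cfg)
  groups <- stage_all(course$datasets)
  expect_true(all(groups$final == "NONE"))
})

test_that("onset_fold below 3 contradicts the fold-filter contract", {
  expect_error(course_config(onset_fold = 2), ">= 3")
})

test_that("stage cross-tab equals planted joint counts with conserved totals", {
  panel <- generate_panel_voters(
    panel_config(n_genes = 150, noise_log_sd = 0, call_flip_rate = 0, seed = 8))
  course <- generate_stage_course(
    course_config(n_genes = 150, noise_log_sd = 0, seed = 8))
  ratings <- rate_all(panel$datasets)
  groups <- stage_all(course$datasets)
  tab <- stage_cross_tab(groups, ratings, "testis")
  lev <- stats::setNames(panel$truth$label, panel$truth$gene_id)
  grp <- stats::setNames(course$truth$label, course$truth$gene_id)
  for (g in c("MI", "ME", "PM")) {
    for (l in c("SP", "MS", "HP", "P")) {
      expect_equal(tab[g, l],
                   sum(grp == g & lev[names(grp)] == l))
    }
  }
  expect_equal(unname(tab["Total", ]), unname(colSums(tab[1:3, ])))
  expect_equal(unname(tab[, "Total"]), unname(rowSums(tab[, 1:4])))
})
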
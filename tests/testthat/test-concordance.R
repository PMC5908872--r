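test_that("venn partition places each called gene in exactly one cell", {
  d <- make_dirs(rbind(c(1L, 1L), c(1L, 0L), c(0L, -1L)), groups = c("A", "B"))
  vp <- venn_partition(d)
  expect_identical(vp$up[["A&B"]], "g001")
  expect_identical(vp$up[["A"]], "g002")
  expect_identical(vp$down[["B"]], "g003")

  d3 <- make_dirs(matrix(c(1L, 0L, -1L), 1L), groups = c("A", "B", "C"))
  vp3 <- venn_partition(d3)
  expect_identical(names(vp3$up), "A")
  expect_identical(names(vp3$down), "C")

  expect_error(venn_partition(d, groups = c("A", "Z")), "unknown group")
  expect_error(venn_partition(d, groups = "A"), "at least 2")
})

test_that("venn partition matches exhaustive enumeration on random matrices", {
  set.seed(23)
  for (i in seq_len(300)) {
    d <- rand_dirs(6L, c("A", "B", "C"))
    vp <- venn_partition(d)
    for (target in c(1L, -1L)) {
      got <- if (target == 1L) vp$up else vp$down
      want <- brute_venn(d, c("A", "B", "C"), target)
      expect_identical(norm_cells(got), norm_cells(want))
      # cell sizes sum to genes called in >= 1 group
      expect_identical(sum(lengths(got)),
                       sum(rowSums(d == target) >= 1L))
    }
  }
})

test_that("consistency classes follow the reference-vs-comparisons rule", {
  d <- make_dirs(rbind(c(1L, 1L, 0L, 1L),
                       c(-1L, 0L, -1L, 0L),
                       c(1L, -1L, 0L, 0L),
                       c(0L, 1L, 1L, 1L)),
                 groups = c("ref", "c1", "c2", "c3"))
  cls <- consistency_class(d, "ref", c("c1", "c2", "c3"))
  expect_identical(unname(cls),
                   c("concordant_up", "concordant_down", "discordant",
                     "not_called"))
})

test_that("genes with one opposing group are discordant across the panel", {
  groups <- c("B_lymphoma", "probT_lymphoma", "CLBL1", "CLBL1M", "GL1",
              "CL1", "OSW")
  # down in GL1, up everywhere else
  shcbp1 <- ifelse(groups == "GL1", -1L, 1L)
  # up in GL1, down everywhere else
  flt3 <- ifelse(groups == "GL1", 1L, -1L)
  d <- make_dirs(rbind(shcbp1, flt3), genes = c("SHCBP1", "FLT3"),
                 groups = groups)
  cls <- consistency_class(d, "B_lymphoma", setdiff(groups, "B_lymphoma"))
  expect_identical(unname(cls), c("discordant", "discordant"))
  core <- all_group_core(d)
  expect_identical(core$discordant, c("SHCBP1", "FLT3"))
})

test_that("all-group core partitions genes called everywhere by sign", {
  d <- make_dirs(rbind(c(1L, 1L, 1L),
                       c(1L, 1L, 0L),
                       c(-1L, -1L, -1L),
                       c(1L, -1L, 1L)))
  core <- all_group_core(d)
  expect_identical(core$concordant_up, "g001")
  expect_identical(core$concordant_down, "g003")
  expect_identical(core$discordant, "g004")
  # g002 not called in every group: outside the core
  expect_false("g002" %in% unlist(core))
})

test_that("core recovery from generator truth matches the planted pools", {
  cfg <- sim_config(n_genes = c(protein_coding = 500L, miRNA = 0L,
                                lncRNA = 0L),
                    n_pathways = 10L, seed = 29L)
  sim <- simulate_experiment(cfg)
  dirs_true <- sign(sim$truth$beta)
  core <- all_group_core(dirs_true)
  expect_identical(sort(core$concordant_up), sort(sim$truth$pools$core_up))
  expect_identical(sort(core$concordant_down),
                   sort(sim$truth$pools$core_down))
  expect_identical(sort(core$discordant), sort(sim$truth$pools$discordant))
})

test_that("concordance operations equal a brute-force per-gene scan", {
  set.seed(37)
  for (i in seq_len(200)) {
    d <- rand_dirs(8L, c("A", "B", "C", "D"))
    core <- all_group_core(d)
    # brute force core
    b_up <- b_down <- b_disc <- character(0)
    for (g in rownames(d)) {
      v <- d[g, ]
      if (all(v != 0L)) {
        if (all(v == 1L)) b_up <- c(b_up, g)
        else if (all(v == -1L)) b_down <- c(b_down, g)
        else b_disc <- c(b_disc, g)
      }
    }
    expect_identical(core$concordant_up, b_up)
    expect_identical(core$concordant_down, b_down)
    expect_identical(core$discordant, b_disc)
    # |core| identity
    expect_identical(length(unlist(core)),
                     sum(rowSums(d != 0L) == ncol(d)))
    # brute-force consistency class
    cls <- consistency_class(d, "A", c("B", "C", "D"))
    for (g in rownames(d)) {
      v <- d[g, ]
      want <- if (v["A"] == 0L) "not_called"
        else if (v["A"] == 1L && all(v[-1L] >= 0L)) "concordant_up"
        else if (v["A"] == -1L && all(v[-1L] <= 0L)) "concordant_down"
        else "discordant"
      expect_identical(unname(cls[g]), want)
    }
  }
})

test_that("concordance table covers every gene with a disjoint partition", {
  set.seed(41)
  d <- rand_dirs(50L, c("A", "B", "C"))
  tab <- concordance_table(d, "A")
  expect_identical(nrow(tab), 50L)
  called <- rowSums(d != 0L) >= 1L
  expect_identical(tab$partition != "", unname(called))
  expect_identical(sort(unique(tab$class)),
                   sort(unique(unname(consistency_class(d, "A",
                                                        c("B", "C"))))))
})
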
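test_that("joint min-max scaling uses the pooled range of cells and plots", {
  cells <- data.frame(BA = c(5, 35), Dg = c(10, 30), BA_b = c(0, 1))
  plots <- data.frame(BA = c(10, 30, 20), Dg = c(15, 25, 20), BA_b = c(0.2, 0.8, 0.5))
  sc <- joint_minmax_scale(cells, plots)
  expect_equal(sc$plots$BA[3], 0.5)            # 20 on joint range [5, 35]
  expect_equal(sc$ranges["min", "BA"], 5)
  expect_equal(range(c(sc$cells$BA, sc$plots$BA)), c(0, 1))

  # constant coordinate maps to 0 for every item
  one <- data.frame(BA = 20, Dg = 25, BA_b = 0.5)
  sc1 <- joint_minmax_scale(one, one)
  expect_equal(unlist(sc1$cells), c(BA = 0, Dg = 0, BA_b = 0))
})

test_that("matching picks the nearest plot with deterministic tie-breaks", {
  space <- data.frame(BA = c(0.2, 0.8, 0.2), Dg = c(0.2, 0.8, 0.2),
                      BA_b = c(0.2, 0.8, 0.2), plot_id = c(7, 2, 3),
                      forest_type = c("fir", "beech", "fir"))
  m <- match_plot(c(0.8, 0.8, 0.8), space)
  expect_equal(m$plot_id, 2)
  expect_equal(m$distance, 0)
  # equidistant candidates: smallest plot_id wins
  m2 <- match_plot(c(0.2, 0.2, 0.2), space)
  expect_equal(m2$plot_id, 3)
  # forest-type filter excludes the globally nearest plot
  m3 <- match_plot(c(0.8, 0.8, 0.8), space, forest_type = "fir")
  expect_equal(m3$plot_id, 3)
  # missing type falls back to the full pool with a warning
  expect_warning(m4 <- match_plot(c(0.8, 0.8, 0.8), space, forest_type = "oak"),
                 "oak")
  expect_equal(m4$plot_id, 2)
})

test_that("alpha correction makes the plot Dg reach the cell Dg exactly", {
  expect_equal(alpha_dg(30, 25), 1.2)
  expect_equal(alpha_dg(25, 25), 1)
  expect_error(alpha_dg(30, 0), "empty")
  trees <- data.frame(species = c("Pi.ab.", "Pi.ab."), dbh = c(20, 30),
                      weight = c(10, 10))
  a <- alpha_dg(30, stand_summary(trees)$Dg)
  scaled <- trees; scaled$dbh <- scaled$dbh * a
  expect_equal(stand_summary(scaled)$Dg, 30)
  expect_equal(a * sqrt(650), 30)  # closed form: 1.2 * sqrt(650) scaling
})

test_that("per-tree targets split the cell BA by class, species and tree shares", {
  single <- data.frame(species = "Fa.sy.", dbh = 30, weight = 20)
  expect_equal(tree_target_ba(20, 1, single), 20)
  # single-class plot facing a mixed cell: the missing class's share is
  # reallocated so the cell BA stays attainable (with a warning)
  expect_warning(t1 <- tree_target_ba(20, 0.5, single), "conifer")
  expect_equal(t1, 20)

  conifers <- data.frame(species = c("Pi.ab.", "Ab.al."), dbh = c(30, 30),
                         weight = c(10, 10))
  expect_equal(tree_target_ba(20, 0, conifers), c(10, 10))

  # algebraic identity: targets sum to BA_ALS when both classes are present
  set.seed(21)
  for (k in 1:30) {
    trees <- random_plot_trees(sample(4:10, 1))
    ba_als <- runif(1, 5, 50); bab <- runif(1)
    expect_equal(sum(tree_target_ba(ba_als, bab, trees)), ba_als)
  }

  # class missing from the plot: share reallocated, total kept exact
  expect_warning(t2 <- tree_target_ba(20, 0.4, conifers), "broadleaf")
  expect_equal(sum(t2), 20)
})

test_that("continuous weights invert the basal-area identity", {
  expect_equal(continuous_weight(10, 1, 50), 40000 * 10 / (pi * 2500))
  ba1 <- tree_basal_area(35)
  expect_equal(continuous_weight(ba1, 1, 35), 1)
  expect_equal(continuous_weight(8, 1.3, 28), 2 * continuous_weight(4, 1.3, 28))
})

test_that("per-cell weights divide by the 16 cells per hectare", {
  expect_equal(cell_weight(plot_component_weight(400)), 1.5625)
  expect_equal(cell_weight(16), 1)
  expect_equal(cell_weight(0), 0)
})

test_that("Bernoulli rounding is unbiased with the quoted 1.56 example", {
  set.seed(1)
  expect_equal(bernoulli_round(3), 3L)
  expect_equal(bernoulli_round(0), 0L)
  set.seed(99)
  draws <- bernoulli_round(rep(1.56, 1e5))
  expect_true(all(draws %in% c(1L, 2L)))
  expect_equal(mean(draws == 2L), 0.56, tolerance = 0.005 / 0.56)
  expect_equal(mean(draws), 1.56, tolerance = 0.005 / 1.56)
})

test_that("final diameters restore each tree record's target basal area", {
  expect_equal(final_dbh(10, 1), sqrt(40000 * 10 / (16 * pi)))
  expect_equal(16 * 2 * tree_basal_area(final_dbh(7, 2)), 7)
  expect_equal(final_dbh(10, 2), final_dbh(10, 1) / sqrt(2))
  # no rounding change: dbh_final equals alpha * dbh_F
  trees <- data.frame(species = "Pi.ab.", dbh = 25, weight = 32)
  a <- 1.1
  ba_t <- tree_basal_area(a * 25) * 32
  wc <- cell_weight(continuous_weight(ba_t, a, 25))
  expect_equal(wc, 2)
  expect_equal(final_dbh(ba_t, 2L), a * 25)
})

test_that("generated cells reach the predicted BA minus dropped-tree losses", {
  set.seed(23)
  for (k in 1:40) {
    trees <- random_plot_trees(sample(3:9, 1))
    cell <- list(BA = runif(1, 5, 45), Dg = runif(1, 12, 40), BA_b = runif(1))
    gen <- suppressWarnings(generate_cell(cell, trees))
    lost <- attr(gen, "lost_ba")
    gen_ba <- if (nrow(gen)) sum(16 * gen$n * tree_basal_area(gen$dbh)) else 0
    expect_equal(gen_ba + lost, cell$BA, tolerance = 1e-9)
  }
  empty <- generate_cell(list(BA = 0, Dg = 20, BA_b = 0.5), mixed_plot_trees())
  expect_equal(nrow(empty), 0)
})

test_that("species Dg ratios of the matched plot survive the transformation", {
  # before rounding, the alpha-scaled diameters preserve inter-species ratios
  set.seed(24)
  for (k in 1:20) {
    trees <- random_plot_trees(10)
    cell <- list(BA = runif(1, 10, 40), Dg = runif(1, 15, 35), BA_b = runif(1))
    a <- alpha_dg(cell$Dg, stand_summary(trees)$Dg)
    sp_dg <- function(d, s, w) {
      vapply(split(seq_along(d), s), function(i)
        sqrt(sum(w[i] * d[i]^2) / sum(w[i])), numeric(1))
    }
    before <- sp_dg(trees$dbh, trees$species, trees$weight)
    ba_t <- tree_target_ba(cell$BA, cell$BA_b, trees)
    w <- continuous_weight(ba_t, a, trees$dbh)
    after <- sp_dg(a * trees$dbh, trees$species, w)
    # weights within a species keep their shares, so Dg scales by alpha
    expect_equal(after / before, rep(a, length(before)), ignore_attr = TRUE,
                 tolerance = 1e-9)
  }
})

test_that("landscape generation is deterministic and order-independent", {
  synth <- small_synth(seed = 31, n_plots = 25, nx = 6, ny = 6)
  cells <- synth$fields$cells
  r1 <- generate_landscape(cells, synth$plots, seed = 42)
  r2 <- generate_landscape(cells, synth$plots, seed = 42)
  expect_identical(r1$trees, r2$trees)
  # processing order must not matter: shuffle the cells
  perm <- sample(nrow(cells))
  r3 <- generate_landscape(cells[perm, ], synth$plots, seed = 42)
  t3 <- r3$trees[order(r3$trees$cellID25, r3$trees$sp, r3$trees$dbh), ]
  t1 <- r1$trees[order(r1$trees$cellID25, r1$trees$sp, r1$trees$dbh), ]
  rownames(t1) <- rownames(t3) <- NULL
  expect_equal(t3, t1)
  # a different seed may change counts but never the attained BA targets
  r4 <- generate_landscape(cells, synth$plots, seed = 43)
  gen_ba <- tapply(16 * r4$trees$n * tree_basal_area(r4$trees$dbh),
                   r4$trees$cellID25, sum)
  ids <- as.numeric(names(gen_ba))
  lost <- r4$diagnostics$lost_ba[match(ids, r4$diagnostics$cellID25)]
  expect_equal(as.numeric(gen_ba) + lost,
               cells$BA[match(ids, cells$cellID25)], tolerance = 1e-9)
})

test_that("a cell equal to a plot's summary matches it at distance zero", {
  synth <- small_synth(seed = 32, n_plots = 20, nx = 5, ny = 5)
  plots <- synth$plots
  ps <- plot_summaries(plots)
  cells <- data.frame(cellID25 = seq_len(nrow(ps)), ps)
  res <- generate_landscape(cells, plots, seed = 1)
  d <- res$diagnostics
  expect_true(all(d$distance < 1e-12))
  expect_equal(as.numeric(d$plot_id),
               as.numeric(vapply(plots, `[[`, 0, "plot_id")))
})
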
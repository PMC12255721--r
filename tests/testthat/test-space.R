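test_that("enumeration is the full Cartesian product in definition order", {
  sp <- toy_space()
  conds <- enumerate_conditions(sp)
  expect_equal(nrow(conds), 3L * 2L * 3L)
  expect_equal(conds$id, 0:17)
  # first parameter varies slowest, last fastest
  expect_equal(conds$base[1:6], rep("K3PO4", 6))
  expect_equal(conds$temperature[1:3], c(25, 60, 100))
  # explicit nested-loop oracle on a randomized small space
  set.seed(3)
  for (rep in 1:5) {
    counts <- sample(1:4, 3, replace = TRUE)
    sp2 <- search_space(list(
      param_def("a", "categorical", paste0("a", seq_len(counts[1]))),
      param_def("b", "categorical", paste0("b", seq_len(counts[2]))),
      param_def("c", "categorical", paste0("c", seq_len(counts[3])))))
    got <- enumerate_conditions(sp2)
    oracle <- expand.grid(c = paste0("c", seq_len(counts[3])),
                          b = paste0("b", seq_len(counts[2])),
                          a = paste0("a", seq_len(counts[1])),
                          stringsAsFactors = FALSE)
    expect_equal(nrow(got), prod(counts))
    expect_equal(got$a, oracle$a)
    expect_equal(got$c, oracle$c)
  }
})

test_that("published campaign spaces have the right combinatorics", {
  suzuki <- search_space(list(
    param_def("ligand", "categorical", paste0("L", 1:50)),
    param_def("precatalyst", "categorical", paste0("Ni", 1:4)),
    param_def("base", "categorical", paste0("B", 1:4)),
    param_def("solvent", "categorical", paste0("S", 1:10)),
    param_def("cosolvent", "categorical", paste0("C", 1:3)),
    param_def("temperature", "temperature", c(40, 55, 70, 85, 100))))
  expect_equal(nrow(enumerate_conditions(suzuki)), 120000L)
  bh <- search_space(list(
    param_def("ligand", "categorical", paste0("L", 1:80)),
    param_def("precatalyst", "categorical", paste0("Pd", 1:3)),
    param_def("base", "categorical", paste0("B", 1:11)),
    param_def("solvent", "categorical", paste0("S", 1:15))))
  expect_equal(nrow(enumerate_conditions(bh)), 39600L)
  one <- search_space(list(param_def("x", "categorical", "only")))
  expect_equal(nrow(enumerate_conditions(one)), 1L)
  expect_error(search_space(list()), "empty space")
})

test_that("boiling-point filter keeps temperatures up to reflux", {
  sp <- search_space(list(
    param_def("solvent", "categorical", "MeOH",
              boiling_points = c(MeOH = 65)),
    param_def("temperature", "temperature", c(40, 55, 70, 85, 100))
  ), feasibility = list(rule_temperature_le_bp("solvent")))
  kept <- apply_feasibility(enumerate_conditions(sp), sp)
  expect_equal(kept$temperature, c(40, 55))   # 65 would also be kept
  expect_equal(kept$id, 0:1)                  # ids re-assigned contiguously
})

test_that("feasibility is vacuous, idempotent and order-preserving", {
  sp <- toy_space(bp = c(MeOH = 200, tol = 200))
  all_conds <- enumerate_conditions(sp)
  kept <- apply_feasibility(all_conds, sp)
  expect_equal(kept, all_conds)
  sp2 <- toy_space(bp = c(MeOH = 65, tol = 111))
  k1 <- apply_feasibility(enumerate_conditions(sp2), sp2)
  k2 <- apply_feasibility(k1, sp2)
  expect_equal(k1[-1], k2[-1])
  expect_equal(k2$id, seq_len(nrow(k2)) - 1L)
  # order preserved relative to the enumeration
  full <- enumerate_conditions(sp2)
  keep_rows <- full$temperature <= ifelse(full$solvent == "MeOH", 65, 111)
  expect_equal(k1$temperature, full$temperature[keep_rows])
})

test_that("missing boiling points and forbidden combinations are handled", {
  sp <- search_space(list(
    param_def("solvent", "categorical", c("MeOH", "tol"),
              boiling_points = c(MeOH = 65)),
    param_def("temperature", "temperature", c(40, 100))
  ), feasibility = list(rule_temperature_le_bp("solvent")))
  expect_error(apply_feasibility(enumerate_conditions(sp), sp), "tol")
  sp2 <- search_space(list(
    param_def("base", "categorical", c("NaH", "K2CO3")),
    param_def("solvent", "categorical", c("DMSO", "THF"))
  ), feasibility = list(rule_forbidden(list(base = "NaH", solvent = "DMSO"))))
  kept <- apply_feasibility(enumerate_conditions(sp2), sp2)
  expect_equal(nrow(kept), 3L)
  expect_false(any(kept$base == "NaH" & kept$solvent == "DMSO"))
})

test_that("PCA reduction picks the smallest sufficient component count", {
  # rank-1 table: one direction carries everything
  v <- matrix(rnorm(6), 1)
  rank1 <- matrix(seq_len(8), ncol = 1) %*% v
  expect_equal(fit_pca_reduction(rank1, 0.99)$n_components, 1L)
  # random rank-3 10x6 matrix at threshold 1: matches spectral oracle
  set.seed(11)
  A <- matrix(rnorm(30), 10, 3) %*% matrix(rnorm(18), 3, 6)
  fit <- fit_pca_reduction(A, 1.0)
  ev <- eigen(cov(A), symmetric = TRUE)$values
  rank_oracle <- sum(ev > max(ev) * 1e-10)
  expect_equal(fit$n_components, rank_oracle)
  expect_error(fit_pca_reduction(matrix(5, 4, 3), 0.9), "no variance")
  # the projection is reusable on new rows of the same width
  newrows <- matrix(rnorm(12), 2, 6)
  proj <- predict(fit, newrows)
  expect_equal(dim(proj), c(2L, fit$n_components))
  # projecting the training data reproduces prcomp scores
  pc <- prcomp(A, center = TRUE)
  expect_equal(abs(predict(fit, A)), abs(pc$x[, seq_len(fit$n_components)]),
               ignore_attr = TRUE)
})

test_that("pool encoding: column structure, scaling and determinism", {
  sp <- tiny_space()   # 2 + 3 one-hot + 1 temperature = 6 raw columns
  conds <- enumerate_conditions(sp)
  pool <- encode_pool(sp, conds)
  expect_equal(ncol(pool$X) + length(pool$dropped), 6L)
  expect_true(all(apply(pool$X, 2, min) == 0))
  expect_true(all(apply(pool$X, 2, max) == 1))
  expect_true(all(pool$X >= 0 & pool$X <= 1))   # exhaustive scan
  # identical inputs give bit-identical matrices
  expect_identical(pool$X, encode_pool(sp, conds)$X)
  # single-value parameters encode as constant columns and are dropped
  sp1 <- search_space(list(
    param_def("a", "categorical", c("x", "y")),
    param_def("b", "categorical", "only")))
  pool1 <- build_pool(sp1)
  expect_true("b=only" %in% pool1$dropped)
})

test_that("one-hot encoding round-trips the condition labels", {
  pool <- toy_pool()
  sp <- pool$space
  for (p in sp$parameters) {
    if (p$role != "categorical") next
    cols <- paste0(p$name, "=", p$values)
    cols <- intersect(cols, colnames(pool$X))
    sub <- pool$X[, cols, drop = FALSE]
    decoded <- sub("^[^=]+=", "", cols[max.col(sub)])
    expect_equal(decoded, as.character(pool$conditions[[p$name]]))
  }
})

test_that("descriptor featurization errors on values absent from the table", {
  desc <- data.frame(d1 = c(1, 2), d2 = c(0, 1),
                     row.names = c("PPh3", "XPhos"))
  expect_error(
    param_def("ligand", "categorical", c("PPh3", "XPhos", "SPhos"),
              descriptors = desc),
    "SPhos")
})

test_that("space YAML round-trips through write/read", {
  sp <- toy_space(bp = c(MeOH = 65, tol = 111))
  dir <- withr::local_tempdir()
  write_space_yaml(sp, file.path(dir, "space.yaml"))
  sp2 <- read_space_yaml(file.path(dir, "space.yaml"))
  expect_equal(names(sp2$parameters), names(sp$parameters))
  expect_equal(sp2$parameters$solvent$boiling_points,
               sp$parameters$solvent$boiling_points)
  expect_identical(build_pool(sp2)$X, build_pool(sp)$X)
})

test_that("the shipped example space file builds a valid pool", {
  f <- system.file("extdata", "example_space.yaml", package = "rxnbo")
  sp <- read_space_yaml(f)
  raw <- enumerate_conditions(sp)
  expect_equal(nrow(raw), 5L * 3L * 3L * 4L * 4L)
  feas <- apply_feasibility(raw, sp)
  # MeOH/THF allow 2 of 4 temperatures, dioxane 4, toluene 4
  expect_equal(nrow(feas), 5L * 3L * 3L * (2L + 2L + 4L + 4L))
  pool <- encode_pool(sp, feas)
  # 4 descriptor columns + 3 + 3 + 4 one-hot + 1 temperature
  expect_equal(ncol(pool$X) + length(pool$dropped), 4L + 3L + 3L + 4L + 1L)
  expect_true(all(pool$X >= 0 & pool$X <= 1))
})
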
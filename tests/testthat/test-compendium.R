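make_mat <- function(vals, samples, genes) {
  matrix(vals, length(samples), length(genes),
         dimnames = list(samples, genes))
}

test_that("loading keeps complete matrices and drops incomplete genes then samples", {
  m <- make_mat(1:9, c("s1", "s2", "s3"), c("g1", "g2", "g3"))
  comp <- suppressMessages(load_expression_matrix(write_tsv_matrix(m)))
  expect_equal(dim(comp$values), c(3L, 3L))
  expect_equal(comp$sample_ids, c("s1", "s2", "s3"))
  expect_equal(unname(comp$values), unname(m * 1.0))

  m_na <- m
  m_na["s2", "g2"] <- NA
  comp_na <- suppressMessages(load_expression_matrix(write_tsv_matrix(m_na)))
  expect_equal(comp_na$gene_ids, c("g1", "g3"))
  expect_equal(length(comp_na$sample_ids), 3L)

  # gene-first dropping retains samples a sample-first rule would lose
  m_both <- m
  m_both["s1", "g1"] <- NA
  comp_both <- suppressMessages(load_expression_matrix(write_tsv_matrix(m_both)))
  expect_equal(comp_both$gene_ids, c("g2", "g3"))
  expect_equal(length(comp_both$sample_ids), 3L)
})

test_that("transposed files load to the same compendium", {
  m <- make_mat(rnorm(12), c("s1", "s2", "s3"), c("g1", "g2", "g3", "g4"))
  p1 <- write_tsv_matrix(m)
  tm <- t(m)
  p2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = rownames(tm), tm, check.names = FALSE),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  c1 <- suppressMessages(load_expression_matrix(p1, "samples_by_genes"))
  c2 <- suppressMessages(load_expression_matrix(p2, "genes_by_samples"))
  expect_equal(c1$values, c2$values)
})

test_that("loading errors on non-numeric cells and empty results", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("id\tg1\tg2", "s1\t1\tx", "s2\t2\t3"), p)
  expect_error(load_expression_matrix(p), "non-numeric")
  m <- make_mat(c(1, NA, NA, 2), c("s1", "s2"), c("g1", "g2"))
  expect_error(suppressMessages(load_expression_matrix(write_tsv_matrix(m))),
               "empty matrix")
  expect_error(load_expression_matrix(tempfile()), "cannot read")
})

test_that("re-loading a written filtered matrix is a fixed point", {
  m <- make_mat(c(1, 2, NA, 4, 5, 6, 7, 8, 9),
                c("s1", "s2", "s3"), c("g1", "g2", "g3"))
  c1 <- suppressMessages(load_expression_matrix(write_tsv_matrix(m)))
  p2 <- tempfile(fileext = ".tsv")
  write_expression_matrix(c1, p2)
  c2 <- suppressMessages(load_expression_matrix(p2))
  expect_equal(c1$values, c2$values)
})

test_that("per-gene normalization maps ranges to [0,1] and constants to 0", {
  m <- make_mat(c(2, 4, 6,  5, 5, 5,  0, 0.5, 1),
                c("s1", "s2", "s3"), c("g1", "g2", "g3"))
  comp <- expression_compendium(m, scale = "log2")
  cn <- normalize_per_gene(comp)
  expect_equal(unname(cn$values[, "g1"]), c(0, 0.5, 1))
  expect_equal(unname(cn$values[, "g2"]), c(0, 0, 0))
  expect_equal(unname(cn$values[, "g3"]), c(0, 0.5, 1))
  expect_equal(cn$scale, "normalized01")
  expect_error(normalize_per_gene(cn), "already normalized")

  # non-constant genes span exactly [0, 1]
  expect_equal(unname(apply(cn$values[, c("g1", "g3")], 2, min)), c(0, 0))
  expect_equal(unname(apply(cn$values[, c("g1", "g3")], 2, max)), c(1, 1))
})

test_that("denormalization inverts normalization", {
  set.seed(3)
  m <- make_mat(c(rnorm(30), rep(7, 10)),
                sprintf("s%d", 1:10), sprintf("g%d", 1:4))
  comp <- expression_compendium(m, scale = "log2")
  cn <- normalize_per_gene(comp)
  back <- denormalize_per_gene(cn)
  expect_lt(max(abs(back$values - m)), 1e-9)
  expect_equal(back$scale, "log2")

  # direct arithmetic: [0, 0.5, 1] with min 2, max 6 -> [2, 4, 6]
  x <- matrix(c(0, 0.5, 1), 3, 1, dimnames = list(paste0("s", 1:3), "g1"))
  cnorm <- expression_compendium(x, scale = "normalized01",
                                 gene_min = 2, gene_max = 6)
  expect_equal(unname(denormalize_per_gene(cnorm)$values[, 1]), c(2, 4, 6))

  cnorm$gene_min <- NULL
  expect_error(denormalize_per_gene(cnorm), "metadata")
})

test_that("train/validation split respects the floor rule and the seed", {
  comp <- make_factor_compendium(100, 10, seed = 5)
  sp <- split_train_validation(comp, 0.75, seed = 11)
  expect_equal(nrow(sp$train$values), 75L)
  expect_equal(nrow(sp$validation$values), 25L)
  expect_length(intersect(sp$train$sample_ids, sp$validation$sample_ids), 0)
  expect_setequal(c(sp$train$sample_ids, sp$validation$sample_ids),
                  comp$sample_ids)

  sp2 <- split_train_validation(comp, 0.75, seed = 11)
  expect_identical(sp$train$sample_ids, sp2$train$sample_ids)

  small <- make_factor_compendium(4, 5, seed = 6)
  sp4 <- split_train_validation(small, 0.75, seed = 1)
  expect_equal(nrow(sp4$train$values), 3L)
  expect_equal(nrow(sp4$validation$values), 1L)
})

test_that("template experiments validate their design", {
  expect_error(template_experiment("t", c("a", "b"), c("x", "x")),
               "two groups")
  expect_error(template_experiment("t", c("a", "b", "c"), c("x", "y")),
               "one group label per sample")
  t <- template_experiment("t", c("a", "b"), c("ctrl", "trt"))
  expect_s3_class(t, "template_experiment")

  p <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup", "a\tctrl", "b\ttrt"), p)
  t2 <- read_template_metadata(p, "exp1")
  expect_equal(t2$sample_ids, c("a", "b"))
  comp <- make_factor_compendium(5, 4)
  expect_error(read_template_metadata(p, "exp1", comp), "not in compendium")
})
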
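fake_de <- function(lfc, genes = sprintf("g%d", seq_along(lfc))) {
  structure(
    data.frame(gene_id = genes, log2fc = lfc, t_stat = lfc,
               p_raw = rep(0.5, length(lfc)), p_adj = rep(0.5, length(lfc))),
    class = c("de_result", "data.frame"))
}

test_that("z-scores standardize the template change against the background", {
  template <- fake_de(c(3.0, 2.0, -1.0))
  sims <- list(fake_de(c(1, 2, -1)), fake_de(c(2, 2, -1)),
               fake_de(c(3, 2, -1)))
  rep <- compute_zscores(template, sims)
  # gene 1: sims [1,2,3], mean 2, sample var 1 (= sd 1) -> z = 1
  expect_equal(rep$z_score[1], 1.0)
  # gene 2: template equals the background mean -> z = 0
  expect_equal(rep$z_score[2], 0)
  expect_equal(rep$sim_mean, c(2, 2, -1))
  expect_equal(rep$sim_var, c(1, 0, 0))

  # negating everything negates z
  neg <- compute_zscores(fake_de(-c(3, 2, -1)),
                         lapply(sims, function(s) fake_de(-s$log2fc)))
  expect_equal(neg$z_score, -rep$z_score)

  # adding a constant to template and simulations leaves z unchanged
  shift <- compute_zscores(fake_de(c(3, 2, -1) + 5),
                           lapply(sims, function(s) fake_de(s$log2fc + 5)))
  expect_equal(shift$z_score, rep$z_score)

  expect_error(compute_zscores(template, sims[1]), "at least 2")
  expect_error(compute_zscores(template,
                               list(fake_de(1:3, genes = c("x", "y", "z")),
                                    fake_de(1:3, genes = c("x", "y", "z")))),
               "same gene set")
})

test_that("the variance-denominator mode matches the printed formula", {
  template <- fake_de(c(6, 0))
  sims <- list(fake_de(c(0, 0)), fake_de(c(2, 0)), fake_de(c(4, 0)))
  # gene 1: sims mean 2, sample var 4, sd 2
  expect_equal(compute_zscores(template, sims)$z_score[1], 2)       # sd
  expect_equal(compute_zscores(template, sims,
                               denominator = "variance")$z_score[1], 1)
})

test_that("ranks scale linearly to 0-100 percentiles", {
  rp <- rank_to_percentile(c(0.1, 0.5, 0.2, 0.9))
  expect_equal(rp$rank, c(1, 3, 2, 4))
  expect_equal(rp$percentile, c(0, 200 / 3, 100 / 3, 100),
               tolerance = 1e-10)

  tied <- rank_to_percentile(rep(2.5, 5))
  expect_equal(tied$percentile, rep(50, 5))

  n <- 40
  set.seed(6)
  v <- rnorm(n)
  rp_n <- rank_to_percentile(v)
  expect_setequal(rp_n$rank, 1:n)
  # invariance under strictly increasing transforms
  expect_equal(rank_to_percentile(exp(v))$percentile, rp_n$percentile)
  expect_error(rank_to_percentile(1), "at least 2")
})

test_that("Spearman comparison of percentiles handles shared universes", {
  a <- setNames(c(0, 50, 100), c("g1", "g2", "g3"))
  expect_equal(compare_percentiles_spearman(a, a), 1)
  expect_equal(compare_percentiles_spearman(a, rev(setNames(a, names(a)))),
               1) # same names, same values reordered
  b <- setNames(c(100, 50, 0), c("g1", "g2", "g3"))
  expect_equal(compare_percentiles_spearman(a, b), -1)

  # values [0.1, 0.5, 0.9] against ranks [1, 3, 2]: sum d^2 = 2 -> rho 0.5
  v <- setNames(c(0.1, 0.5, 0.9), c("g1", "g2", "g3"))
  r <- setNames(c(1, 3, 2), c("g1", "g2", "g3"))
  expect_equal(compare_percentiles_spearman(v, r), 0.5)

  big <- setNames(runif(10), sprintf("g%d", 1:10))
  expect_equal(suppressMessages(
    compare_percentiles_spearman(big, big[1:5])), 1)
  expect_error(compare_percentiles_spearman(big[1:2], big[1:2]),
               "fewer than 3")
})

test_that("common-DEG over-representation is an exact one-sided test", {
  universe <- sprintf("g%d", 1:10)
  half <- universe[1:5]
  res <- common_deg_overrepresentation(half, half, universe)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  expect_equal(
    common_deg_overrepresentation(character(0), half, universe)$p_value, 1)
  disjoint <- common_deg_overrepresentation(universe[1:5], universe[6:10],
                                            universe)
  expect_equal(disjoint$p_value, 1)
  expect_error(common_deg_overrepresentation("zz", half, universe),
               "subsets")
})

test_that("gene labels follow the percentile and z cutoffs", {
  rep <- compute_zscores(
    fake_de(c(0, 0, 5, 0)),
    list(fake_de(c(1, 4, 0, 0.1)), fake_de(c(2, 5, 1, 0.2)),
         fake_de(c(3, 6, 2, 0.3))))
  lab <- classify_common_specific(rep, common_percentile_min = 60, z_min = 2)
  expect_equal(unname(lab[rep$percentile >= 60] == "common"),
               rep(TRUE, sum(rep$percentile >= 60)))

  # a null template with z = 0 everywhere yields no specific genes
  null_rep <- compute_zscores(
    fake_de(c(1, 2, 3)),
    list(fake_de(c(0, 1, 2)), fake_de(c(1, 2, 3)), fake_de(c(2, 3, 4))))
  expect_true(all(classify_common_specific(null_rep, 100, z_min = 0.5)
                  != "specific"))

  # raising z_min never increases the specific count
  n_spec <- function(z) sum(classify_common_specific(rep, 90, z) == "specific")
  zs <- seq(0, 5, by = 0.5)
  counts <- vapply(zs, n_spec, integer(1))
  expect_true(all(diff(counts) <= 0))
})
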
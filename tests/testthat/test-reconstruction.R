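## unrooted-topology comparison via Robinson-Foulds on shared splits
same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

test_that("p-distance ignores gapped columns (pairwise deletion)", {
  msa <- c(a = strrep("A", 100), b = strrep("A", 100))
  expect_equal(p_distance(msa, "a", "b")$p, 0)

  b2 <- paste0(strrep("C", 5), strrep("A", 95))
  res <- p_distance(c(a = strrep("A", 100), b = b2), "a", "b")
  expect_equal(res$p, 0.05)
  expect_equal(res$n, 100)

  ## gapped rows vs a brute-force per-column scan
  set.seed(12)
  for (i in 1:30) {
    L <- 50
    mk <- function() paste(sample(c("A", "C", "D", "-"), L, replace = TRUE,
                                  prob = c(.4, .25, .25, .1)), collapse = "")
    msa <- c(x = mk(), y = mk())
    xs <- strsplit(msa["x"], "")[[1]]; ys <- strsplit(msa["y"], "")[[1]]
    ok <- xs != "-" & ys != "-"
    if (!any(ok)) next
    got <- p_distance(msa, "x", "y")
    expect_equal(got$p, sum(xs[ok] != ys[ok]) / sum(ok))
    expect_equal(got$n, sum(ok))
  }
  expect_error(p_distance(c(x = "---A", y = "AA--"), "x", "y"),
               "comparable")
})

test_that("Poisson correction inverts the expected mismatch curve", {
  expect_equal(as.numeric(poisson_correct(0)), 0)
  expect_equal(as.numeric(poisson_correct(0.5)),
               -(19 / 20) * log(1 - 10 / 19), tolerance = 1e-12)
  expect_equal(as.numeric(poisson_correct(0.5)), 0.7098, tolerance = 1e-4)

  d <- seq(0.01, 2.99, by = 0.01)
  p <- (19 / 20) * (1 - exp(-20 * d / 19))
  expect_true(all(abs(as.numeric(poisson_correct(p)) - d) < 1e-12))

  sat <- poisson_correct(c(0.2, 0.96))
  expect_true(is.na(sat[2]))
  expect_identical(attr(sat, "saturated"), c(FALSE, TRUE))
})

test_that("NJ solves the classic additive 4-taxon matrix exactly", {
  d <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  tr <- neighbor_joining(d)
  keys <- plastidorigin:::phylo_split_keys(tr$phylo)
  expect_equal(length(keys$keys), 1)
  ## split AB|CD
  expect_equal(keys$keys,
               plastidorigin:::tree_split_keys(list(c("C", "D")),
                                               c("A", "B", "C", "D")))
  ## exact branch lengths via path distances: a=2 b=3 c=4 d=5 m=1
  co <- ape::cophenetic.phylo(tr$phylo)
  expect_equal(co[rownames(d), colnames(d)], d, tolerance = 1e-12)
  ## terminal branches recoverable individually
  phy <- tr$phylo
  tl <- stats::setNames(numeric(4), phy$tip.label)
  term <- phy$edge[, 2] <= 4
  tl[phy$tip.label[phy$edge[term, 2]]] <- phy$edge.length[term]
  expect_equal(unname(tl[c("A", "B", "C", "D")]), c(2, 3, 4, 5))
})

test_that("3-taxon closed form and input validation", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  co <- ape::cophenetic.phylo(tr$phylo)
  expect_equal(co[rownames(d), colnames(d)], d, tolerance = 1e-12)

  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
  d[1, 2] <- d[2, 1] <- NA
  expect_error(neighbor_joining(d), "saturated")
})

test_that("NJ recovers random additive trees and matches ape::nj", {
  set.seed(2024)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    true <- ape::rtree(n, tip.label = paste0("s", 1:n))
    true$edge.length <- runif(nrow(true$edge), 0.1, 1)
    d <- ape::cophenetic.phylo(true)
    tr <- neighbor_joining(d[paste0("s", 1:n), paste0("s", 1:n)])
    expect_true(same_topology(tr$phylo, true), label = paste("case", i))
    co <- ape::cophenetic.phylo(tr$phylo)
    expect_equal(co[rownames(d), colnames(d)], d, tolerance = 1e-9)
    ## independent implementation agrees on generic matrices
    ref <- ape::nj(as.dist(d))
    expect_true(same_topology(tr$phylo, ref), label = paste("ape case", i))
  }
})

test_that("bootstrap on a degenerate congruent alignment gives support 100", {
  ## one variable site pattern, fully congruent with split ab|cd
  col_ab <- c(a = "A", b = "A", c = "C", d = "C")
  msa <- vapply(names(col_ab), function(id)
    paste0(strrep(col_ab[[id]], 30), strrep("G", 10)), "")
  bt <- bootstrap_support(msa, B = 10, seed = 5)
  expect_equal(sum(!is.na(bt$mlbp)), 1)
  expect_equal(max(bt$mlbp, na.rm = TRUE), 100)
  expect_true(all(is.na(bt$bpp)))
})

test_that("bootstrap supports are reproducible, bounded, and MLBP-only", {
  fam <- build_scenario_tree(scenario_params("VI", n_host = 4, n_endo = 4,
                                             n_outgroup = 2,
                                             n_heterotroph = 2,
                                             donor_groups = c(donor1 = 2),
                                             seed = 8))
  msa <- simulate_alignment(fam$tree, 300, seed = 9)
  b1 <- bootstrap_support(msa, B = 30, seed = 11)
  b2 <- bootstrap_support(msa, B = 30, seed = 11)
  expect_identical(write_newick(b1), write_newick(b2))
  sup <- b1$mlbp[!is.na(b1$mlbp)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(all(is.na(b1$bpp)))
  b3 <- bootstrap_support(msa, B = 30, seed = 12)
  expect_s3_class(b3, "gene_tree")
})

test_that("a long internal branch is recovered with high support", {
  ## scaled-down version of the Monte-Carlo property (5 reps, L = 2000)
  hits <- 0
  for (r in 1:5) {
    t <- parse_newick("((A:0.1,B:0.1):0.5,(C:0.1,D:0.1):0.0001);")
    msa <- simulate_alignment(t, 2000, seed = 100 + r)
    bt <- bootstrap_support(msa, B = 50, seed = 200 + r)
    keys <- plastidorigin:::phylo_split_keys(bt$phylo)
    want <- plastidorigin:::tree_split_keys(list(c("C", "D")),
                                            bt$phylo$tip.label)
    ix <- match(want, keys$keys)
    sup <- bt$mlbp[keys$nodes[ix] - 4L]
    if (!is.na(sup) && sup >= 95) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("topology recovery is monotone in alignment length", {
  fam <- build_scenario_tree(scenario_params(
    "VI", n_host = 3, n_endo = 3, n_outgroup = 2, n_heterotroph = 2,
    donor_groups = c(donor1 = 2), seed = 77))
  truth <- fam$tree$phylo
  rate <- vapply(c(100, 1000, 5000), function(L) {
    hits <- 0
    for (r in 1:20) {
      msa <- simulate_alignment(fam$tree, L, seed = L + r)
      tr <- neighbor_joining(distance_matrix(msa))
      if (same_topology(tr$phylo, truth)) hits <- hits + 1
    }
    hits / 20
  }, 0)
  expect_true(all(diff(rate) >= 0))
  expect_equal(rate[3], 1)
})

test_that("PHYLIP export round-trips through a file", {
  d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tmp <- withr::local_tempfile()
  write_phylip_dist(d, tmp)
  lines <- readLines(tmp)
  expect_equal(trimws(lines[1]), "3")
  expect_match(lines[2], "^a\\s")
  nums <- as.numeric(strsplit(trimws(sub("^a\\s+", "", lines[2])),
                              "\\s+")[[1]])
  expect_equal(nums, c(0, 1, 2))
})
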
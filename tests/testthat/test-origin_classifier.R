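## Support pairs printed in the study's results, with the verdict the
## authors reached: accepted pairs anchored clade-origin calls, rejected
## pairs were deemed insufficient.
PRINTED_SUPPORT <- data.frame(
  mlbp = c(66, 73, 76, 81, 47, 38, 8),
  bpp = c(0.99, 0.83, 0.95, 0.68, 0.67, NA, NA),
  accepted = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))

test_that("default thresholds reproduce the printed accept/reject pattern", {
  cfg <- classification_config()
  for (i in seq_len(nrow(PRINTED_SUPPORT))) {
    expect_identical(
      evaluate_support(support_pair(PRINTED_SUPPORT$mlbp[i],
                                    PRINTED_SUPPORT$bpp[i]), cfg),
      PRINTED_SUPPORT$accepted[i],
      label = sprintf("pair (%s, %s)", PRINTED_SUPPORT$mlbp[i],
                      PRINTED_SUPPORT$bpp[i]))
  }
})

test_that("support rules combine and fail absent components", {
  pr <- support_pair(60, 0.5)
  expect_true(evaluate_support(pr, classification_config(support_rule = "or")))
  expect_false(evaluate_support(pr, classification_config(support_rule = "and")))
  expect_true(evaluate_support(pr,
                               classification_config(support_rule = "mlbp_only")))
  expect_false(evaluate_support(pr,
                                classification_config(support_rule = "bpp_only")))
  expect_false(evaluate_support(support_pair(), classification_config()))
  expect_true(evaluate_support(support_pair(bpp = 0.99),
                               classification_config()))
})

test_that("long-branch pruning removes only outliers, never the query", {
  even <- parse_newick("((A:1,B:1)90:1,(C:1,D:1)90:1,E:1);")
  expect_length(attr(prune_long_branches(even, 2), "removed"), 0)

  one <- parse_newick("((A:1,B:10)90:1,(C:1,D:1)90:1,E:1);")
  pr <- prune_long_branches(one, 5)
  expect_equal(attr(pr, "removed"), "B")
  expect_setequal(pr$phylo$tip.label, c("A", "C", "D", "E"))
  ## supports survive the pruning
  expect_equal(unname(support_map(pr)[["A|E"]]), c(90, NA))

  protected <- prune_long_branches(one, 5, protect = "B")
  expect_length(attr(protected, "removed"), 0)

  nolen <- parse_newick("((A,B)90,C,D);")
  expect_error(prune_long_branches(nolen, 5), "skip")
})

test_that("pruned tip sets match a brute-force filter on random trees", {
  set.seed(7)
  for (i in 1:20) {
    t <- random_gene_tree(sample(5:12, 1))
    fac <- sample(c(1.5, 2, 5), 1)
    phy <- t$phylo
    ntip <- length(phy$tip.label)
    term <- phy$edge[, 2] <= ntip
    tl <- numeric(ntip)
    tl[phy$edge[term, 2]] <- phy$edge.length[term]
    expected <- phy$tip.label[tl > fac * median(tl)]
    expected <- setdiff(expected, "t1")
    if (length(expected) >= ntip - 2) next
    got <- attr(prune_long_branches(t, fac, protect = "t1"), "removed")
    expect_setequal(got, expected)
  }
})

SPEC_TREE <- paste0("(((Q,H1)100/1.0,(H2,H3)90/0.9)80/0.9,",
                    "((P1,P2)100/1.0,P3)95/1.0,(B1,B2)100/1.0);")

test_that("smallest supported enclosing clade walks rootward correctly", {
  map <- fixture_map()
  t <- parse_newick(SPEC_TREE)
  res <- smallest_supported_enclosing_clade(t, "Q", map)
  expect_setequal(res$tips, c("Q", "H1"))
  expect_equal(res$support$mlbp, 100)
  expect_equal(res$support$bpp, 1.0)

  ## exhaustive check: smallest supported clade containing Q among all
  ## enumerated clades
  oc <- oracle_clades(t, map)
  encl <- Filter(function(cl) "Q" %in% cl$tips, oc$clades)
  ok <- Filter(function(cl) oracle_pass(cl$m, cl$b, classification_config()),
               encl)
  expect_setequal(res$tips, ok[[which.min(lengths(lapply(ok, `[[`, "tips")))]]$tips)

  ## nothing passes when all supports are weak
  low <- gsub("100/1.0", "10/0.3", SPEC_TREE)
  low <- gsub("90/0.9", "10/0.3", low)
  low <- gsub("95/1.0", "10/0.3", low)
  low <- gsub("80/0.9", "10/0.3", low)
  expect_null(smallest_supported_enclosing_clade(parse_newick(low), "Q", map))

  ## query sister to the whole host clade
  t2 <- parse_newick(paste0("((Q,((P1,P2)100/1.0,P3)95/1.0)100/1.0,",
                            "(H1,H2)90/0.99,(B1,B2)100/1.0);"))
  res2 <- smallest_supported_enclosing_clade(t2, "Q", map)
  expect_setequal(res2$tips, c("Q", "P1", "P2", "P3"))

  expect_error(smallest_supported_enclosing_clade(t, "nope", map), "nope")
})

test_that("classify_query reproduces the published decision patterns", {
  map <- fixture_map()
  cfg <- classification_config()

  ## query nested in a supported endosymbiont clade -> EA
  ea <- parse_newick(paste0("(((Q,H1)66/0.99,(H2,H3)90/0.9)80/0.9,",
                            "((P1,P2)100/1.0,P3)95/1.0,(B1,B2)100/1.0);"))
  call <- classify_query(ea, "Q", map, cfg)
  expect_equal(call$call, "EA")
  expect_equal(call$donor_group, "hapto")
  expect_false(call$exclusion_based)
  expect_setequal(call$evidence_clade, c("Q", "H1"))
  expect_equal(call$evidence_support$mlbp, 66)

  ## smallest supported clade mixes endosymbiont and donor -> UNCERTAIN
  mixed <- parse_newick(paste0("(((Q,X1)40/0.5,(H1,H2)30/0.4)100/0.99,",
                               "((P1,P2)100/1.0,P3)95/1.0,(B1,B2)100/1.0);"))
  expect_equal(classify_query(mixed, "Q", map, cfg)$call, "UNCERTAIN")

  ## no supported enclosing clade, but both reference clades supported
  ## and query-free -> LA by exclusion, donor unknown
  excl <- parse_newick(paste0("((Q,((H1,H2)100/0.99,H3)100/0.99)10/0.3,",
                              "((P1,P2)100/1.0,P3)100/1.0,(B1,B2)100/1.0);"))
  call2 <- classify_query(excl, "Q", map, cfg)
  expect_equal(call2$call, "LA")
  expect_equal(call2$donor_group, "unknown")
  expect_true(call2$exclusion_based)

  ## only one reference clade supported -> UNCERTAIN (the published
  ## distinction between exclusion-LA and unresolved calls)
  half <- parse_newick(paste0("((Q,((H1,H2)100/0.99,H3)100/0.99)10/0.3,",
                              "((P1,P2)100/1.0,P3)20/0.4,(B1,B2)100/1.0);"))
  expect_equal(classify_query(half, "Q", map, cfg)$call, "UNCERTAIN")

  ## positive LA: nested in a supported donor clade
  la <- parse_newick(paste0("(((Q,X1)95/0.99,X2)90/0.99,",
                            "(((P1,P2)100/1.0,P3)95/1.0,(H1,H2)90/0.99)50/0.5,",
                            "(B1,B2)100/1.0);"))
  call3 <- classify_query(la, "Q", map, cfg)
  expect_equal(call3$call, "LA")
  expect_equal(call3$donor_group, "strame")

  ## nested among heterotrophs -> UNCERTAIN cytosolic candidate
  het <- parse_newick(paste0("(((Q,C1)95/0.99,C2)90/0.99,",
                             "(((P1,P2)100/1.0,P3)95/1.0,(H1,H2)90/0.99)50/0.5,",
                             "(B1,B2)100/1.0);"))
  call4 <- classify_query(het, "Q", map, cfg)
  expect_equal(call4$call, "UNCERTAIN")
  expect_gte(call4$n_heterotroph_evidence, 1)
  expect_match(call4$notes, "cytosolic")
})

test_that("degenerate inputs yield UNCERTAIN, and missing outgroup errors", {
  map <- fixture_map()
  tiny <- parse_newick("(Q,P1,B1);")
  expect_equal(classify_query(tiny, "Q", map)$call, "UNCERTAIN")
  no_out <- parse_newick("((Q,H1)90/0.99,(P1,P2)100/1.0,P3);")
  expect_error(classify_query(no_out, "Q", map), "outgroup")
  cfg_no <- classification_config(outgroup_required = FALSE)
  expect_s3_class(classify_query(no_out, "Q", map, cfg_no), "origin_call")
})

test_that("co-query tips are transparent to composition tests", {
  ## Q and its co-query form their own supported clade inside the
  ## endosymbiont clade; the walk must pass through it to the EA call
  map <- fixture_map(coquery = "Q2")
  t <- parse_newick(paste0("((((Q,Q2)100/1.0,H1)66/0.99,(H2,H3)90/0.9)80/0.9,",
                           "((P1,P2)100/1.0,P3)95/1.0,(B1,B2)100/1.0);"))
  tg <- c(map$tip_to_group, Q2 = "focal")
  map2 <- taxon_map(tg, map$group_to_role, query_tips = "Q",
                    coquery_tips = "Q2")
  call <- classify_query(t, "Q", map2)
  expect_equal(call$call, "EA")
  expect_setequal(call$evidence_clade, c("Q", "Q2", "H1"))
})

test_that("max_foreign_tips tolerates single-taxon exceptions", {
  map <- fixture_map()
  ## one stramenopile intrudes into the otherwise pure endosymbiont
  ## clade; the host clade is unsupported so no exclusion call can fire
  t <- parse_newick(paste0("(((Q,X1)30/0.5,(H1,H2)90/0.9)95/0.99,",
                           "((P1,P2)100/1.0,P3)20/0.4,(B1,B2)100/1.0);"))
  strict <- classify_query(t, "Q", map, classification_config())
  lax <- classify_query(t, "Q", map,
                        classification_config(max_foreign_tips = 1))
  expect_equal(strict$call, "UNCERTAIN")
  expect_equal(lax$call, "EA")
})

test_that("flag_cytosolic combines heterotroph affinity and extensions", {
  map <- fixture_map()
  het <- parse_newick(paste0("(((Q,C1)95/0.99,C2)90/0.99,",
                             "(((P1,P2)100/1.0,P3)95/1.0,(H1,H2)90/0.99)50/0.5,",
                             "(B1,B2)100/1.0);"))
  call <- classify_query(het, "Q", map)
  msa <- c(Q = paste0(strrep("M", 25), strrep("A", 50)),
           B1 = paste0(strrep("-", 25), strrep("A", 50)))
  ext_yes <- detect_extension(msa, "Q", "B1", min_len = 10)
  ext_no <- detect_extension(c(Q = strrep("A", 50), B1 = strrep("A", 50)),
                             "Q", "B1", min_len = 10)

  expect_true(flag_cytosolic(call, NULL)$cytosolic)
  expect_true(flag_cytosolic(call, ext_no)$cytosolic)
  expect_false(flag_cytosolic(call, ext_yes)$cytosolic)

  vi <- parse_newick(paste0("(((Q,P1)95/0.99,(P2,P3)100/1.0)95/1.0,",
                            "(H1,H2)90/0.99,(B1,B2)100/1.0);"))
  call_vi <- classify_query(vi, "Q", map)
  expect_equal(call_vi$call, "VI")
  expect_false(flag_cytosolic(call_vi, ext_no)$cytosolic)
})

test_that("classifier matches the literal rule-cascade oracle", {
  set.seed(1234)
  cfgs <- list(classification_config(),
               classification_config(max_foreign_tips = 1),
               classification_config(support_rule = "and", bpp_min = 0.9))
  for (i in 1:60) {
    cs <- random_case()
    cfg <- cfgs[[(i %% length(cfgs)) + 1L]]
    got <- classify_query(cs$tree, cs$query, cs$map, cfg)
    want <- oracle_classify(cs$tree, cs$query, cs$map, cfg)
    expect_equal(got$call, want$call, label = paste("case", i))
    if (want$call %in% c("VI", "EA", "LA")) {
      expect_equal(got$donor_group, want$donor_group,
                   label = paste("donor, case", i))
      expect_equal(got$exclusion_based, want$exclusion_based,
                   label = paste("exclusion, case", i))
    }
  }
})

test_that("classification is deterministic and permutation-invariant", {
  set.seed(555)
  for (i in 1:20) {
    cs <- random_case()
    a <- classify_query(cs$tree, cs$query, cs$map)
    b <- classify_query(cs$tree, cs$query, cs$map)
    expect_identical(calls_to_data_frame(a), calls_to_data_frame(b))
    perm <- parse_newick(perm_newick(cs$tree))
    cp <- classify_query(perm, cs$query, cs$map)
    expect_equal(cp$call, a$call)
    expect_setequal(cp$evidence_clade, a$evidence_clade)
  }
})

test_that("tightening thresholds never converts UNCERTAIN to a typed call", {
  set.seed(777)
  loose <- classification_config(mlbp_min = 40, bpp_min = 0.9)
  tight <- classification_config(mlbp_min = 90, bpp_min = 0.999)
  for (i in 1:60) {
    cs <- random_case()
    a <- classify_query(cs$tree, cs$query, cs$map, loose)
    b <- classify_query(cs$tree, cs$query, cs$map, tight)
    if (a$call == "UNCERTAIN")
      expect_equal(b$call, "UNCERTAIN", label = paste("case", i))
  }
})

test_that("typed calls carry evidence; UNCERTAIN carries no support", {
  set.seed(888)
  for (i in 1:40) {
    cs <- random_case()
    call <- classify_query(cs$tree, cs$query, cs$map)
    if (call$call %in% c("VI", "EA", "LA")) {
      expect_true(length(call$evidence_clade) > 0 || call$exclusion_based)
      if (!call$exclusion_based)
        expect_true(call$query_id %in% call$evidence_clade)
    } else {
      expect_true(is.na(call$evidence_support$mlbp) &&
                  is.na(call$evidence_support$bpp))
    }
  }
})

test_that("truth trees with full supports recover every scenario", {
  for (sc in c("VI", "EA", "LA")) for (gd in c("nested", "sister")) {
    fam <- build_scenario_tree(scenario_params(sc, graft_depth = gd,
                                               seed = 11))
    t <- fam$tree
    t$mlbp[] <- 100; t$bpp[] <- 1
    call <- classify_query(t, fam$truth$query_id, fam$map)
    expect_equal(call$call, sc, label = paste(sc, gd))
    if (sc == "LA")
      expect_equal(call$donor_group, fam$truth$donor_group)
  }
})
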
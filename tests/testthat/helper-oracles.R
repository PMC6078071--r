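## Independent oracles and case generators. These deliberately avoid the
## package's internal clade machinery: descendant sets come from
## phangorn::Descendants, enumeration is exhaustive, and the origin-call
## rule cascade is applied literally over the full clade list.

## ---- random gene trees -------------------------------------------------

## random unrooted topology with random supports (some absent)
random_gene_tree <- function(n, p_absent = 0.2) {
  phy <- ape::rtopology(n, rooted = FALSE,
                        tip.label = paste0("t", seq_len(n)))
  phy$edge.length <- runif(nrow(phy$edge), 0.05, 1)
  nn <- phy$Nnode
  mlbp <- ifelse(runif(nn) < p_absent, NA_real_,
                 sample(0:100, nn, replace = TRUE))
  bpp <- ifelse(runif(nn) < p_absent, NA_real_,
                round(runif(nn), 2))
  gene_tree(phy, mlbp = mlbp, bpp = bpp)
}

## newick writer with shuffled child order (independent of write_newick),
## used to check tip-order permutation invariance of the parser
perm_newick <- function(tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  labs <- mapply(plastidorigin:::support_label, tree$mlbp, tree$bpp)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  elen <- if (is.null(phy$edge.length)) NULL else phy$edge.length
  eidx <- stats::setNames(seq_len(nrow(phy$edge)),
                          paste(phy$edge[, 1], phy$edge[, 2]))
  rec <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    ch <- sample(kids[[as.character(v)]])
    parts <- vapply(ch, function(c2) {
      s <- rec(c2)
      if (!is.null(elen))
        s <- paste0(s, ":", format(elen[eidx[[paste(v, c2)]]], digits = 12))
      s
    }, "")
    paste0("(", paste(parts, collapse = ","), ")", labs[v - ntip])
  }
  paste0(rec(ntip + 1L), ";")
}

## canonical bipartition -> support map of a gene tree, for isomorphism
## checks (sides keyed on the half not containing the first tip)
support_map <- function(tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  all_tips <- sort(phy$tip.label)
  out <- list()
  for (v in setdiff((ntip + 1L):(ntip + phy$Nnode), root)) {
    s <- sort(phy$tip.label[unlist(phangorn::Descendants(phy, v, "tips"))])
    if (length(s) < 2L || length(s) > ntip - 2L) next
    k1 <- paste(s, collapse = "|")
    k2 <- paste(sort(setdiff(all_tips, s)), collapse = "|")
    key <- min(k1, k2)
    out[[key]] <- c(tree$mlbp[v - ntip], tree$bpp[v - ntip])
  }
  out[order(names(out))]
}

## ---- literal rule-cascade classifier oracle ---------------------------

oracle_pass <- function(m, b, cfg) {
  mo <- !is.na(m) && m >= cfg$mlbp_min
  bo <- !is.na(b) && b >= cfg$bpp_min
  switch(cfg$support_rule, or = mo || bo, and = mo && bo,
         mlbp_only = mo, bpp_only = bo)
}

oracle_roles <- function(tips, map) {
  grp <- map$tip_to_group[tips]
  grp[is.na(grp)] <- paste0("unassigned:", tips[is.na(grp)])
  role <- map$group_to_role[grp]
  role[is.na(role)] <- "donor"
  names(grp) <- names(role) <- tips
  list(group = grp, role = role)
}

## every clade of the outgroup-rooted tree, by exhaustive enumeration
oracle_clades <- function(tree, map) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  tips <- phy$tip.label
  root <- ntip + 1L
  rl <- oracle_roles(tips, map)
  sides <- list()
  for (v in setdiff(seq_len(ntip + phy$Nnode), root)) {
    s <- sort(tips[unlist(phangorn::Descendants(phy, v, "tips"))])
    m <- if (v > ntip) tree$mlbp[v - ntip] else NA_real_
    b <- if (v > ntip) tree$bpp[v - ntip] else NA_real_
    sides[[length(sides) + 1L]] <-
      list(s = s, comp = sort(setdiff(tips, s)), m = m, b = b,
           internal = v > ntip)
  }
  out_tips <- tips[rl$role == "outgroup"]
  best <- NULL
  for (sd in sides) for (cand in list(sd$s, sd$comp)) {
    sc <- c(-sum(cand %in% out_tips), sum(!cand %in% out_tips))
    key <- paste(cand, collapse = "\r")
    if (is.null(best) || sc[1] < best$sc[1] ||
        (sc[1] == best$sc[1] && sc[2] < best$sc[2]) ||
        (sc[1] == best$sc[1] && sc[2] == best$sc[2] && key < best$key))
      best <- list(rs = cand, sc = sc, key = key)
  }
  rs <- if (length(out_tips)) best$rs else NULL
  clades <- list()
  for (sd in sides) {
    if (!sd$internal) next
    if (is.null(rs)) {
      clades[[length(clades) + 1L]] <- list(tips = sd$s, m = sd$m, b = sd$b)
      next
    }
    comp_rs <- setdiff(tips, rs)
    w <- function(x) all(x %in% rs) || all(x %in% comp_rs)
    if (w(sd$s) && w(sd$comp)) {
      clades[[length(clades) + 1L]] <- list(tips = sd$s, m = sd$m, b = sd$b)
      clades[[length(clades) + 1L]] <- list(tips = sd$comp, m = sd$m,
                                            b = sd$b)
    } else if (w(sd$s)) {
      clades[[length(clades) + 1L]] <- list(tips = sd$s, m = sd$m, b = sd$b)
    } else {
      clades[[length(clades) + 1L]] <- list(tips = sd$comp, m = sd$m,
                                            b = sd$b)
    }
  }
  list(clades = clades, roles = rl)
}

oracle_categories <- function(clade_tips, query, map, rl) {
  rest <- setdiff(clade_tips, c(query, map$coquery_tips))
  role <- rl$role[rest]
  grp <- rl$group[rest]
  ifelse(role == "donor", paste0("donor:", grp),
         ifelse(role == "host_vertical", "host",
                ifelse(role == "endosymbiont", "endo",
                       ifelse(role == "heterotroph", "het", "out"))))
}

## literal application of the decision cascade over the full clade list
oracle_classify <- function(tree, query, map, cfg = classification_config()) {
  tips <- tree$phylo$tip.label
  rest <- setdiff(tips, c(query, map$coquery_tips))
  if (length(tips) < 4L || !length(rest))
    return(list(call = "UNCERTAIN", donor_group = "unknown",
                exclusion_based = FALSE))
  oc <- oracle_clades(tree, map)
  rl <- oc$roles
  host_group <- names(map$group_to_role)[map$group_to_role ==
                                         "host_vertical"][1]
  endo_group <- names(map$group_to_role)[map$group_to_role ==
                                         "endosymbiont"][1]
  encl <- Filter(function(cl) {
    query %in% cl$tips &&
      length(oracle_categories(cl$tips, query, map, rl)) > 0L
  }, oc$clades)
  sup <- Filter(function(cl) oracle_pass(cl$m, cl$b, cfg), encl)
  C <- NULL
  if (length(sup)) C <- sup[[which.min(lengths(lapply(sup, `[[`, "tips")))]]
  if (!is.null(C)) {
    cats <- oracle_categories(C$tips, query, map, rl)
    tab <- table(cats)
    donors <- grep("^donor:", names(tab), value = TRUE)
    donors <- donors[order(-tab[donors], donors)]
    for (cat in c("host", "endo", donors, "het")) {
      if (!cat %in% names(tab)) next
      if (length(cats) - tab[[cat]] > cfg$max_foreign_tips) next
      if (cat == "host")
        return(list(call = "VI", donor_group = host_group,
                    exclusion_based = FALSE))
      if (cat == "endo")
        return(list(call = "EA", donor_group = endo_group,
                    exclusion_based = FALSE))
      if (cat == "het")
        return(list(call = "UNCERTAIN", donor_group = "unknown",
                    exclusion_based = FALSE))
      return(list(call = "LA", donor_group = sub("^donor:", "", cat),
                  exclusion_based = FALSE))
    }
  }
  if (cfg$allow_exclusion_la) {
    ref_ok <- function(role) {
      role_tips <- setdiff(tips[rl$role == role],
                           c(query, map$coquery_tips))
      if (!length(role_tips)) return(FALSE)
      cand <- Filter(function(cl) all(role_tips %in% cl$tips), oc$clades)
      if (!length(cand)) return(FALSE)
      cl <- cand[[which.min(lengths(lapply(cand, `[[`, "tips")))]]
      if (query %in% cl$tips) return(FALSE)
      foreign <- setdiff(cl$tips, c(role_tips, map$coquery_tips))
      length(foreign) <= cfg$max_foreign_tips &&
        oracle_pass(cl$m, cl$b, cfg)
    }
    if (ref_ok("host_vertical") && ref_ok("endosymbiont"))
      return(list(call = "LA", donor_group = "unknown",
                  exclusion_based = TRUE))
  }
  list(call = "UNCERTAIN", donor_group = "unknown", exclusion_based = FALSE)
}

## random classification case: tree + map with randomized roles
random_case <- function(n = NULL) {
  n <- n %||% sample(5:8, 1)
  tree <- random_gene_tree(n)
  tips <- tree$phylo$tip.label
  query <- sample(tips, 1)
  rest <- setdiff(tips, query)
  groups <- sample(c("hostg", "endog", "donA", "donB", "hetg", "outg"),
                   length(rest), replace = TRUE)
  groups[sample(seq_along(rest), 1)] <- "outg"   # guarantee an outgroup
  tg <- stats::setNames(c(groups, "focal"), c(rest, query))
  roles <- c(hostg = "host_vertical", endog = "endosymbiont",
             donA = "donor", donB = "donor", hetg = "heterotroph",
             outg = "outgroup", focal = "donor")
  co <- character()
  if (length(rest) > 2 && runif(1) < 0.3)
    co <- sample(rest[groups != "outg"],
                 min(1 + rbinom(1, 1, 0.5),
                     sum(groups != "outg")))
  map <- taxon_map(tg, roles, query_tips = query, coquery_tips = co)
  list(tree = tree, query = query, map = map)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## small reference taxon map used across classifier tests
fixture_map <- function(query = "Q", coquery = character()) {
  tg <- c(Q = "focal", H1 = "hapto", H2 = "hapto", H3 = "hapto",
          P1 = "dino", P2 = "dino", P3 = "dino",
          B1 = "bact", B2 = "bact",
          X1 = "strame", X2 = "strame", C1 = "cil", C2 = "cil")
  roles <- c(focal = "donor", hapto = "endosymbiont",
             dino = "host_vertical", bact = "outgroup",
             strame = "donor", cil = "heterotroph")
  taxon_map(tg, roles, query_tips = query, coquery_tips = coquery)
}
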
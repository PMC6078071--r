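## Origin-typing decision procedure.
##
## A query protein is classified by (1) rooting the gene tree on the
## outgroup role, (2) walking rootward from the query to the smallest
## clade whose subtending edge is statistically supported, and (3) testing
## the taxon-group composition of that clade: pure host-lineage -> VI
## (vertical inheritance), pure endosymbiont -> EA (endosymbiotic
## acquisition), pure single donor group -> LA (lateral acquisition), pure
## heterotroph -> UNCERTAIN flagged as a cytosolic-paralog candidate.
## When the smallest supported clade is mixed (or none exists), an LA call
## can still be made by exclusion if both the host clade and the
## endosymbiont clade are supported and query-free. Everything else is
## UNCERTAIN.

#' Classification thresholds and switches
#'
#' The source trees report both MLBP and BPP per clade but state no
#' numeric cut-off; the defaults (MLBP >= 50 OR BPP >= 0.95) reproduce
#' the accepted/rejected support pattern of the published calls and are
#' fully configurable.
#'
#' @param mlbp_min minimum MLBP percentage (default 50).
#' @param bpp_min minimum BPP (default 0.95).
#' @param support_rule how the two sub-tests combine: `"or"`, `"and"`,
#'   `"mlbp_only"`, `"bpp_only"`.
#' @param max_foreign_tips intruding tips tolerated in an otherwise pure
#'   clade (default 0; set 1 to mimic single-taxon exceptions).
#' @param allow_exclusion_la permit exclusion-based LA calls.
#' @param outgroup_required error when the tree has no outgroup-role tip.
#' @param long_branch_factor when non-NULL, non-query tips whose terminal
#'   branch exceeds `factor` x median terminal branch length are pruned
#'   before classification.
#' @return a `classification_config` list.
#' @export
classification_config <- function(mlbp_min = 50, bpp_min = 0.95,
                                  support_rule = c("or", "and", "mlbp_only",
                                                   "bpp_only"),
                                  max_foreign_tips = 0L,
                                  allow_exclusion_la = TRUE,
                                  outgroup_required = TRUE,
                                  long_branch_factor = NULL) {
  support_rule <- match.arg(support_rule)
  stopifnot(mlbp_min >= 0, mlbp_min <= 100, bpp_min >= 0, bpp_min <= 1,
            is_count(max_foreign_tips))
  if (!is.null(long_branch_factor))
    stopifnot(is.numeric(long_branch_factor), long_branch_factor >= 1)
  structure(list(mlbp_min = mlbp_min, bpp_min = bpp_min,
                 support_rule = support_rule,
                 max_foreign_tips = as.integer(max_foreign_tips),
                 allow_exclusion_la = isTRUE(allow_exclusion_la),
                 outgroup_required = isTRUE(outgroup_required),
                 long_branch_factor = long_branch_factor),
            class = "classification_config")
}

#' A (MLBP, BPP) support pair
#'
#' @param mlbp bootstrap percentage in [0, 100] or NA.
#' @param bpp posterior probability in [0, 1] or NA.
#' @return a `support_pair` list.
#' @export
support_pair <- function(mlbp = NA_real_, bpp = NA_real_) {
  if (!is.na(mlbp)) stopifnot(mlbp >= 0, mlbp <= 100)
  if (!is.na(bpp)) stopifnot(bpp >= 0, bpp <= 1)
  structure(list(mlbp = as.numeric(mlbp), bpp = as.numeric(bpp)),
            class = "support_pair")
}

#' Does a support pair pass the configured thresholds?
#'
#' An absent component fails its sub-test.
#'
#' @param s a [support_pair()] (or list with `mlbp`, `bpp`).
#' @param cfg a [classification_config()].
#' @return TRUE or FALSE.
#' @examples
#' cfg <- classification_config()
#' evaluate_support(support_pair(66, 0.99), cfg)  # TRUE
#' evaluate_support(support_pair(47, 0.67), cfg)  # FALSE
#' @export
evaluate_support <- function(s, cfg = classification_config()) {
  m_ok <- !is.na(s$mlbp) && s$mlbp >= cfg$mlbp_min
  b_ok <- !is.na(s$bpp) && s$bpp >= cfg$bpp_min
  switch(cfg$support_rule,
         or = m_ok || b_ok,
         and = m_ok && b_ok,
         mlbp_only = m_ok,
         bpp_only = b_ok)
}

#' Remove long-branch tips before re-analysis
#'
#' Drops every unprotected tip whose terminal branch length exceeds
#' `factor` times the median terminal branch length, mirroring the
#' long-branch exclusion re-analysis convention for rapidly evolving
#' sequences.
#'
#' @param tree a `gene_tree` with branch lengths.
#' @param factor positive multiplier (>= 1) of the median terminal branch.
#' @param protect tips never removed (the query and co-query tips).
#' @return a pruned `gene_tree` with attribute `"removed"` listing the
#'   dropped tips.
#' @export
prune_long_branches <- function(tree, factor, protect = character()) {
  stopifnot(inherits(tree, "gene_tree"), is.numeric(factor), factor >= 1)
  phy <- tree$phylo
  if (is.null(phy$edge.length))
    stop2("tree has no branch lengths; skip long-branch pruning")
  ntip <- length(phy$tip.label)
  term <- phy$edge[, 2] <= ntip
  tlen <- numeric(ntip)
  tlen[phy$edge[term, 2]] <- phy$edge.length[term]
  med <- median(tlen)
  drop <- phy$tip.label[tlen > factor * med]
  drop <- setdiff(drop, protect)
  if (!length(drop)) {
    attr(tree, "removed") <- character()
    return(tree)
  }
  if (length(drop) >= ntip - 2L)
    stop2("long-branch pruning would leave fewer than 3 tips")
  phy$node.label <- mapply(support_label, tree$mlbp, tree$bpp,
                           USE.NAMES = FALSE)
  pruned <- ape::drop.tip(phy, drop, collapse.singles = TRUE)
  sup <- parse_support_labels(pruned$node.label %||% rep("", pruned$Nnode),
                              "auto")
  out <- gene_tree(pruned, mlbp = sup$mlbp, bpp = sup$bpp)
  attr(out, "removed") <- drop
  out
}

## ---- rooted clade machinery -------------------------------------------

## descendant tip-index sets for every node, from one postorder pass
desc_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

## Choose the root side: the bipartition side that maximizes the number
## of outgroup tips, then minimizes non-outgroup tips, ties broken on the
## lexicographically smallest sorted tip set. Returns tip indices or NULL
## when the tree has no outgroup tips.
choose_root_side <- function(phy, out_idx, sets) {
  if (!length(out_idx)) return(NULL)
  ntip <- length(phy$tip.label)
  all_idx <- seq_len(ntip)
  best <- NULL; best_key <- NULL
  consider <- function(side) {
    n_out <- sum(side %in% out_idx)
    n_other <- length(side) - n_out
    key <- list(-n_out, n_other,
                paste(sort(phy$tip.label[side]), collapse = "\r"))
    if (is.null(best) ||
        key[[1]] < best_key[[1]] ||
        (key[[1]] == best_key[[1]] && key[[2]] < best_key[[2]]) ||
        (key[[1]] == best_key[[1]] && key[[2]] == best_key[[2]] &&
         key[[3]] < best_key[[3]])) {
      best <<- side; best_key <<- key
    }
  }
  root <- ntip + 1L
  for (v in seq_len(ntip + phy$Nnode)) {
    if (v == root) next
    s <- sets[[v]]
    if (length(s) == 0L || length(s) == ntip) next
    consider(s)
    consider(setdiff(all_idx, s))
  }
  best
}

## Table of rooted clades: one row per supported internal edge (the root
## edge contributes both of its sides). Returns a list of entries
## (tips: character, mlbp, bpp).
rooted_clades <- function(tree, root_side) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  sets <- desc_sets(phy)
  all_idx <- seq_len(ntip)
  rs <- root_side
  comp_rs <- if (is.null(rs)) NULL else setdiff(all_idx, rs)
  out <- list()
  add <- function(idx, m, b) {
    out[[length(out) + 1L]] <<- list(tips = phy$tip.label[idx],
                                     mlbp = m, bpp = b)
  }
  root_node <- ntip + 1L
  for (v in (ntip + 1L):(ntip + phy$Nnode)) {
    if (v == root_node) next       # no subtending edge
    s <- sets[[v]]
    m <- tree$mlbp[v - ntip]; b <- tree$bpp[v - ntip]
    if (is.null(rs)) { add(s, m, b); next }
    comp <- setdiff(all_idx, s)
    within <- function(x) all(x %in% rs) || all(x %in% comp_rs)
    s_in <- within(s); c_in <- within(comp)
    if (s_in && c_in) {            # the root edge: both sides are clades
      add(s, m, b); add(comp, m, b)
    } else if (s_in) add(s, m, b)
    else if (c_in) add(comp, m, b)
    else add(s, m, b)              # unreachable on a valid tree
  }
  out
}

clade_context <- function(tree, map, cfg) {
  phy <- tree$phylo
  tips <- phy$tip.label
  tr <- tip_roles(tips, map)
  out_idx <- which(tr$role[tips] == "outgroup")
  if (!length(out_idx) && cfg$outgroup_required)
    stop2("no outgroup-role tips in tree; set outgroup_required = FALSE ",
          "to classify anyway")
  sets <- desc_sets(phy)
  rs <- choose_root_side(phy, out_idx, sets)
  list(tips = tips, roles = tr$role, groups = tr$group,
       clades = rooted_clades(tree, rs), root_side = tips[rs])
}

## composition categories of the non-query, non-coquery tips of a clade
clade_categories <- function(clade_tips, query, map, ctx) {
  rest <- setdiff(clade_tips, c(query, map$coquery_tips))
  if (!length(rest)) return(character())
  role <- ctx$roles[rest]
  grp <- ctx$groups[rest]
  ifelse(role == "donor", paste0("donor:", grp),
         ifelse(role == "host_vertical", "host",
                ifelse(role == "endosymbiont", "endo",
                       ifelse(role == "heterotroph", "het", "out"))))
}

## pure-category test: dominant category with at most max_foreign_tips
## intruders; categories tried in the fixed order host, endo, donor
## groups (largest first, then name), heterotroph
pure_category <- function(cats, max_foreign) {
  if (!length(cats)) return(NULL)
  tab <- table(cats)
  total <- length(cats)
  donors <- grep("^donor:", names(tab), value = TRUE)
  donors <- donors[order(-tab[donors], donors)]
  for (cat in c("host", "endo", donors, "het")) {
    if (!cat %in% names(tab)) next
    if (total - tab[[cat]] <= max_foreign) return(cat)
  }
  NULL
}

#' Smallest supported clade enclosing a query tip
#'
#' Walks rootward from the query (on the tree rooted on the outgroup
#' role) and returns the first enclosing clade whose subtending edge
#' passes [evaluate_support()]. Clades containing only query/co-query
#' tips are transparent and skipped.
#'
#' @param tree a `gene_tree`.
#' @param query tip name under analysis.
#' @param map a [taxon_map()].
#' @param cfg a [classification_config()].
#' @return a list with `tips` and `support` (a [support_pair()]), or
#'   NULL when no supported enclosing clade exists below the root.
#' @export
smallest_supported_enclosing_clade <- function(tree, query, map,
                                               cfg = classification_config()) {
  stopifnot(inherits(tree, "gene_tree"))
  if (!query %in% tree$phylo$tip.label)
    stop2("query tip '", query, "' not in tree")
  ctx <- clade_context(tree, map, cfg)
  find_enclosing_clade(query, map, cfg, ctx)
}

find_enclosing_clade <- function(query, map, cfg, ctx) {
  encl <- Filter(function(cl) query %in% cl$tips, ctx$clades)
  if (!length(encl)) return(NULL)
  sizes <- vapply(encl, function(cl) length(cl$tips), 0L)
  encl <- encl[order(sizes)]
  for (cl in encl) {
    if (!length(clade_categories(cl$tips, query, map, ctx))) next
    if (evaluate_support(support_pair(cl$mlbp, cl$bpp), cfg))
      return(list(tips = cl$tips,
                  support = support_pair(cl$mlbp, cl$bpp)))
  }
  NULL
}

## smallest supported, query-free, pure clade containing every tip of a
## reference role (host_vertical or endosymbiont); NULL when none
reference_clade <- function(role, query, map, cfg, ctx) {
  role_tips <- ctx$tips[ctx$roles == role]
  role_tips <- setdiff(role_tips, c(query, map$coquery_tips))
  if (!length(role_tips)) return(NULL)
  cand <- Filter(function(cl) all(role_tips %in% cl$tips), ctx$clades)
  if (!length(cand)) return(NULL)
  sizes <- vapply(cand, function(cl) length(cl$tips), 0L)
  cl <- cand[[which.min(sizes)]]
  if (query %in% cl$tips) return(NULL)
  foreign <- setdiff(cl$tips, c(role_tips, map$coquery_tips))
  if (length(foreign) > cfg$max_foreign_tips) return(NULL)
  if (!evaluate_support(support_pair(cl$mlbp, cl$bpp), cfg)) return(NULL)
  list(tips = cl$tips, support = support_pair(cl$mlbp, cl$bpp))
}

new_origin_call <- function(query, call, donor_group = "unknown",
                            evidence_clade = character(),
                            evidence_support = support_pair(),
                            exclusion_based = FALSE, cytosolic = FALSE,
                            n_heterotroph_evidence = 0L, notes = "") {
  structure(list(query_id = query, call = call, donor_group = donor_group,
                 evidence_clade = evidence_clade,
                 evidence_support = evidence_support,
                 exclusion_based = exclusion_based, cytosolic = cytosolic,
                 n_heterotroph_evidence = as.integer(n_heterotroph_evidence),
                 notes = notes),
            class = "origin_call")
}

#' Classify the evolutionary origin of one query protein
#'
#' Deterministic decision cascade: (1) find the smallest supported clade
#' enclosing the query; (2) if its non-query composition is pure
#' host-lineage, endosymbiont, a single donor group, or heterotrophs,
#' call VI, EA, LA, or UNCERTAIN (cytosolic candidate) respectively;
#' (3) otherwise, if both the host clade and the endosymbiont clade are
#' supported and exclude the query, call LA by exclusion with unknown
#' donor; (4) otherwise UNCERTAIN. Trees with fewer than 4 tips or
#' without non-query reference tips yield UNCERTAIN with a note.
#'
#' @param tree a `gene_tree`.
#' @param query tip name of the query paralog.
#' @param map a [taxon_map()]; tips listed in `map$coquery_tips` are
#'   transparent to composition tests.
#' @param cfg a [classification_config()].
#' @return an `origin_call`.
#' @export
classify_query <- function(tree, query, map, cfg = classification_config()) {
  stopifnot(inherits(tree, "gene_tree"), inherits(map, "taxon_map"))
  if (!query %in% tree$phylo$tip.label)
    stop2("query tip '", query, "' not in tree")
  if (!is.null(cfg$long_branch_factor) &&
      !is.null(tree$phylo$edge.length)) {
    tree <- prune_long_branches(tree, cfg$long_branch_factor,
                                protect = c(query, map$coquery_tips))
  }
  tips <- tree$phylo$tip.label
  rest <- setdiff(tips, c(query, map$coquery_tips))
  if (length(tips) < 4L || !length(rest))
    return(new_origin_call(query, "UNCERTAIN",
                           notes = "degenerate tree: too few informative tips"))
  ctx <- clade_context(tree, map, cfg)
  host_group <- names(map$group_to_role)[map$group_to_role == "host_vertical"][1]
  endo_group <- names(map$group_to_role)[map$group_to_role == "endosymbiont"][1]

  cl <- find_enclosing_clade(query, map, cfg, ctx)
  if (!is.null(cl)) {
    cats <- clade_categories(cl$tips, query, map, ctx)
    n_het <- sum(cats == "het")
    pure <- pure_category(cats, cfg$max_foreign_tips)
    if (!is.null(pure)) {
      sup_txt <- sprintf("MLBP %s, BPP %s",
                         format(cl$support$mlbp), format(cl$support$bpp))
      if (pure == "host")
        return(new_origin_call(query, "VI", donor_group = host_group,
                               evidence_clade = cl$tips,
                               evidence_support = cl$support,
                               n_heterotroph_evidence = n_het,
                               notes = paste("nested in host clade;", sup_txt)))
      if (pure == "endo")
        return(new_origin_call(query, "EA", donor_group = endo_group,
                               evidence_clade = cl$tips,
                               evidence_support = cl$support,
                               n_heterotroph_evidence = n_het,
                               notes = paste("nested in endosymbiont clade;",
                                             sup_txt)))
      if (startsWith(pure, "donor:"))
        return(new_origin_call(query, "LA",
                               donor_group = sub("^donor:", "", pure),
                               evidence_clade = cl$tips,
                               evidence_support = cl$support,
                               n_heterotroph_evidence = n_het,
                               notes = paste("nested in donor clade;", sup_txt)))
      if (pure == "het")
        return(new_origin_call(query, "UNCERTAIN",
                               evidence_clade = cl$tips,
                               n_heterotroph_evidence = n_het,
                               notes = paste("nested among heterotrophic",
                                             "eukaryotes; cytosolic-paralog",
                                             "candidate;", sup_txt)))
    }
  }
  if (cfg$allow_exclusion_la) {
    host_ref <- reference_clade("host_vertical", query, map, cfg, ctx)
    endo_ref <- reference_clade("endosymbiont", query, map, cfg, ctx)
    if (!is.null(host_ref) && !is.null(endo_ref))
      return(new_origin_call(query, "LA", donor_group = "unknown",
                             evidence_clade = union(host_ref$tips,
                                                    endo_ref$tips),
                             exclusion_based = TRUE,
                             notes = paste("excluded from supported host and",
                                           "endosymbiont clades; donor unknown")))
  }
  note <- if (is.null(cl)) "no supported enclosing clade"
          else "smallest supported enclosing clade has mixed composition"
  new_origin_call(query, "UNCERTAIN", notes = note)
}

#' Flag a call as a cytosolic paralog
#'
#' A query nesting with heterotrophic eukaryotes and lacking an
#' N-terminal extension is attributed to the cytosolic (non-plastid)
#' pathway and excluded from plastid aggregation downstream.
#'
#' @param call an `origin_call` from [classify_query()].
#' @param ext an `extension_report` for the same query, or NULL when no
#'   extension analysis is available.
#' @return the call with `cytosolic` (and possibly `notes`) updated.
#' @export
flag_cytosolic <- function(call, ext = NULL) {
  stopifnot(inherits(call, "origin_call"))
  het <- call$n_heterotroph_evidence >= 1L
  if (!het) {
    call$cytosolic <- FALSE
    return(call)
  }
  if (!is.null(ext) && isTRUE(ext$has_extension)) {
    call$cytosolic <- FALSE
    call$notes <- paste(call$notes,
                        "| heterotroph affinity but N-terminal extension",
                        "present: kept as plastid-targeted")
    return(call)
  }
  call$cytosolic <- TRUE
  call$notes <- paste(call$notes, "| cytosolic paralog (heterotroph",
                      "affinity, no N-terminal extension)")
  call
}

#' Classify several query paralogs in one tree
#'
#' Each query is classified independently with the remaining queries
#' marked as co-query (transparent to composition tests).
#'
#' @param tree a `gene_tree`.
#' @param queries character vector of query tip names.
#' @param map a [taxon_map()].
#' @param cfg a [classification_config()].
#' @return a list of `origin_call`s, one per query.
#' @export
classify_tree <- function(tree, queries, map,
                          cfg = classification_config()) {
  lapply(queries, function(q) {
    m <- map
    m$query_tips <- q
    m$coquery_tips <- union(setdiff(queries, q), map$coquery_tips)
    m$coquery_tips <- setdiff(m$coquery_tips, q)
    classify_query(tree, q, m, cfg)
  })
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf("<origin_call> %s: %s (donor %s)%s%s\n", x$query_id, x$call,
              x$donor_group,
              if (x$exclusion_based) " [by exclusion]" else "",
              if (x$cytosolic) " [cytosolic]" else ""))
  if (length(x$evidence_clade))
    cat("  evidence clade:", paste(x$evidence_clade, collapse = ", "), "\n")
  if (nzchar(x$notes)) cat("  ", x$notes, "\n")
  invisible(x)
}

#' Tabulate origin calls
#'
#' @param calls a list of `origin_call`s.
#' @return a data.frame with the CLI output columns (query_id, call,
#'   donor_group, evidence_tips, mlbp, bpp, exclusion_based, cytosolic,
#'   notes).
#' @export
calls_to_data_frame <- function(calls) {
  if (inherits(calls, "origin_call")) calls <- list(calls)
  do.call(rbind, lapply(calls, function(x) {
    data.frame(query_id = x$query_id, call = x$call,
               donor_group = x$donor_group,
               evidence_tips = paste(x$evidence_clade, collapse = ","),
               mlbp = x$evidence_support$mlbp %||% NA_real_,
               bpp = x$evidence_support$bpp %||% NA_real_,
               exclusion_based = x$exclusion_based,
               cytosolic = x$cytosolic, notes = x$notes,
               stringsAsFactors = FALSE)
  }))
}
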
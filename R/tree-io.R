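## Newick gene trees with dual clade supports, and tip->group->role maps.
##
## Support dialect: an internal-node label is "", "M", "M/B", "M/-" or
## "-/B", where M is a maximum-likelihood bootstrap percentage (MLBP,
## 0-100) and B a Bayesian posterior probability (BPP, 0-1). "-" marks an
## absent value (the figure convention for BPP < 0.50). A bare numeric
## label is read as MLBP when > 1 and as BPP otherwise; `label_as`
## overrides that guess so externally produced treefiles with other
## conventions can be mapped without code changes.

ROLE_NAMES <- c("host_vertical", "endosymbiont", "donor", "heterotroph",
                "outgroup")

#' Parse a newick gene tree with single or dual support labels
#'
#' @param text a newick string (one tree).
#' @param label_as how to interpret a bare numeric internal-node label:
#'   `"auto"` (MLBP if > 1, else BPP), `"mlbp"` or `"bpp"`.
#' @return a `gene_tree`: a list with `phylo` (an [ape::read.tree()]
#'   phylogeny), and `mlbp`/`bpp` numeric vectors with one entry per
#'   internal node (NA where absent).
#' @export
parse_newick <- function(text, label_as = c("auto", "mlbp", "bpp")) {
  label_as <- match.arg(label_as)
  stopifnot(is_string(text))
  check_parens(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(e) NULL)
  if (is.null(phy)) stop2("newick parse failure: ", substr(text, 1, 60))
  if (anyDuplicated(phy$tip.label))
    stop2("duplicate tip label(s): ",
          paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                collapse = ", "))
  if (length(phy$tip.label) < 2L) stop2("tree must have >= 2 tips")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop2("negative branch length(s) in input")
  labels <- phy$node.label %||% rep("", phy$Nnode)
  sup <- parse_support_labels(labels, label_as)
  gene_tree(phy, mlbp = sup$mlbp, bpp = sup$bpp)
}

## balance pre-check with a character offset in the error, which ape's
## parser does not report
check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  stack <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack))
        stop2("unbalanced ')' at character offset ", i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop2("unmatched '(' at character offset ", stack[length(stack)])
  invisible(TRUE)
}

parse_support_labels <- function(labels, label_as) {
  n <- length(labels)
  mlbp <- rep(NA_real_, n)
  bpp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (is.na(lab) || !nzchar(lab)) next
    parts <- strsplit(lab, "/", fixed = TRUE)[[1]]
    num <- function(x) {
      if (x == "-") return(NA_real_)
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v)) stop2("non-numeric support label part '", x, "'")
      v
    }
    if (length(parts) == 1L) {
      v <- num(parts[1])
      kind <- switch(label_as,
                     auto = if (!is.na(v) && v > 1) "mlbp" else "bpp",
                     label_as)
      if (kind == "mlbp") mlbp[i] <- v else bpp[i] <- v
    } else if (length(parts) == 2L) {
      mlbp[i] <- num(parts[1])
      bpp[i] <- num(parts[2])
    } else {
      stop2("malformed support label '", lab, "'")
    }
  }
  if (any(!is.na(mlbp) & (mlbp < 0 | mlbp > 100)))
    stop2("MLBP out of range [0, 100]")
  if (any(!is.na(bpp) & (bpp < 0 | bpp > 1)))
    stop2("BPP out of range [0, 1]")
  list(mlbp = mlbp, bpp = bpp)
}

#' Construct a gene tree from a phylo object and support vectors
#'
#' @param phylo an [ape::read.tree()] phylogeny.
#' @param mlbp,bpp numeric vectors, one entry per internal node of
#'   `phylo` (recycled NA when omitted).
#' @return a `gene_tree`.
#' @export
gene_tree <- function(phylo, mlbp = NULL, bpp = NULL) {
  stopifnot(inherits(phylo, "phylo"))
  n <- phylo$Nnode
  mlbp <- mlbp %||% rep(NA_real_, n)
  bpp <- bpp %||% rep(NA_real_, n)
  stopifnot(length(mlbp) == n, length(bpp) == n)
  structure(list(phylo = phylo, mlbp = as.numeric(mlbp),
                 bpp = as.numeric(bpp)),
            class = "gene_tree")
}

format_support_num <- function(x) {
  format(x, digits = 12, scientific = FALSE, trim = TRUE)
}

support_label <- function(m, b) {
  if (is.na(m) && is.na(b)) return("")
  if (is.na(b)) {
    ## a bare MLBP <= 1 would re-read as a BPP; mark the absent BPP
    if (m > 1) format_support_num(m) else paste0(format_support_num(m), "/-")
  } else if (is.na(m)) {
    paste0("-/", format_support_num(b))
  } else {
    paste0(format_support_num(m), "/", format_support_num(b))
  }
}

#' Serialize a gene tree to newick
#'
#' Inverse of [parse_newick()]: `parse_newick(write_newick(t))` is
#' isomorphic to `t` with identical supports and branch lengths.
#'
#' @param tree a `gene_tree`.
#' @param file optional path; when given the string is also written there.
#' @return the newick string.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  phy <- tree$phylo
  phy$node.label <- mapply(support_label, tree$mlbp, tree$bpp,
                           USE.NAMES = FALSE)
  out <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("<gene_tree>", length(x$phylo$tip.label), "tips,",
      x$phylo$Nnode, "internal nodes\n")
  ns <- sum(!is.na(x$mlbp) | !is.na(x$bpp))
  cat("  supports on", ns, "internal node(s)\n")
  invisible(x)
}

#' Build a taxon map in memory
#'
#' @param tip_to_group named character vector: tip name -> group name.
#' @param group_to_role named character vector: group name -> one of
#'   `host_vertical`, `endosymbiont`, `donor`, `heterotroph`, `outgroup`.
#' @param query_tips,coquery_tips tips under analysis; co-query tips are
#'   treated as the same focal lineage as the query and are transparent to
#'   clade-composition tests.
#' @return a `taxon_map`.
#' @export
taxon_map <- function(tip_to_group, group_to_role,
                      query_tips = character(), coquery_tips = character()) {
  stopifnot(is.character(tip_to_group), !is.null(names(tip_to_group)),
            is.character(group_to_role), !is.null(names(group_to_role)))
  bad <- setdiff(unique(group_to_role), ROLE_NAMES)
  if (length(bad))
    stop2("unknown role(s) ", paste0("'", bad, "'", collapse = ", "),
          "; legal roles: ", paste(ROLE_NAMES, collapse = ", "))
  if (anyDuplicated(names(tip_to_group))) {
    d <- names(tip_to_group)[duplicated(names(tip_to_group))]
    stop2("tip(s) assigned more than once: ", paste(unique(d), collapse = ", "))
  }
  if (length(intersect(query_tips, coquery_tips)))
    stop2("query_tips and coquery_tips must be disjoint")
  structure(list(tip_to_group = tip_to_group,
                 group_to_role = group_to_role,
                 query_tips = query_tips,
                 coquery_tips = coquery_tips),
            class = "taxon_map")
}

#' Load a taxon map from TSV
#'
#' Accepts either one 3-column file (`tip`, `group`, `role`) or a
#' 2-column `tip`/`group` file plus a 2-column `group`/`role` file.
#'
#' @param path path to the tip table.
#' @param roles_path optional path to a separate group/role table.
#' @return a `taxon_map` (with empty query sets; queries are named at
#'   classification time).
#' @export
load_taxon_map <- function(path, roles_path = NULL) {
  tips <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tip", "group") %in% names(tips)))
    stop2("taxon map must have columns 'tip' and 'group' (got: ",
          paste(names(tips), collapse = ", "), ")")
  if (is.null(roles_path)) {
    if (!"role" %in% names(tips))
      stop2("3-column taxon map needs a 'role' column, ",
            "or pass roles_path for a separate group/role table")
    roles <- unique(tips[, c("group", "role")])
  } else {
    roles <- read.delim(roles_path, stringsAsFactors = FALSE)
    if (!all(c("group", "role") %in% names(roles)))
      stop2("roles table must have columns 'group' and 'role'")
  }
  dup <- duplicated(tips$tip)
  if (any(dup)) {
    two <- tapply(tips$group, tips$tip, function(g) length(unique(g)) > 1L)
    if (any(two))
      stop2("tip(s) listed with two different groups: ",
            paste(names(two)[two], collapse = ", "))
    tips <- tips[!dup, , drop = FALSE]
  }
  if (anyDuplicated(roles$group)) {
    two <- tapply(roles$role, roles$group,
                  function(r) length(unique(r)) > 1L)
    if (any(two))
      stop2("group(s) listed with two different roles: ",
            paste(names(two)[two], collapse = ", "))
    roles <- roles[!duplicated(roles$group), , drop = FALSE]
  }
  tg <- stats::setNames(tips$group, tips$tip)
  gr <- stats::setNames(roles$role, roles$group)
  taxon_map(tg, gr)
}

#' Cross-check a gene tree against a taxon map
#'
#' Pure report, never an error: lists tree tips absent from the map
#' (the classifier will treat them as singleton donor groups named
#' `unassigned:<tip>`), map entries absent from the tree, and whether at
#' least one outgroup-role tip is present in the tree.
#'
#' @param tree a `gene_tree`.
#' @param map a `taxon_map`.
#' @return a `validation_report` list with `unassigned_tips`,
#'   `missing_tips`, `has_outgroup`, `ok`.
#' @export
validate_tree_map <- function(tree, map) {
  stopifnot(inherits(tree, "gene_tree"), inherits(map, "taxon_map"))
  tips <- tree$phylo$tip.label
  known <- names(map$tip_to_group)
  unassigned <- setdiff(tips, known)
  missing <- setdiff(known, tips)
  roles <- map$group_to_role[map$tip_to_group[intersect(tips, known)]]
  has_outgroup <- any(roles == "outgroup", na.rm = TRUE)
  structure(list(unassigned_tips = unassigned, missing_tips = missing,
                 has_outgroup = has_outgroup,
                 ok = !length(unassigned) && !length(missing) && has_outgroup),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  if (length(x$unassigned_tips))
    cat("  tips not in map:", paste(x$unassigned_tips, collapse = ", "), "\n")
  if (length(x$missing_tips))
    cat("  map entries not in tree:",
        paste(x$missing_tips, collapse = ", "), "\n")
  if (!x$has_outgroup) cat("  no outgroup present\n")
  if (x$ok) cat("  ok\n")
  invisible(x)
}

## role of every tip under a map, with unassigned tips defaulting to a
## singleton donor group "unassigned:<tip>"
tip_roles <- function(tips, map) {
  grp <- map$tip_to_group[tips]
  un <- is.na(grp)
  grp[un] <- paste0("unassigned:", tips[un])
  role <- map$group_to_role[grp]
  role[is.na(role)] <- "donor"
  names(grp) <- names(role) <- tips
  list(group = grp, role = role)
}
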
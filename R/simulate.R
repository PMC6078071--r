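## Synthetic gene families with a known origin scenario. The scenario
## tree mirrors the taxon structure of the real alignments: a bacterial
## outgroup, a heterotrophic-eukaryote clade, one or more donor clades,
## and sister host (peridinin dinoflagellate) and endosymbiont clades.
## The query is grafted inside (or sister to) the clade selected by the
## generating scenario: VI -> host, EA -> endosymbiont, LA -> first
## donor. Sequences evolve along the tree under the Poisson (equal-rate,
## 20-state) amino-acid model, which admits an exact closed-form distance
## inversion used by the reconstruction stage.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Parameters of a synthetic gene-family scenario
#'
#' @param scenario `"VI"`, `"EA"` or `"LA"` — the true origin of the
#'   query gene.
#' @param n_host,n_endo,n_outgroup,n_heterotroph clade sizes (each >= 2
#'   so clade composition is testable).
#' @param donor_groups named integer vector of donor-clade sizes
#'   (each >= 2).
#' @param internal_branch,terminal_branch branch lengths in expected
#'   substitutions per site.
#' @param graft_depth `"nested"` (query sister to a member tip inside
#'   the target clade) or `"sister"` (query attached to the edge
#'   subtending the target clade).
#' @param seed integer seed; the whole generator is deterministic in it.
#' @return a `scenario_params` list.
#' @export
scenario_params <- function(scenario = c("VI", "EA", "LA"),
                            n_host = 6L, n_endo = 6L, n_outgroup = 3L,
                            n_heterotroph = 2L,
                            donor_groups = c(donor1 = 4L, donor2 = 4L),
                            internal_branch = 0.3, terminal_branch = 0.1,
                            graft_depth = c("nested", "sister"),
                            seed = 1L) {
  scenario <- match.arg(scenario)
  graft_depth <- match.arg(graft_depth)
  stopifnot(is_count(n_host, 2), is_count(n_endo, 2),
            is_count(n_outgroup, 2), is_count(n_heterotroph, 2),
            length(donor_groups) >= 1L, !is.null(names(donor_groups)),
            all(donor_groups >= 2),
            internal_branch > 0, terminal_branch > 0)
  structure(list(scenario = scenario, n_host = n_host, n_endo = n_endo,
                 n_outgroup = n_outgroup, n_heterotroph = n_heterotroph,
                 donor_groups = donor_groups,
                 internal_branch = internal_branch,
                 terminal_branch = terminal_branch,
                 graft_depth = graft_depth, seed = as.integer(seed)),
            class = "scenario_params")
}

## Balanced clade newick fragment (no subtending branch length; the
## caller appends it). Balanced shapes keep the tree diameter small so
## that realistic internal branches do not saturate pairwise distances.
clade_fragment <- function(tips, tb, ib) {
  if (length(tips) == 1L) return(tips)
  h <- ceiling(length(tips) / 2)
  left <- clade_fragment(tips[seq_len(h)], tb, ib)
  right <- clade_fragment(tips[-seq_len(h)], tb, ib)
  lb <- if (h == 1L) tb else ib
  rb <- if (length(tips) - h == 1L) tb else ib
  paste0("(", left, ":", lb, ",", right, ":", rb, ")")
}

## balanced join of several already-built fragments
join_fragments <- function(frags, ib) {
  while (length(frags) > 1L) {
    h <- ceiling(length(frags) / 2)
    frags <- c(
      paste0("(", frags[1L], ":", ib, ",", frags[2L], ":", ib, ")"),
      frags[-(1:2)])
  }
  frags[[1L]]
}

#' Build a scenario tree with a grafted query
#'
#' @param p a [scenario_params()].
#' @return a list with `tree` (the truth `gene_tree`, supports unset),
#'   `truth` (a `scenario_truth`: scenario, donor group, query id) and
#'   `map` (the matching [taxon_map()] with the query registered).
#' @export
build_scenario_tree <- function(p) {
  stopifnot(inherits(p, "scenario_params"))
  tb <- p$terminal_branch; ib <- p$internal_branch
  groups <- c(list(host = paste0("host", seq_len(p$n_host)),
                   endo = paste0("endo", seq_len(p$n_endo)),
                   outgroup = paste0("out", seq_len(p$n_outgroup)),
                   het = paste0("het", seq_len(p$n_heterotroph))),
              lapply(stats::setNames(seq_along(p$donor_groups),
                                     names(p$donor_groups)),
                     function(i) paste0(names(p$donor_groups)[i],
                                        "_", seq_len(p$donor_groups[i]))))
  target_group <- switch(p$scenario, VI = "host", EA = "endo",
                         LA = names(p$donor_groups)[1L])
  query <- "query1"
  frag <- lapply(groups, clade_fragment, tb = tb, ib = ib)
  with_seed(p$seed, {
    if (p$graft_depth == "nested") {
      anchor <- sample(groups[[target_group]], 1L)
      cherry <- paste0("(", query, ":", tb, ",", anchor, ":", tb, "):", ib)
      frag[[target_group]] <- clade_fragment(groups[[target_group]], tb, ib)
      frag[[target_group]] <- sub(paste0("(?<![A-Za-z0-9_])", anchor, ":",
                                         tb, "(?![0-9])"),
                                  cherry, frag[[target_group]], perl = TRUE)
    } else {
      ## the caller appends this fragment's own subtending branch length
      frag[[target_group]] <- paste0("(", query, ":", tb, ",",
                                     frag[[target_group]], ":", ib, ")")
    }
  })
  ## shallow backbone: (outgroup, heterotrophs, (donors, (host, endo)))
  hostendo <- paste0("(", frag$host, ":", ib, ",", frag$endo, ":", ib, ")")
  donors <- join_fragments(unname(frag[names(p$donor_groups)]), ib)
  inner <- paste0("(", donors, ":", ib, ",", hostendo, ":", ib, ")")
  nwk <- paste0("(", frag$outgroup, ":", ib, ",", frag$het, ":", ib, ",",
                inner, ":", ib, ");")
  tree <- parse_newick(nwk)

  tip_groups <- c(stats::setNames(rep(names(groups),
                                      lengths(groups)), unlist(groups)),
                  stats::setNames("focal", query))
  roles <- c(host = "host_vertical", endo = "endosymbiont",
             outgroup = "outgroup", het = "heterotroph",
             stats::setNames(rep("donor", length(p$donor_groups)),
                             names(p$donor_groups)),
             focal = "donor")
  map <- taxon_map(tip_groups, roles, query_tips = query)
  truth <- structure(list(scenario = p$scenario,
                          donor_group = target_group,
                          query_id = query, true_tree = tree),
                     class = "scenario_truth")
  list(tree = tree, truth = truth, map = map)
}

expected_mismatch <- function(d) (19 / 20) * (1 - exp(-20 * d / 19))

#' Evolve an amino-acid alignment along a tree (Poisson model)
#'
#' The root sequence is i.i.d. uniform over the 20 amino acids; each
#' site evolves independently, and along a branch of length `d` the
#' probability that the child differs from the parent at a site is
#' `(19/20) * (1 - exp(-20 d / 19))`, with the replacement uniform over
#' the other 19 residues. No rate heterogeneity, no indels.
#'
#' @param tree a `gene_tree` with branch lengths.
#' @param length alignment length in columns (>= 1).
#' @param seed integer seed.
#' @return a named character vector of ungapped aligned sequences.
#' @export
simulate_alignment <- function(tree, length, seed = 1L) {
  stopifnot(inherits(tree, "gene_tree"), is_count(length, 1))
  phy <- tree$phylo
  if (is.null(phy$edge.length)) stop2("tree has no branch lengths")
  ntip <- base::length(phy$tip.label)
  nn <- ntip + phy$Nnode
  with_seed(seed, {
    seqs <- matrix(0L, nrow = nn, ncol = length)
    root <- ntip + 1L
    seqs[root, ] <- sample.int(20L, length, replace = TRUE)
    ord <- ape::reorder.phylo(phy, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
      d <- ord$edge.length[k]
      s <- seqs[parent, ]
      mut <- runif(length) < expected_mismatch(d)
      nmut <- sum(mut)
      if (nmut)  # uniform over the 19 non-parent states
        s[mut] <- ((s[mut] + sample.int(19L, nmut, replace = TRUE) - 1L)
                   %% 20L) + 1L
      seqs[child, ] <- s
    }
    out <- apply(seqs[seq_len(ntip), , drop = FALSE], 1L,
                 function(x) paste(AA_ALPHABET[x], collapse = ""))
    stats::setNames(out, phy$tip.label)
  })
}

#' Generate one synthetic gene family and (optionally) write it to disk
#'
#' @param p a [scenario_params()].
#' @param length alignment length in columns.
#' @param out_prefix when non-NULL, writes `<prefix>.true.nwk`,
#'   `<prefix>.fasta`, `<prefix>.taxa.tsv` and `<prefix>.truth.json`.
#' @return a list with `tree`, `truth`, `map`, `msa`.
#' @export
simulate_family <- function(p, length = 500L, out_prefix = NULL) {
  fam <- build_scenario_tree(p)
  fam$msa <- simulate_alignment(fam$tree, length, seed = p$seed + 1L)
  if (!is.null(out_prefix)) {
    write_newick(fam$tree, paste0(out_prefix, ".true.nwk"))
    writeLines(paste0(">", names(fam$msa), "\n", fam$msa),
               paste0(out_prefix, ".fasta"))
    tg <- fam$map$tip_to_group
    write.table(data.frame(tip = names(tg), group = unname(tg),
                           role = unname(fam$map$group_to_role[tg])),
                paste0(out_prefix, ".taxa.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(scenario = fam$truth$scenario,
                              donor_group = fam$truth$donor_group,
                              query_id = fam$truth$query_id),
                         paste0(out_prefix, ".truth.json"),
                         auto_unbox = TRUE)
  }
  fam
}
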
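## Pathway registry: the three plastid-localized biosynthetic pathways
## (C5 heme, chlorophyll a, non-mevalonate IPP) as queryable static data.
## The registry ships as a TSV under inst/extdata so it can be audited row
## by row; it is parsed once per session and cached.

.registry_cache <- new.env(parent = emptyenv())

PATHWAY_NAMES <- c("heme_C5", "chlorophyll_a", "non_mevalonate")

registry_table <- function() {
  if (is.null(.registry_cache$tab)) {
    path <- system.file("extdata", "pathway_registry.tsv",
                        package = "plastidorigin", mustWork = TRUE)
    tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
    tab$koids <- as.character(tab$koids)
    .registry_cache$tab <- tab
  }
  .registry_cache$tab
}

split_koids <- function(x) {
  out <- unlist(strsplit(x, ",", fixed = TRUE))
  out[nzchar(out)]
}

build_step <- function(rows) {
  koids <- unique(split_koids(paste(rows$koids, collapse = ",")))
  alternatives <- rows$component[rows$kind == "alternative"]
  subunits <- rows$component[rows$kind == "subunit"]
  comp <- unique(rows$compartment)
  compartment <- if (length(comp) == 1L) comp else "mixed"
  structure(
    list(
      index = rows$step_index[1L],
      enzyme_name = rows$enzyme[1L],
      ec_or_koids = koids,
      alternatives = alternatives,
      subunits = subunits,
      substrate = rows$substrate[1L],
      product = rows$product[1L],
      compartment_note = compartment,
      components = rows[, c("component", "kind", "koids", "compartment", "note")]
    ),
    class = "pathway_step"
  )
}

#' Retrieve one of the three plastid-localized pathways
#'
#' Returns the ordered enzymatic steps of the C5 heme pathway
#' (glutamyl-tRNA to protoheme, 9 steps), the chlorophyll a pathway
#' (protoporphyrin IX to Chl a, 6 steps) or the non-mevalonate IPP pathway
#' (pyruvate + G3P to IPP, 7 steps). A step catalyzed by isofunctional but
#' evolutionarily distinct enzymes (e.g. hemN/hemF for CPOX) counts once
#' and carries its variants in `alternatives`; multi-subunit enzymes such
#' as Mg-chelatase carry independently classifiable `subunits`.
#'
#' @param name one of `"heme_C5"`, `"chlorophyll_a"`, `"non_mevalonate"`.
#' @return an object of class `pathway`: a list with `name` and `steps`
#'   (a list of `pathway_step` objects).
#' @examples
#' p <- get_pathway("heme_C5")
#' count_steps(p)
#' @export
get_pathway <- function(name) {
  if (!is_string(name) || !name %in% PATHWAY_NAMES) {
    stop2("unknown pathway '", paste(name, collapse = ","),
          "'; valid options: ", paste(PATHWAY_NAMES, collapse = ", "))
  }
  tab <- registry_table()
  tab <- tab[tab$pathway == name, , drop = FALSE]
  steps <- lapply(split(tab, tab$step_index), build_step)
  steps <- steps[order(vapply(steps, `[[`, 1, "index"))]
  names(steps) <- vapply(steps, `[[`, "", "enzyme_name")
  structure(list(name = name, steps = steps), class = "pathway")
}

#' Number of enzymatic steps in a pathway
#'
#' A step with isofunctional alternatives counts once.
#'
#' @param pathway a `pathway` from [get_pathway()].
#' @return integer step count.
#' @export
count_steps <- function(pathway) {
  stopifnot(inherits(pathway, "pathway"))
  length(pathway$steps)
}

#' Steps catalyzed by two or more evolutionarily distinct enzymes
#'
#' @param pathway a `pathway` from [get_pathway()].
#' @return list of `pathway_step` objects whose `alternatives` is
#'   non-empty, in step order.
#' @export
dual_enzyme_steps <- function(pathway) {
  stopifnot(inherits(pathway, "pathway"))
  keep <- vapply(pathway$steps, function(s) length(s$alternatives) > 0L, NA)
  pathway$steps[keep]
}

#' Export the registry as a flat table
#'
#' One row per pathway step with comma-separated KO identifiers and
#' alternative names, mirroring the shipped registry data file.
#'
#' @param format `"tsv"` (tab-delimited text, invisibly returned) or
#'   `"data.frame"`.
#' @param file optional path to write the TSV to.
#' @return a data.frame (or its TSV rendering, invisibly, when a file is
#'   written).
#' @export
registry_dump <- function(format = c("data.frame", "tsv"), file = NULL) {
  format <- match.arg(format)
  rows <- lapply(PATHWAY_NAMES, function(nm) {
    p <- get_pathway(nm)
    do.call(rbind, lapply(p$steps, function(s) {
      data.frame(
        pathway = nm, step_index = s$index, enzyme = s$enzyme_name,
        koids = paste(s$ec_or_koids, collapse = ","),
        alternatives = paste(s$alternatives, collapse = ","),
        compartment = s$compartment_note,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (format == "tsv" || !is.null(file)) {
    con <- file %||% stdout()
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @export
print.pathway <- function(x, ...) {
  cat("<pathway>", x$name, "with", length(x$steps), "steps:\n")
  for (s in x$steps) {
    alt <- if (length(s$alternatives))
      paste0(" [", paste(s$alternatives, collapse = "/"), "]") else ""
    cat(sprintf("  %d. %s%s: %s -> %s\n", s$index, s$enzyme_name, alt,
                s$substrate, s$product))
  }
  invisible(x)
}
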
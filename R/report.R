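## Aggregation of origin calls into the pathway x species x step
## origin-type overview (the summary-figure layout of the source
## analysis), plain-text/TSV rendering, and the one-config pipeline
## driver (simulate -> reconstruct -> classify -> report).

CALL_TYPES <- c("VI", "EA", "LA", "UNCERTAIN")

#' Aggregate origin calls into a pathway x species x step matrix
#'
#' Each non-cytosolic call is tallied into its assigned cell; cytosolic
#' calls are excluded from the cells and counted in the
#' `cytosolic_excluded` column. Steps with no calls keep zero
#' multiplicity (an empty cell is distinct from an uncertain one).
#'
#' @param calls list of `origin_call`s.
#' @param assignments data.frame with columns `query_id`, `species`,
#'   `pathway`, `step` (enzyme name as in the registry).
#' @return an `origin_matrix` data.frame with columns species, pathway,
#'   step_index, step, n_versions, n_VI, n_EA, n_LA, n_uncertain,
#'   cytosolic_excluded, covering every registry step for every species
#'   present.
#' @export
aggregate_calls <- function(calls, assignments) {
  if (inherits(calls, "origin_call")) calls <- list(calls)
  stopifnot(is.data.frame(assignments),
            all(c("query_id", "species", "pathway", "step") %in%
                names(assignments)))
  reg <- registry_dump("data.frame")
  key <- paste(reg$pathway, reg$enzyme)
  bad <- !paste(assignments$pathway, assignments$step) %in% key
  if (any(bad))
    stop2("assignment(s) to unknown pathway step: ",
          paste(unique(paste(assignments$pathway[bad],
                             assignments$step[bad])), collapse = "; "))
  species <- sort(unique(assignments$species))
  if (!length(species)) {
    grid <- data.frame(species = character(), pathway = character(),
                       step_index = integer(), step = character(),
                       n_versions = integer(), n_VI = integer(),
                       n_EA = integer(), n_LA = integer(),
                       n_uncertain = integer(),
                       cytosolic_excluded = integer(),
                       stringsAsFactors = FALSE)
    return(structure(grid, class = c("origin_matrix", "data.frame")))
  }
  grid <- do.call(rbind, lapply(species, function(sp) {
    data.frame(species = sp, pathway = reg$pathway,
               step_index = reg$step_index, step = reg$enzyme,
               n_versions = 0L, n_VI = 0L, n_EA = 0L, n_LA = 0L,
               n_uncertain = 0L, cytosolic_excluded = 0L,
               stringsAsFactors = FALSE)
  }))
  for (call in calls) {
    a <- assignments[assignments$query_id == call$query_id, , drop = FALSE]
    if (!nrow(a))
      stop2("no step assignment for query '", call$query_id, "'")
    a <- a[1L, ]
    row <- which(grid$species == a$species & grid$pathway == a$pathway &
                 grid$step == a$step)
    if (call$cytosolic) {
      grid$cytosolic_excluded[row] <- grid$cytosolic_excluded[row] + 1L
      next
    }
    grid$n_versions[row] <- grid$n_versions[row] + 1L
    col <- paste0("n_", if (call$call == "UNCERTAIN") "uncertain" else
                  call$call)
    grid[[col]][row] <- grid[[col]][row] + 1L
  }
  structure(grid, class = c("origin_matrix", "data.frame"))
}

#' Render an origin matrix
#'
#' @param matrix an `origin_matrix` from [aggregate_calls()].
#' @param format `"tsv"` for a tab-delimited table, `"text"` for a
#'   per-pathway grid with symbols V/E/L/? (and `.` for empty cells).
#' @return a character vector of output lines.
#' @export
render_matrix <- function(matrix, format = c("tsv", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "origin_matrix"))
  if (format == "tsv") {
    header <- paste(names(matrix), collapse = "\t")
    if (!nrow(matrix)) return(header)
    rows <- apply(matrix, 1L, function(r) paste(trimws(r), collapse = "\t"))
    return(c(header, unname(rows)))
  }
  lines <- character()
  for (pw in unique(matrix$pathway)) {
    sub <- matrix[matrix$pathway == pw, , drop = FALSE]
    lines <- c(lines, paste0("== ", pw, " =="))
    for (sp in unique(sub$species)) {
      ss <- sub[sub$species == sp, , drop = FALSE]
      ss <- ss[order(ss$step_index), , drop = FALSE]
      cells <- vapply(seq_len(nrow(ss)), function(i) {
        r <- ss[i, ]
        if (r$n_versions == 0L) return(".")
        paste0(strrep("V", r$n_VI), strrep("E", r$n_EA),
               strrep("L", r$n_LA), strrep("?", r$n_uncertain))
      }, "")
      lines <- c(lines, paste0(formatC(sp, width = 12, flag = "-"),
                               paste(formatC(ss$step, width = 8),
                                     collapse = "")),
                 paste0(strrep(" ", 12),
                        paste(formatC(cells, width = 8), collapse = "")))
    }
  }
  lines
}

#' Parse a TSV rendering back into an origin matrix
#'
#' Inverse of `render_matrix(..., "tsv")`; render -> parse -> render is
#' a fixed point.
#'
#' @param lines character vector of TSV lines (or a file path).
#' @return an `origin_matrix`.
#' @export
parse_matrix_tsv <- function(lines) {
  if (length(lines) == 1L && file.exists(lines))
    lines <- readLines(lines)
  con <- textConnection(lines)
  on.exit(close(con))
  out <- read.delim(con, stringsAsFactors = FALSE)
  structure(out, class = c("origin_matrix", "data.frame"))
}

## ---- run configuration -------------------------------------------------

CONFIG_KEYS <- list(
  top = "mode",
  simulate = c("scenarios", "reps", "seed", "n_host", "n_endo",
               "n_outgroup", "n_heterotroph", "donors", "internal_branch",
               "terminal_branch", "graft_depth", "length"),
  reconstruct = c("bootstrap", "seed"),
  classify = c("mlbp_min", "bpp_min", "support_rule", "max_foreign_tips",
               "allow_exclusion_la", "outgroup_required",
               "long_branch_factor", "tree", "taxa", "query",
               "assignments", "species"),
  report = "out_dir"
)

#' Parse a flat key-value run configuration
#'
#' Sections are introduced by `[simulate]`, `[reconstruct]`,
#' `[classify]`, `[report]`; entries are `key: value` lines; `#` starts
#' a comment. Unknown sections or keys are startup errors naming the
#' offender.
#'
#' @param path config file path.
#' @return nested named list of sections.
#' @export
parse_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list(top = list())
  section <- "top"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(CONFIG_KEYS))
        stop2("unknown config section [", section, "]")
      cfg[[section]] <- cfg[[section]] %||% list()
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop2("malformed config line: ", ln)
    key <- kv[2]; val <- trimws(kv[3])
    if (!key %in% CONFIG_KEYS[[section]])
      stop2("unknown config key '", key, "' in section [", section, "]")
    cfg[[section]][[key]] <- val
  }
  cfg
}

cfg_num <- function(x, default) if (is.null(x)) default else as.numeric(x)
cfg_int <- function(x, default) if (is.null(x)) default else as.integer(x)
cfg_lgl <- function(x, default) {
  if (is.null(x)) default else toupper(x) %in% c("TRUE", "YES", "1")
}

config_to_classification <- function(cl) {
  lbf <- cl$long_branch_factor
  classification_config(
    mlbp_min = cfg_num(cl$mlbp_min, 50),
    bpp_min = cfg_num(cl$bpp_min, 0.95),
    support_rule = cl$support_rule %||% "or",
    max_foreign_tips = cfg_int(cl$max_foreign_tips, 0L),
    allow_exclusion_la = cfg_lgl(cl$allow_exclusion_la, TRUE),
    outgroup_required = cfg_lgl(cl$outgroup_required, TRUE),
    long_branch_factor = if (is.null(lbf) || toupper(lbf) == "OFF") NULL
                         else as.numeric(lbf))
}

parse_donors <- function(x) {
  if (is.null(x)) return(c(donor1 = 4L, donor2 = 4L))
  parts <- strsplit(strsplit(x, ",")[[1]], ":")
  stats::setNames(vapply(parts, function(p) as.integer(p[2]), 0L),
                  vapply(parts, `[[`, "", 1L))
}

#' Run the full pipeline from one configuration
#'
#' Synthetic mode simulates gene families for each scenario, rebuilds
#' the trees with bootstrap NJ, classifies the query of each family and
#' writes `calls.tsv`, `matrix.tsv`, `recovery_summary.tsv` and
#' `run.log`. Real mode classifies named queries on an existing newick
#' tree + taxon map and writes `calls.tsv` (plus `matrix.tsv` when a
#' step-assignment table is given) and `run.log`. Per-family failures
#' are logged and the pipeline continues.
#'
#' @param config path to a run file (see [parse_run_config()]) or an
#'   equivalent nested list.
#' @param out_dir output directory (overrides the config's
#'   `[report] out_dir`).
#' @return invisibly, a list with `calls` (data.frame) and, in synthetic
#'   mode, `recovery` (per-scenario correct/incorrect/uncertain counts).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) parse_run_config(config) else config
  out_dir <- out_dir %||% cfg$report$out_dir %||% stop2("no out_dir set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mode <- cfg$top$mode %||% "synthetic"
  ccfg <- config_to_classification(cfg$classify %||% list())
  log <- c(paste("plastidorigin", as.character(utils::packageVersion("plastidorigin"))),
           paste("mode:", mode),
           paste("config:", paste(deparse(cfg), collapse = " ")))
  if (mode == "synthetic") {
    sim <- cfg$simulate %||% list()
    scenarios <- strsplit(sim$scenarios %||% "VI,EA,LA", ",")[[1]]
    reps <- cfg_int(sim$reps, 5L)
    seed0 <- cfg_int(sim$seed, 1L)
    B <- cfg_int(cfg$reconstruct$bootstrap, 100L)
    len <- cfg_int(sim$length, 500L)
    log <- c(log, paste("base seed:", seed0), paste("bootstrap:", B))
    calls <- list(); assign_rows <- list(); recov <- list()
    reg <- registry_dump("data.frame")
    fam_i <- 0L
    for (sc in scenarios) {
      tally <- c(correct = 0L, incorrect = 0L, uncertain = 0L)
      for (r in seq_len(reps)) {
        fam_i <- fam_i + 1L
        seed <- seed0 + 1000L * fam_i
        res <- tryCatch({
          p <- scenario_params(
            scenario = sc,
            n_host = cfg_int(sim$n_host, 6L),
            n_endo = cfg_int(sim$n_endo, 6L),
            n_outgroup = cfg_int(sim$n_outgroup, 3L),
            n_heterotroph = cfg_int(sim$n_heterotroph, 2L),
            donor_groups = parse_donors(sim$donors),
            internal_branch = cfg_num(sim$internal_branch, 0.3),
            terminal_branch = cfg_num(sim$terminal_branch, 0.1),
            graft_depth = sim$graft_depth %||% "nested",
            seed = seed)
          fam <- simulate_family(p, length = len)
          tre <- bootstrap_support(fam$msa, B = B, seed = seed + 1L)
          call <- classify_query(tre, fam$truth$query_id, fam$map, ccfg)
          list(call = call, truth = fam$truth)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          log <- c(log, paste0("family ", fam_i, " (", sc, " rep ", r,
                               ") failed: ", conditionMessage(res)))
          next
        }
        qid <- paste0(sc, "_rep", r)
        res$call$query_id <- qid
        calls[[qid]] <- res$call
        step_row <- reg[((fam_i - 1L) %% nrow(reg)) + 1L, ]
        assign_rows[[qid]] <- data.frame(query_id = qid,
                                         species = "synthetic",
                                         pathway = step_row$pathway,
                                         step = step_row$enzyme,
                                         stringsAsFactors = FALSE)
        tally[[if (res$call$call == res$truth$scenario) "correct"
               else if (res$call$call == "UNCERTAIN") "uncertain"
               else "incorrect"]] <-
          tally[[if (res$call$call == res$truth$scenario) "correct"
                 else if (res$call$call == "UNCERTAIN") "uncertain"
                 else "incorrect"]] + 1L
      }
      recov[[sc]] <- data.frame(scenario = sc, correct = tally["correct"],
                                incorrect = tally["incorrect"],
                                uncertain = tally["uncertain"],
                                row.names = NULL)
    }
    calls_df <- calls_to_data_frame(calls)
    assignments <- do.call(rbind, assign_rows)
    mat <- aggregate_calls(calls, assignments)
    recovery <- do.call(rbind, recov)
    write.table(calls_df, file.path(out_dir, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(render_matrix(mat, "tsv"), file.path(out_dir, "matrix.tsv"))
    write.table(recovery, file.path(out_dir, "recovery_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log, file.path(out_dir, "run.log"))
    return(invisible(list(calls = calls_df, matrix = mat,
                          recovery = recovery)))
  }
  if (mode != "real") stop2("unknown mode '", mode, "'")
  cl <- cfg$classify %||% list()
  if (is.null(cl$tree) || is.null(cl$taxa))
    stop2("real mode needs [classify] keys 'tree' and 'taxa'")
  if (!file.exists(cl$tree)) stop2("missing tree file: ", cl$tree)
  if (!file.exists(cl$taxa)) stop2("missing taxon map: ", cl$taxa)
  tree <- parse_newick(paste(readLines(cl$tree), collapse = ""))
  map <- load_taxon_map(cl$taxa)
  queries <- strsplit(cl$query %||% stop2("real mode needs 'query'"),
                      ",")[[1]]
  calls <- classify_tree(tree, queries, map, ccfg)
  calls_df <- calls_to_data_frame(calls)
  write.table(calls_df, file.path(out_dir, "calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mat <- NULL
  if (!is.null(cl$assignments)) {
    assignments <- read.delim(cl$assignments, stringsAsFactors = FALSE)
    mat <- aggregate_calls(calls, assignments)
    writeLines(render_matrix(mat, "tsv"), file.path(out_dir, "matrix.tsv"))
  }
  for (call in calls)
    log <- c(log, sprintf("%s: %s (MLBP %s, BPP %s) clade [%s]",
                          call$query_id, call$call,
                          format(call$evidence_support$mlbp),
                          format(call$evidence_support$bpp),
                          paste(call$evidence_clade, collapse = ",")))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(list(calls = calls_df, matrix = mat))
}
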
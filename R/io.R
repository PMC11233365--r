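# ---- trees ------------------------------------------------------------------

#' Read a rooted phylogenetic tree with exact branch lengths
#'
#' Parses Newick text (or a file containing it) with \pkg{ape} and converts
#' every branch length to an exact rational through its decimal
#' representation, so that downstream cluster and split weights are exact.
#' Missing branch lengths are treated as 0.
#'
#' @param source Newick text, or the path of a file holding it.
#' @return An object of class `pdindex_tree`: a list with the `phylo` tree
#'   and a `pdindex_rq` vector `edge_weight` aligned with its edge matrix.
#' @examples
#' tr <- read_newick(example_tree_newick())
#' taxa(tr)
#' @export
read_newick <- function(source) {
  text <- if (length(source) == 1 && !grepl("[();]", source) && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "")
  } else {
    paste(source, collapse = "")
  }
  nopen <- lengths(regmatches(text, gregexpr("\\(", text)))
  nclose <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (nopen != nclose) {
    stop("Newick parse error: ", nopen, " '(' vs ", nclose, " ')'", call. = FALSE)
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(phy)) stop("Newick parse error: no tree found", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf labels", call. = FALSE)
  ew <- if (is.null(phy$edge.length)) rq_zero(nrow(phy$edge)) else as_rq(phy$edge.length)
  out <- structure(list(phylo = phy, edge_weight = ew), class = "pdindex_tree")
  attr(out, "taxa") <- sort(phy$tip.label)
  out
}

#' @export
print.pdindex_tree <- function(x, ...) {
  cat("# A weighted rooted tree on {", paste(taxa(x), collapse = ", "), "}, total length ",
      format(rq_sum(x$edge_weight)), "\n", sep = "")
  print(x$phylo)
  invisible(x)
}

tree_leafsets <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
  # edges in postorder so children are resolved before parents
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]
    ch <- phy$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Clusters of a rooted weighted tree
#'
#' Each edge induces the cluster of leaves below it, weighted by the branch
#' length. Clusters arising from several edges (unresolved degree-2 chains)
#' are merged with summed weights and a warning.
#'
#' @param tree a `pdindex_tree` from [read_newick()].
#' @return A weighted cluster system.
#' @export
tree_to_clusters <- function(tree) {
  phy <- tree$phylo
  below <- tree_leafsets(phy)
  clusters <- lapply(phy$edge[, 2], function(v) sort(below[[v]]))
  cluster_system(clusters, weights = tree$edge_weight, taxa = taxa(tree))
}

#' Splits of a weighted tree, after unrooting
#'
#' Each edge induces the split of the leaves below it against the rest. A
#' degree-2 root is suppressed: its two incident edges induce the same
#' split, whose weights are summed (silently — this is the standard
#' unrooting step, not a data problem). Trivial splits are kept.
#'
#' @param tree a `pdindex_tree` with at least 2 leaves.
#' @return A weighted split system.
#' @export
tree_to_splits <- function(tree) {
  phy <- tree$phylo
  tx <- taxa(tree)
  if (length(tx) < 2) stop("need at least 2 leaves to form splits", call. = FALSE)
  below <- tree_leafsets(phy)
  keys <- character(nrow(phy$edge))
  sides <- vector("list", nrow(phy$edge))
  for (e in seq_len(nrow(phy$edge))) {
    side <- sort(below[[phy$edge[e, 2]]])
    sides[[e]] <- side
    keys[e] <- split_key(side, tx)
  }
  ukeys <- unique(keys)
  w <- vctrs::vec_init(new_rq(), length(ukeys))
  for (i in seq_along(ukeys)) w[i] <- rq_sum(tree$edge_weight[keys == ukeys[i]])
  split_system(sides[match(ukeys, keys)], weights = w, taxa = tx)
}

# ---- tabular formats --------------------------------------------------------

read_system_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !grepl("^#taxa:", lines[1])) {
    stop("missing '#taxa:' header in ", path, call. = FALSE)
  }
  tx <- trimws(strsplit(sub("^#taxa:", "", lines[1]), ",")[[1]])
  body <- lines[-1]
  members <- list()
  weights <- character(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t")[[1]]
    if (length(parts) != 2) {
      stop("malformed line ", i + 1, " in ", path, ": expected '<members>\\t<weight>'",
           call. = FALSE)
    }
    members[[i]] <- trimws(strsplit(parts[1], ",")[[1]])
    weights[i] <- trimws(parts[2])
  }
  list(taxa = tx, members = members, weights = as_rq(weights))
}

#' Read and write weighted systems as TSV
#'
#' A minimal diff-friendly text format: a `#taxa: a,b,c` header followed by
#' one line per cluster (or per split, listing one part; the complement is
#' implied), members comma-separated, then a tab and the weight as an exact
#' fraction or decimal string. Round trips preserve rationals exactly.
#' Duplicate records are merged with summed weights and a warning.
#'
#' @param path file path.
#' @param system the system to write.
#' @return Readers return the system; writers return `path` invisibly.
#' @export
read_cluster_tsv <- function(path) {
  p <- read_system_tsv(path)
  cluster_system(p$members, weights = p$weights, taxa = p$taxa)
}

#' @rdname read_cluster_tsv
#' @export
read_split_tsv <- function(path) {
  p <- read_system_tsv(path)
  split_system(p$members, weights = p$weights, taxa = p$taxa)
}

#' @rdname read_cluster_tsv
#' @export
write_cluster_tsv <- function(system, path) {
  lines <- c(paste0("#taxa: ", paste(taxa(system), collapse = ",")),
             paste0(system$label, "\t", format(system$weight)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_cluster_tsv
#' @export
write_split_tsv <- function(system, path) {
  lines <- c(paste0("#taxa: ", paste(taxa(system), collapse = ",")),
             paste0(vapply(system$side_a, paste, "", collapse = ","), "\t",
                    format(system$weight)))
  writeLines(lines, path)
  invisible(path)
}

# ---- NEXUS splits blocks ----------------------------------------------------

#' Read and write NEXUS splits blocks (SplitsTree dialect)
#'
#' Writes TAXA and SPLITS blocks with 1-based taxon indices, WEIGHTS, and an
#' optional CYCLE statement carrying a circular ordering. The reader accepts
#' the same dialect, converts weights exactly, and — when a CYCLE is present
#' — validates it against the splits with [is_circular()], attaching the
#' ordering as attribute `"ordering"` of the result.
#'
#' @param path file path.
#' @param sw a weighted split system.
#' @param ordering optional circular ordering to record as CYCLE.
#' @return The reader returns a `pdindex_splits`; the writer returns `path`
#'   invisibly.
#' @export
read_nexus_splits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  text <- paste(lines, collapse = "\n")
  if (!grepl("#NEXUS", text, ignore.case = TRUE)) stop("not a NEXUS file", call. = FALSE)
  # taxa
  tl <- regmatches(text, regexpr("TAXLABELS[^;]*;", text, ignore.case = TRUE))
  if (length(tl) == 0) stop("no TAXLABELS found", call. = FALSE)
  tx <- strsplit(trimws(sub(";$", "", sub("^TAXLABELS", "", tl, ignore.case = TRUE))),
                 "[[:space:]]+")[[1]]
  tx <- gsub("^'|'$", "", tx[nzchar(tx)])
  # cycle (optional)
  cyc <- regmatches(text, regexpr("CYCLE[^;]*;", text, ignore.case = TRUE))
  ordering <- NULL
  if (length(cyc) == 1) {
    idx <- as.integer(strsplit(trimws(sub(";$", "", sub("^CYCLE", "", cyc,
                                                        ignore.case = TRUE))),
                               "[[:space:]]+")[[1]])
    ordering <- tx[idx]
  }
  # splits matrix: inside the SPLITS block
  block <- regmatches(text, regexpr("BEGIN SPLITS.*?END;", text,
                                    ignore.case = TRUE))
  if (length(block) == 0) stop("no SPLITS block found", call. = FALSE)
  mat <- regmatches(block, regexpr("MATRIX.*?;", block, ignore.case = TRUE))
  rows <- strsplit(sub("^MATRIX", "", sub(";$", "", mat), ignore.case = TRUE), ",")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  sides <- list()
  weights <- character(0)
  for (i in seq_along(rows)) {
    toks <- strsplit(rows[i], "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    toks <- toks[!grepl("^\\[", toks)]  # optional [label]
    weights[i] <- toks[1]
    ids <- suppressWarnings(as.integer(toks[-1]))
    if (anyNA(ids)) stop("malformed MATRIX row ", i, call. = FALSE)
    sides[[i]] <- tx[ids]
  }
  out <- split_system(sides, weights = as_rq(weights), taxa = tx)
  if (!is.null(ordering)) {
    if (!isTRUE(is_circular(out, ordering))) {
      warning("CYCLE ordering does not make the split system circular", call. = FALSE)
    }
    attr(out, "ordering") <- ordering
  }
  out
}

#' @rdname read_nexus_splits
#' @export
write_nexus_splits <- function(sw, path, ordering = NULL) {
  tx <- taxa(sw)
  ordering <- ordering %||% attr(sw, "ordering")
  lines <- c(
    "#NEXUS",
    "BEGIN TAXA;",
    paste0("DIMENSIONS NTAX=", length(tx), ";"),
    paste0("TAXLABELS ", paste(tx, collapse = " "), ";"),
    "END;",
    "BEGIN SPLITS;",
    paste0("DIMENSIONS NTAX=", length(tx), " NSPLITS=", nrow(sw), ";"),
    "FORMAT LABELS=NO WEIGHTS=YES;"
  )
  if (!is.null(ordering)) {
    lines <- c(lines, paste0("CYCLE ", paste(match(ordering, tx), collapse = " "), ";"))
  }
  rows <- vapply(seq_len(nrow(sw)), function(i) {
    paste0(format(sw$weight[i]), " ",
           paste(match(sw$side_a[[i]], tx), collapse = " "), ",")
  }, "")
  lines <- c(lines, "MATRIX", rows, ";", "END;")
  writeLines(lines, path)
  invisible(path)
}

# ---- JSON export ------------------------------------------------------------

#' Write an index vector or property report as JSON
#'
#' Index vectors are written as `{"taxon": {"value": ..., "fraction": ...}}`
#' objects; property reports as an object of booleans plus notes. Exact
#' fractions are carried as strings so nothing is lost to decimal rounding.
#'
#' @param x a `pdindex_index` or `pdindex_properties`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_index_json <- function(x, path) {
  obj <- if (inherits(x, "pdindex_index")) {
    vals <- lapply(seq_len(nrow(x)), function(i) {
      list(value = as.double(x$value[i]), fraction = format(x$value[i]))
    })
    stats::setNames(vals, x$taxon)
  } else if (inherits(x, "pdindex_properties")) {
    x[c("complete", "nonnegative", "neutrality", "descendant_diversity", "notes")]
  } else {
    stop("cannot serialize objects of class ", class(x)[1], call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- PHYLIP distances -------------------------------------------------------

#' Export induced distances as a PHYLIP square matrix
#'
#' Writes the symmetric zero-diagonal distance matrix of
#' [split_distances()] in PHYLIP format (taxon count, then one row per
#' taxon). PHYLIP is a decimal format, so values are written as decimals
#' with up to 12 significant digits.
#'
#' @param distances a `pdindex_distances` tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(distances, path) {
  tx <- attr(distances, "taxa")
  n <- length(tx)
  d <- matrix(0, n, n, dimnames = list(tx, tx))
  for (i in seq_len(nrow(distances))) {
    v <- as.double(distances$distance[i])
    d[distances$x[i], distances$y[i]] <- v
    d[distances$y[i], distances$x[i]] <- v
  }
  rows <- vapply(seq_len(n), function(i) {
    paste(formatC(tx[i], width = 10, flag = "-"),
          paste(formatC(d[i, ], format = "g", digits = 12), collapse = " "))
  }, "")
  writeLines(c(as.character(n), rows), path)
  invisible(path)
}
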
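#' Read a rooted tree from a newick string or file
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' ape `phylo` object, the universal substrate for every method in the
#' package. Quoted labels are unquoted, missing branch lengths default to 0,
#' and the usual well-formedness rules are enforced: unique non-empty tip
#' names, finite non-negative branch lengths, a single root.
#'
#' @param text newick string (exactly one of `text`/`file`).
#' @param file path to a newick file.
#' @return a rooted `phylo` object; tip order as encountered in the input.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of 'text' or 'file'")
  }
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  .check_balanced(text)
  # square-bracket comments (our annotation dialect) are ignored on input
  stripped <- gsub("\\[[^]]*\\]", "", text)
  phy <- tryCatch(
    ape::read.tree(text = stripped),
    error = function(e) stop("newick parse error: ", conditionMessage(e))
  )
  if (is.null(phy)) stop("newick parse error: could not parse '", text, "'")
  phy$tip.label <- .unquote_label(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- .unquote_label(phy$node.label)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  .validate_tree(phy)
  phy
}

.check_balanced <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("newick parse error: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop("newick parse error: ", depth, " unclosed '(' in input")
  }
}

.unquote_label <- function(x) {
  q <- grepl("^'.*'$", x)
  x[q] <- gsub("''", "'", substr(x[q], 2L, nchar(x[q]) - 1L))
  x
}

.validate_tree <- function(phy) {
  tips <- phy$tip.label
  if (any(!nzchar(tips))) stop("tree has an empty tip name")
  if (anyDuplicated(tips)) {
    stop(
      "duplicate tip name(s): ",
      paste(unique(tips[duplicated(tips)]), collapse = ", ")
    )
  }
  bl <- phy$edge.length
  if (any(!is.finite(bl))) stop("non-finite branch length in tree")
  if (any(bl < 0)) {
    bad <- which(bl < 0)[1]
    stop(
      "negative branch length ", bl[bad], " on edge to node ",
      phy$edge[bad, 2]
    )
  }
  invisible(phy)
}

#' Write a tree as newick, optionally with node annotations
#'
#' Produces standard newick. When `annotations` is supplied, node-specific
#' values are embedded as square-bracket comment blocks in the dialect
#' `[&time=...,ci_lo=...,ci_hi=...]`, placed after the node's label/branch
#' length. Labels containing whitespace or newick specials are single-quoted.
#'
#' @param phy a `phylo` object.
#' @param annotations optional data frame with a `node` column (ape node ids)
#'   plus any numeric/character columns to embed as `key=value` pairs.
#' @param file optional path; when given the string is also written to disk.
#' @param digits significant digits for branch lengths (default 15, which
#'   round-trips doubles to well below 1e-12).
#' @return the newick string, invisibly when `file` is given.
#' @export
write_newick <- function(phy, annotations = NULL, file = NULL, digits = 15) {
  .validate_tree(phy)
  ix <- .tree_index(phy)
  ann <- character(ix$n_all)
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations), "node" %in% names(annotations))
    keys <- setdiff(names(annotations), "node")
    for (r in seq_len(nrow(annotations))) {
      vals <- vapply(keys, function(k) {
        v <- annotations[[k]][r]
        if (is.numeric(v)) format(v, digits = digits) else as.character(v)
      }, character(1))
      ann[annotations$node[r]] <-
        paste0("[&", paste0(keys, "=", vals, collapse = ","), "]")
    }
  }
  lab <- function(x) {
    if (grepl("[\\s()\\[\\]',;:]", x, perl = TRUE)) {
      paste0("'", gsub("'", "''", x), "'")
    } else {
      x
    }
  }
  node_lab <- character(ix$n_all)
  node_lab[seq_len(ix$n_tip)] <- vapply(phy$tip.label, lab, character(1))
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    nl[is.na(nl)] <- ""
    has <- nzchar(nl)
    node_lab[ix$n_tip + which(has)] <-
      vapply(nl[has], lab, character(1))
  }
  emit <- function(v) {
    core <- if (v <= ix$n_tip) {
      node_lab[v]
    } else {
      paste0(
        "(", paste(vapply(ix$children[[v]], emit, character(1)),
          collapse = ","
        ), ")", node_lab[v]
      )
    }
    br <- if (v == ix$root) "" else paste0(":", format(ix$blen[v], digits = digits))
    paste0(core, br, ann[v])
  }
  out <- paste0(emit(ix$root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Pairwise patristic distances between tips
#'
#' Sum of branch lengths along the tree path between every pair of tips.
#'
#' @param phy a `phylo` object with branch lengths.
#' @return symmetric numeric matrix in tip order, zero diagonal.
#' @export
#' @examples
#' patristic_distances(read_newick("((A:1,B:1):1,C:2);"))
patristic_distances <- function(phy) {
  .validate_tree(phy)
  d <- stats::cophenetic(phy)
  d[phy$tip.label, phy$tip.label, drop = FALSE]
}

#' Export patristic distances as TSV
#'
#' Long format with header `taxon_i<TAB>taxon_j<TAB>distance`, one row per
#' unordered tip pair.
#'
#' @param phy a `phylo` object.
#' @param file output path.
#' @return the data frame that was written, invisibly.
#' @export
write_patristic_tsv <- function(phy, file) {
  m <- patristic_distances(phy)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(
    taxon_i = rownames(m)[idx[, 1]],
    taxon_j = colnames(m)[idx[, 2]],
    distance = m[idx],
    stringsAsFactors = FALSE
  )
  utils::write.table(df, file,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(df)
}
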
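#' Read a multiple sequence alignment from FASTA
#'
#' Wrapped lines and mixed case are handled; the sequence identifier is the
#' first whitespace-delimited token of the header. The alphabet is detected
#' from the residues unless given.
#'
#' @param file FASTA path.
#' @param alphabet `"auto"`, `"nt"` or `"aa"`.
#' @return uppercase character matrix, rows = taxa (named), columns = sites,
#'   with attribute `alphabet`.
#' @export
read_fasta <- function(file, alphabet = c("auto", "nt", "aa")) {
  alphabet <- match.arg(alphabet)
  x <- ape::read.FASTA(file, type = "AA")
  names(x) <- vapply(
    strsplit(names(x), "\\s+"), `[`, character(1), 1
  )
  len <- lengths(x)
  if (length(unique(len)) > 1) {
    ref <- len[1]
    bad <- names(x)[which(len != ref)[1]]
    stop(
      "alignment rows have unequal lengths: '", bad, "' has ",
      len[bad], " sites, '", names(x)[1], "' has ", ref
    )
  }
  m <- toupper(as.character(as.matrix(x)))
  if (alphabet == "auto") {
    resid <- setdiff(unique(as.vector(m)), c("-", ".", "?", "N", "X"))
    nt_chars <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V")
    alphabet <- if (length(resid) && all(resid %in% nt_chars)) "nt" else "aa"
  }
  structure(m, alphabet = alphabet)
}

#' Write a character-matrix alignment to FASTA
#'
#' @param x character matrix, rows = taxa (named).
#' @param file output path.
#' @param width line-wrap width.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(x, file, width = 70) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", rownames(x)[i]), con)
    s <- paste(x[i, ], collapse = "")
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(file)
}

.NT_STATES <- c("A", "C", "G", "T")
.NT_MISSING <- c("-", ".", "?", "N", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")
.AA_STATES <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)
.AA_MISSING <- c("-", ".", "?", "X", "B", "Z", "J", "*")

#' Compress an alignment into distinct site configurations
#'
#' A site configuration (site pattern) is the vector of states shown by all
#' sequences at one column. Identical configurations have identical
#' likelihoods, so an alignment of L sites reduces to its m distinct
#' configurations plus integer weights summing to L; memory and likelihood
#' work scale with m instead of L. Gap/ambiguity codes are treated as
#' missing data but remain part of a column's identity, so two columns
#' differing only in gap placement are distinct patterns.
#'
#' @param x character matrix (taxa by sites, rows named) or the result of
#'   [read_fasta()].
#' @param alphabet `"nt"` or `"aa"`; taken from `x`'s attribute if present.
#' @return a `pattern_alignment`: list with `taxa`, `states` (matrix taxa by
#'   m of state indices, `NA` = missing), `weights`, `m`, `L`, `alphabet`
#'   and the compression factor `m/L`.
#' @export
#' @examples
#' aln <- rbind(A = c("A", "A", "C", "G"), B = c("A", "A", "C", "G"),
#'              C = c("A", "A", "C", "G"))
#' compress_patterns(aln)$m  # 3 distinct configurations in 4 sites
compress_patterns <- function(x, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- attr(x, "alphabet")
  if (is.null(alphabet)) alphabet <- "nt"
  if (!is.matrix(x) || !is.character(x)) {
    stop("expected a character matrix of states")
  }
  if (is.null(rownames(x))) stop("alignment rows must be named")
  x[] <- toupper(x)
  states <- if (alphabet == "nt") .NT_STATES else .AA_STATES
  missing_codes <- if (alphabet == "nt") .NT_MISSING else .AA_MISSING
  known <- c(states, missing_codes)
  bad <- which(!(x %in% known))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(x))
    stop(
      "unknown character '", x[bad[1]], "' in sequence '",
      rownames(x)[rc[1]], "' at site ", rc[2]
    )
  }
  key <- apply(x, 2, paste, collapse = "\1")
  first <- !duplicated(key)
  weights <- as.vector(table(factor(key, levels = key[first])))
  cols <- x[, first, drop = FALSE]
  idx <- match(cols, states) # NA for missing codes
  state_idx <- matrix(idx, nrow = nrow(x),
    dimnames = list(rownames(x), NULL)
  )
  structure(
    list(
      taxa = rownames(x), states = state_idx, weights = weights,
      m = sum(first), L = ncol(x), alphabet = alphabet,
      compression = sum(first) / ncol(x)
    ),
    class = "pattern_alignment"
  )
}

#' @export
print.pattern_alignment <- function(x, ...) {
  cat(sprintf(
    "pattern_alignment: %d taxa, L = %d sites, m = %d configurations (m/L = %.3f)\n",
    length(x$taxa), x$L, x$m, x$compression
  ))
  invisible(x)
}

#' Write a compression report
#'
#' One `key<TAB>value` line each for taxa, L, m, m/L and (optionally) the
#' total log-likelihood.
#'
#' @param pa a `pattern_alignment`.
#' @param file output path.
#' @param loglik optional total log-likelihood to include.
#' @export
write_compression_report <- function(pa, file, loglik = NULL) {
  lines <- c(
    paste0("taxa\t", length(pa$taxa)),
    paste0("L\t", pa$L),
    paste0("m\t", pa$m),
    paste0("m_over_L\t", format(pa$compression, digits = 10))
  )
  if (!is.null(loglik)) {
    lines <- c(lines, paste0("log_likelihood\t", format(loglik, digits = 12)))
  }
  writeLines(lines, file)
  invisible(file)
}
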
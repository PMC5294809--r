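#' Read a nucleotide alignment
#'
#' FASTA and NEXUS (DATA/CHARACTERS block) are supported, via ape's
#' readers; symbols are validated against the IUPAC nucleotide alphabet
#' and upper-cased.
#'
#' @param path File path.
#' @param format `"fasta"`, `"nexus"`, or `"auto"` (by extension).
#' @return A taxa x sites character matrix.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|nxs)$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  aln <- if (format == "fasta") {
    as.character(ape::read.FASTA(path))
  } else {
    ape::read.nexus.data(path)
  }
  if (anyDuplicated(names(aln)))
    stop("duplicate taxon names in ", path)
  lens <- lengths(aln)
  if (length(unique(lens)) != 1)
    stop("ragged alignment in ", path, ": lengths ",
         paste(unique(lens), collapse = ", "))
  as_char_alignment(do.call(rbind, lapply(aln, toupper)))
}

#' Write an alignment as FASTA
#'
#' @param alignment A taxa x sites character matrix.
#' @param path Output file.
#' @export
write_fasta <- function(alignment, path) {
  lines <- unlist(lapply(rownames(alignment), function(tx)
    c(paste0(">", tx), paste(alignment[tx, ], collapse = ""))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' @param path File path, or a Newick string via `text`.
#' @param text Optional Newick string (overrides `path`).
#' @return A rooted `ape::phylo`.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (any(tree$tip.label == "")) stop("unlabeled leaves")
  tree
}

#' Write / read a trace table
#'
#' Tab-separated with a header row; floats at full precision so that a
#' round-trip is bit-identical.  Comment lines starting with `#` (the
#' provenance header) are skipped on read.
#'
#' @param trace A trace data frame from [run_chain()].
#' @param path File path.
#' @param provenance Optional named character vector written as
#'   `# key: value` comment lines.
#' @return `path` invisibly ([write_trace()]); the data frame
#'   ([read_trace()]).
#' @export
write_trace <- function(trace, path, provenance = NULL) {
  if (nrow(trace) == 0) stop("empty trace")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  num <- vapply(trace, is.numeric, TRUE)
  out <- trace
  out[num] <- lapply(trace[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(model = "character"))
  tr$model <- as.character(tr$model)
  for (col in setdiff(names(tr), "model")) tr[[col]] <- as.numeric(tr[[col]])
  tr
}
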
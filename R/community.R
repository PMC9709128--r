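#' Assemble a community of reference genomes
#'
#' A genome set is the ordered community the index is built over.  Genome ids
#' are assigned 1-based in input order and the order is part of the object:
#' one-phase builds depend on it, so it must be reproducible.
#'
#' @param sequences A named list; each element is a character vector of one or
#'   more contig sequences for one genome.  Names become genome names and
#'   must be unique.
#' @return An object of class `genome_set`: a list of records with fields
#'   `gid`, `name` and `sequences`.
#' @examples
#' gs <- genome_set(list(gA = "ACGTACGTACGT", gB = c("TTTTACGT", "GGGGCCCC")))
#' @export
genome_set <- function(sequences) {
  if (!is.list(sequences) || length(sequences) == 0)
    stop("sequences must be a non-empty named list of contig vectors")
  nms <- names(sequences)
  if (is.null(nms) || any(!nzchar(nms))) stop("every genome must be named")
  if (anyDuplicated(nms)) stop("duplicate genome names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  recs <- lapply(seq_along(sequences), function(i) {
    ctg <- toupper(as.character(sequences[[i]]))
    if (length(ctg) == 0 || any(!nzchar(ctg)))
      stop("genome '", nms[i], "' has an empty contig")
    list(gid = i, name = nms[i], sequences = ctg)
  })
  structure(recs, class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  lens <- vapply(x, function(r) sum(nchar(r$sequences)), numeric(1))
  cat(sprintf("<genome_set> %d genomes, %s bp total\n",
              length(x), format(sum(lens), big.mark = ",")))
  for (r in utils::head(x, 8))
    cat(sprintf("  [%d] %s: %d contig(s), %s bp\n", r$gid, r$name,
                length(r$sequences), format(sum(nchar(r$sequences)), big.mark = ",")))
  if (length(x) > 8) cat("  ...\n")
  invisible(x)
}

genome_table <- function(genomes) {
  data.frame(
    gid = vapply(genomes, `[[`, integer(1), "gid"),
    name = vapply(genomes, `[[`, character(1), "name"),
    length = vapply(genomes, function(r) sum(nchar(r$sequences)), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Read a community from FASTA files or a manifest
#'
#' Each FASTA file holds one genome; all records in a file are treated as
#' contigs of that genome.  Alternatively a tab-separated manifest with
#' columns `gid`, `name`, `path` fixes the processing order explicitly.
#' Gzip-compressed FASTA is accepted.
#'
#' @param files Character vector of FASTA paths (one genome per file).
#' @param names Genome names; defaults to file base names without extension.
#' @param manifest Path to a manifest TSV (used instead of `files`).
#' @return A [genome_set()].
#' @export
read_community <- function(files = NULL, names = NULL, manifest = NULL) {
  if (!is.null(manifest)) {
    man <- utils::read.table(manifest, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("gid", "name", "path") %in% base::names(man)))
      stop("manifest must have columns gid, name, path")
    man <- man[order(man$gid), , drop = FALSE]
    files <- man$path
    rel <- !file.exists(files) & file.exists(file.path(dirname(manifest), files))
    files[rel] <- file.path(dirname(manifest), files[rel])
    names <- man$name
  }
  if (is.null(files) || length(files) == 0)
    stop("either files or manifest must be given")
  if (is.null(names)) names <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(files))
  seqs <- lapply(files, function(f) {
    ss <- Biostrings::readDNAStringSet(f)
    if (length(ss) == 0) stop("no sequences in ", f)
    as.character(ss)
  })
  base::names(seqs) <- names
  genome_set(seqs)
}

#' Write a community as FASTA files plus a manifest
#'
#' @param genomes A [genome_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_community <- function(genomes, dir) {
  stopifnot(inherits(genomes, "genome_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(genomes))
  for (r in genomes) {
    ss <- Biostrings::DNAStringSet(r$sequences)
    base::names(ss) <- if (length(r$sequences) == 1) r$name else
      sprintf("%s|contig%d", r$name, seq_along(r$sequences))
    paths[r$gid] <- file.path(dir, paste0(r$name, ".fasta"))
    Biostrings::writeXStringSet(ss, paths[r$gid])
  }
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(gid = seq_along(genomes),
               name = vapply(genomes, `[[`, character(1), "name"),
               path = basename(paths)),
    man, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}
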
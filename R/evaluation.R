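#' Per-genome signature statistics
#'
#' Re-scans every genome's k-mers against the built index and counts, per
#' genome, the positions whose k-mer classifies back to that genome's id --
#' the signature count the index effectively offers at query time.  Reports
#' the per-genome table plus the total/min/max summary and the genomes left
#' without any signature.
#'
#' @param index A `signature_index`.
#' @param genomes The [genome_set()] the index was built from (same k and
#'   canonical flag; every genome must be present in the index table).
#' @return An object of class `signature_stats`: list with `per_genome`
#'   (data.frame `gid`, `name`, `length`, `signature_count`), `total`, `min`,
#'   `max`, `zero_signature_genomes`.
#' @export
signature_stats <- function(index, genomes) {
  stopifnot(inherits(index, "signature_index"), inherits(genomes, "genome_set"))
  tab <- index$genome_table
  counts <- numeric(length(genomes))
  for (i in seq_along(genomes)) {
    r <- genomes[[i]]
    j <- match(r$name, tab$name)
    if (is.na(j)) stop("genome '", r$name, "' is not in the index table")
    gid <- tab$gid[j]
    cnt <- 0
    for (s in r$sequences) {
      calls <- cpp_classify_sequence(index$entries, s, index$k,
                                     index$family$seeds, index$m,
                                     index$canonical)
      cnt <- cnt + sum(calls == gid)
    }
    counts[i] <- cnt
  }
  per <- data.frame(
    gid = vapply(genomes, `[[`, integer(1), "gid"),
    name = vapply(genomes, `[[`, character(1), "name"),
    length = vapply(genomes, function(r) sum(nchar(r$sequences)), numeric(1)),
    signature_count = counts,
    stringsAsFactors = FALSE
  )
  structure(
    list(per_genome = per, total = sum(counts), min = min(counts),
         max = max(counts),
         zero_signature_genomes = per$name[per$signature_count == 0]),
    class = "signature_stats"
  )
}

#' @export
print.signature_stats <- function(x, ...) {
  cat(sprintf("<signature_stats> %d genomes: total %s, min %s, max %s signatures\n",
              nrow(x$per_genome), format(x$total, big.mark = ","),
              format(x$min, big.mark = ","), format(x$max, big.mark = ",")))
  if (length(x$zero_signature_genomes))
    cat("  zero signatures:", paste(x$zero_signature_genomes, collapse = ", "), "\n")
  invisible(x)
}

#' Write signature statistics as TSV plus a JSON summary
#'
#' @param stats A `signature_stats` object.
#' @param tsv_path Per-genome table destination (TSV).
#' @param json_path Summary destination (JSON with `total`, `min`, `max`,
#'   `zero_signature_genomes`); omitted when `NULL`.
#' @return Invisibly, `tsv_path`.
#' @export
write_signature_stats <- function(stats, tsv_path, json_path = NULL) {
  stopifnot(inherits(stats, "signature_stats"))
  utils::write.table(stats$per_genome, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(total = stats$total, min = stats$min, max = stats$max,
           zero_signature_genomes = as.list(stats$zero_signature_genomes)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}

#' Call genome presence from read assignments
#'
#' A genome is called present when at least `min_reads` reads were assigned
#' to it.  The default of 1 is deliberately permissive: every genome that
#' attracts a single read is predicted, which maximizes recall at the cost of
#' precision.
#'
#' @param assignments Output of [query_sample()].
#' @param min_reads Minimum assigned-read count (`>= 1`).
#' @return Sorted integer vector of predicted genome ids.
#' @export
call_presence <- function(assignments, min_reads = 1L) {
  min_reads <- as.integer(min_reads)
  if (is.na(min_reads) || min_reads < 1) stop("min_reads must be >= 1")
  g <- assignments$gid[!is.na(assignments$gid)]
  if (length(g) == 0) return(integer(0))
  tab <- table(g)
  sort(as.integer(names(tab)[tab >= min_reads]))
}

#' Precision, recall and F1 of a presence call
#'
#' Precision is the number of correctly predicted genomes over all predicted
#' genomes (0 when nothing is predicted); recall is the number of correctly
#' predicted genomes over the genomes truly in the sample; F1 is their
#' harmonic mean (0 when both are 0).
#'
#' @param predicted Predicted genome ids or names.
#' @param truth True genome ids or names (same namespace; must be non-empty).
#' @return An object of class `presence_eval`: list with `precision`,
#'   `recall`, `f1`, `n_predicted`, `n_truth`, `true_positives`.
#' @examples
#' evaluate_presence(c("A", "B", "C", "D"), c("A", "B"))
#' @export
evaluate_presence <- function(predicted, truth) {
  truth <- unique(truth)
  if (length(truth) == 0) stop("truth set must be non-empty (recall undefined)")
  predicted <- unique(predicted)
  tp <- length(intersect(predicted, truth))
  precision <- if (length(predicted) == 0) 0 else tp / length(predicted)
  recall <- tp / length(truth)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(
    list(precision = precision, recall = recall, f1 = f1,
         n_predicted = length(predicted), n_truth = length(truth),
         true_positives = tp),
    class = "presence_eval"
  )
}

#' @export
print.presence_eval <- function(x, ...) {
  cat(sprintf("<presence_eval> precision %.3f, recall %.3f, F1 %.3f (%d predicted, %d truth, %d correct)\n",
              x$precision, x$recall, x$f1, x$n_predicted, x$n_truth,
              x$true_positives))
  invisible(x)
}

#' Write a presence evaluation as JSON
#'
#' @param eval A `presence_eval` object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_presence_eval <- function(eval, path) {
  stopifnot(inherits(eval, "presence_eval"))
  jsonlite::write_json(unclass(eval), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
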
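#' Summarise a genome assembly FASTA
#'
#' Computes the standard printed assembly statistics: contig count, total
#' length in bp and Mbp (2 decimals), and GC content in percent (1 decimal).
#' Ambiguity codes (N etc.) count toward the total length; by default they
#' are excluded from both the numerator and denominator of the GC fraction
#' (`gc_denominator = "acgt"`); `"all"` divides by the full length instead.
#' The difference between the conventions is negligible for typical draft
#' assemblies but both are offered since published GC values rarely state
#' which was used.
#'
#' @param path nucleotide FASTA file.
#' @param gc_denominator `"acgt"` (default) or `"all"`.
#' @return list of class `genome_summary` with `n_contigs`,
#'   `total_length_bp`, `total_length_mbp`, `gc_percent`.
#' @export
summarize_fasta <- function(path, gc_denominator = c("acgt", "all")) {
  gc_denominator <- match.arg(gc_denominator)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("cannot read FASTA ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0)
    stop("FASTA file ", path, " contains no sequences", call. = FALSE)
  up <- Biostrings::BStringSet(toupper(as.character(seqs)))
  totals <- colSums(Biostrings::letterFrequency(up, c("A", "C", "G", "T")))
  acgt <- sum(totals)
  len <- sum(Biostrings::width(seqs))
  if (len > 0 && acgt / len < 0.5)
    warning("sequence composition looks non-nucleotide (possibly amino ",
            "acids); GC content may be meaningless", call. = FALSE)
  gc <- sum(totals[c("G", "C")])
  names(gc) <- NULL
  denom <- if (gc_denominator == "acgt") acgt else len
  structure(list(n_contigs = length(seqs),
                 total_length_bp = len,
                 total_length_mbp = round(len / 1e6, 2),
                 gc_percent = round(100 * gc / denom, 1)),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("contigs: ", x$n_contigs, "\n",
      "total length: ", x$total_length_bp, " bp (", x$total_length_mbp,
      " Mbp)\n", "GC content: ", x$gc_percent, " %\n", sep = "")
  invisible(x)
}
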
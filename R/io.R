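#' Read amplicon sequences from FASTA or FASTQ
#'
#' Format is chosen by file extension (`.fastq`/`.fq` read as FASTQ,
#' anything else as FASTA). Qualities are dropped; reads are assumed
#' quality-filtered upstream (see [filter_mean_quality()]).
#'
#' @param path file path.
#' @return named character vector of uppercase sequences.
#' @export
read_sequences <- function(path) {
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
        "fastq" else "fasta"
    ss <- Biostrings::readDNAStringSet(path, format = fmt)
    setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Exact primer trimming
#'
#' Removes a forward-primer prefix and/or reverse-primer suffix by exact
#' match; reads missing either primer are dropped. A deliberately simple
#' stand-in for dedicated primer-removal tools, sufficient for
#' synthetic or pre-demultiplexed data.
#'
#' @param reads named character vector.
#' @param forward,reverse primer sequences (`NULL` to skip either end).
#' @return trimmed reads (subset of the input).
#' @export
trim_primers <- function(reads, forward = NULL, reverse = NULL) {
    keep <- rep(TRUE, length(reads))
    if (!is.null(forward)) {
        keep <- keep & startsWith(reads, forward)
        reads <- substr(reads, nchar(forward) + 1L, nchar(reads))
    }
    if (!is.null(reverse)) {
        keep <- keep & endsWith(reads, reverse)
        reads <- substr(reads, 1L, nchar(reads) - nchar(reverse))
    }
    reads[keep]
}

#' Mean-quality read filter for FASTQ input
#'
#' Keeps reads whose mean Phred quality is at or above `min_q`.
#'
#' @param path FASTQ file.
#' @param min_q minimum mean Phred score (default 20).
#' @return named character vector of passing reads.
#' @export
filter_mean_quality <- function(path, min_q = 20) {
    qs <- Biostrings::readQualityScaledDNAStringSet(path)
    mq <- vapply(as(Biostrings::quality(qs), "IntegerList"), mean, 0)
    ss <- qs[mq >= min_q]
    setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}
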
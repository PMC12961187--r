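#' Pairwise DNA alignment with affine gap penalties
#'
#' Dynamic-programming alignment backing the similarity-search engine, the
#' reference-validation homolog search and the long-read clustering code.
#' Two modes are provided:
#' \describe{
#'   \item{`"semi-global"`}{ends-free ("overlap") alignment: terminal gaps on
#'     either sequence are free; identity, mismatch and gap counts are
#'     computed over the aligned core (first to last column in which both
#'     sequences contribute a residue), and the reported query/subject
#'     intervals delimit that core.}
#'   \item{`"global"`}{end-to-end alignment; terminal gaps are charged at
#'     their own (usually milder) rates and all columns, terminal gaps
#'     included, enter the identity denominator.}
#' }
#' Identity is always `matches / alignment columns` with gap columns counted,
#' in percent. `N` matches nothing, not even another `N`.
#'
#' @param query,subject DNA strings over `A,C,G,T,N` (case-insensitive).
#' @param mode `"semi-global"` or `"global"`.
#' @param match,mismatch match score and mismatch score (mismatch negative).
#' @param gap_open,gap_ext internal gap penalties, positive costs; a gap of
#'   length L costs `gap_open + L * gap_ext`.
#' @param term_open,term_ext terminal-gap penalties for `mode = "global"`
#'   (ignored in semi-global mode, where terminal gaps are free). Defaults
#'   equal the internal penalties.
#' @return A list with elements `score`, `identity`, `query_coverage`
#'   (percent of the query inside the aligned core; 100 for global mode),
#'   `matches`, `mismatches`, `gap_opens`, `columns`, `query_start`,
#'   `query_end`, `subject_start`, `subject_end` (0-based half-open),
#'   `aligned_query`, `aligned_subject`.
#' @examples
#' aln <- pairwise_alignment("ACGTACGTAC", "ACGTACGTAC")
#' aln$identity   # 100
#' @export
pairwise_alignment <- function(query, subject,
                               mode = c("semi-global", "global"),
                               match = 2, mismatch = -3,
                               gap_open = 5, gap_ext = 2,
                               term_open = gap_open, term_ext = gap_ext) {
    mode <- match.arg(mode)
    query <- toupper(as.character(query))
    subject <- toupper(as.character(subject))
    if (nchar(query) < 1L || nchar(subject) < 1L)
        stop("query and subject must be non-empty")
    bad <- grepl("[^ACGTN]", c(query, subject))
    if (any(bad))
        stop("sequences must be over the alphabet {A,C,G,T,N}")
    free_ends <- mode == "semi-global"
    res <- .align_pair_cpp(query, subject, match, mismatch,
                           gap_open, gap_ext, term_open, term_ext, free_ends)
    qlen <- nchar(query)
    res$query_coverage <- if (free_ends)
        100 * (res$query_end - res$query_start) / qlen else 100
    res
}

#' Reverse-complement a DNA string
#' @param x DNA string over `A,C,G,T,N`.
#' @return the reverse complement, uppercase.
#' @keywords internal
revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}
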
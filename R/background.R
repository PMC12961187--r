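#' Build the non-target background database by greedy centroid clustering
#'
#' The background database absorbs off-target amplification (non-fish
#' mitochondria, rRNA/ITS carry-over) during annotation. Fish-taxon
#' sequences are removed, the remainder are sorted by decreasing length
#' (ties broken by id) and clustered in a single greedy pass: a sequence
#' joins the first existing centroid with global-alignment identity at or
#' above the threshold, otherwise it founds a new cluster. Only centroids
#' are returned; the result is a filtering tool, not a precise non-fish
#' identifier.
#'
#' @param seqs named character vector (or `DNAStringSet`) of sequences;
#'   names are ids.
#' @param taxa character vector of taxon labels parallel to `seqs`.
#' @param fish_taxa character vector of taxon labels to exclude.
#' @param identity inclusive clustering identity threshold in percent
#'   (default 97).
#' @return data.frame with columns `id`, `sequence`, `taxon`, `cluster_size`.
#' @export
build_background_db <- function(seqs, taxa, fish_taxa = character(0),
                                identity = 97) {
    seqs <- setNames(toupper(as.character(seqs)), names(seqs))
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stop("sequences must be named")
    stopifnot(length(taxa) == length(seqs))
    keep <- !(taxa %in% fish_taxa)
    seqs <- seqs[keep]; taxa <- taxa[keep]
    empty <- data.frame(id = character(0), sequence = character(0),
                        taxon = character(0), cluster_size = integer(0))
    if (length(seqs) == 0L) return(empty)
    ord <- order(-nchar(seqs), names(seqs))
    seqs <- seqs[ord]; taxa <- taxa[ord]
    cent_id <- character(0); cent_seq <- character(0)
    cent_tax <- character(0); cent_n <- integer(0)
    for (k in seq_along(seqs)) {
        joined <- FALSE
        for (c in seq_along(cent_seq)) {
            aln <- pairwise_alignment(seqs[[k]], cent_seq[c], mode = "global")
            if (aln$identity >= identity) {
                cent_n[c] <- cent_n[c] + 1L
                joined <- TRUE
                break
            }
        }
        if (!joined) {
            cent_id <- c(cent_id, names(seqs)[k])
            cent_seq <- c(cent_seq, seqs[[k]])
            cent_tax <- c(cent_tax, taxa[k])
            cent_n <- c(cent_n, 1L)
        }
    }
    data.frame(id = cent_id, sequence = cent_seq, taxon = cent_tax,
               cluster_size = cent_n, stringsAsFactors = FALSE)
}
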
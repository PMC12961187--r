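#' Canonical mitochondrial gene names
#'
#' The 15 mitochondrial genes used as metabarcoding references in fish: the
#' two rRNA genes and the 13 protein-coding genes, each with the alternative
#' spellings commonly found in sequence-record annotations. Matching is
#' case-insensitive and ignores hyphens and spaces.
#'
#' @return A data.frame with columns `canonical`, `type`
#'   (`"rRNA"`/`"protein_coding"`) and `aliases` (list column of alternative
#'   names).
#' @examples
#' tab <- canonical_gene_table()
#' table(tab$type)
#' @export
canonical_gene_table <- function() {
    spec <- list(
        list("12S rRNA", "rRNA",
             c("rrnS", "rrn12", "rns", "rrnaS", "s-rRNA", "SSU")),
        list("16S rRNA", "rRNA",
             c("rrnL", "rrn16", "rnl", "rrnaL", "l-rRNA", "LSU")),
        list("ND1", "protein_coding", c("NAD1", "NADH1", "NADH-1")),
        list("ND2", "protein_coding", c("NAD2", "NADH2", "NADH-2")),
        list("COXI", "protein_coding", c("COX1", "COI", "CO1", "COX-1")),
        list("COXII", "protein_coding", c("COX2", "COII", "CO2", "COX-II")),
        list("ATPase8", "protein_coding",
             c("ATP8", "apt8", "MTATP8", "stp8", "ATPase-8", "AT8")),
        list("ATPase6", "protein_coding",
             c("ATP6", "MTATP6", "ATPase-6", "AT6")),
        list("COXIII", "protein_coding", c("COX3", "COIII", "CO3", "COX-III")),
        list("ND3", "protein_coding", c("NAD3", "NADH3", "NADH-3")),
        list("ND4L", "protein_coding",
             c("NAD4L", "NADH4L", "NADH-4L", "ND41", "NA4L")),
        list("ND4", "protein_coding", c("NAD4", "NADH4", "NADH-4")),
        list("ND5", "protein_coding", c("NAD5", "NADH5", "NADH-5", "NND5", "MD5")),
        list("ND6", "protein_coding", c("NAD6", "NADH6", "NADH-6")),
        list("Cytb", "protein_coding",
             c("MT-CYB", "cyto B", "Cyt-B", "CYBT", "ctb", "cob", "Cb")))
    data.frame(
        canonical = vapply(spec, `[[`, "", 1L),
        type = vapply(spec, `[[`, "", 2L),
        aliases = I(lapply(spec, `[[`, 3L)),
        stringsAsFactors = FALSE)
}

.gene_key <- function(x) toupper(gsub("[-[:space:]]", "", x))

# lookup table built once per session
.gene_lookup <- local({
    env <- new.env(parent = emptyenv())
    function() {
        if (is.null(env$map)) {
            tab <- canonical_gene_table()
            keys <- character(0); vals <- character(0)
            for (i in seq_len(nrow(tab))) {
                nm <- c(tab$canonical[i], tab$aliases[[i]])
                keys <- c(keys, .gene_key(nm))
                vals <- c(vals, rep(tab$canonical[i], length(nm)))
            }
            env$map <- setNames(vals, keys)
        }
        env$map
    }
})

#' Normalize a mitochondrial gene name
#'
#' Maps the many alternative spellings found in sequence records (e.g.
#' `"rrnS"`, `"COi"`, `"MT-CYB"`) to one of the 15 canonical names in
#' [canonical_gene_table()]. Matching is case-insensitive and ignores hyphens
#' and spaces.
#'
#' @param raw character vector of raw gene names.
#' @return character vector of canonical names, `NA` where the name is not a
#'   recognized mitochondrial gene.
#' @examples
#' normalize_gene_name(c("rrnS", "COi", "ND7"))
#' @export
normalize_gene_name <- function(raw) {
    stopifnot(is.character(raw), all(nzchar(raw)))
    map <- .gene_lookup()
    out <- unname(map[.gene_key(raw)])
    out
}
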
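#' Run the full metabarcoding analysis
#'
#' Convenience wrapper chaining ASV generation (platform-appropriate),
#' similarity search with fallback, taxonomy annotation, table
#' summarization and (when a manifest is given) the multi-sample result
#' matrix with P/N/S badges.
#'
#' @param reads_by_sample named list of reads per sample (ignored when
#'   `asvs` is supplied).
#' @param ref an `mb_refdb` reference database.
#' @param chunk_statuses `mb_chunks` from [validate_reference_set()] (or
#'   `NULL` to skip heterospecific filtering).
#' @param background background centroid data.frame (or `NULL`).
#' @param manifest an `mb_manifest` (or `NULL` for no matrix).
#' @param platform `"illumina"` or `"nanopore"`.
#' @param threshold species-level identity threshold in percent.
#' @param asvs precomputed `mb_asvs` (reanalysis path); bypasses read
#'   processing.
#' @param ... passed to [illumina_asvs()] / [nanopore_asvs()].
#' @return list with `asvs`, `annotations`, `tables` and (optionally)
#'   `matrix`.
#' @export
run_pipeline <- function(reads_by_sample = NULL, ref, chunk_statuses = NULL,
                         background = NULL, manifest = NULL,
                         platform = c("illumina", "nanopore"),
                         threshold = 99, asvs = NULL, ...) {
    platform <- match.arg(platform)
    if (is.null(asvs)) {
        stopifnot(!is.null(reads_by_sample))
        asvs <- if (platform == "illumina")
            illumina_asvs(reads_by_sample, ...)
        else nanopore_asvs(reads_by_sample, ...)
    }
    db <- combined_search_db(ref, background)
    tax <- taxonomy_table(ref)
    ann <- annotate_asvs(asvs, db, chunk_statuses, tax,
                         threshold = threshold)
    tables <- summarize_tables(ann, asvs)
    out <- list(asvs = asvs, annotations = ann, tables = tables)
    if (!is.null(manifest))
        out$matrix <- build_matrix(tables$species, manifest)
    out
}
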